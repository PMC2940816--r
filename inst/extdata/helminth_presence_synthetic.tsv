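species	Algeria	Brazil	Cambodia	CentralAfricanRepublic	China	Colombia	DRCongo	France	Israel	Italy	Japan	Kenya	Mexico	Namibia	Nigeria	Pakistan	PapuaNewGuinea	Russia	Senegal	SouthAfrica	UnitedStates
Ascaris lumbricoides	0	1	R	1	1	1	1	0	0	0	0	1	R	1	R	0	1	0	1	1	R
Trichuris trichiura	R	0	1	1	0	R	R	R	1	0	1	R	1	1	R	1	R	0	1	1	0
Necator americanus	1	R	1	0	1	1	0	0	0	0	0	0	0	0	1	1	1	0	0	0	0
Ancylostoma duodenale	0	1	1	1	0	R	R	R	0	0	1	1	R	0	R	0	1	0	R	1	0
Wuchereria bancrofti	0	R	1	0	0	0	0	0	0	0	R	0	0	0	0	1	1	1	0	R	1
Brugia malayi	0	1	1	R	1	R	R	0	1	0	R	1	1	1	R	1	1	R	0	R	1
Onchocerca volvulus	0	R	R	1	0	R	1	0	1	0	0	1	0	1	1	0	1	0	R	R	0
Loa loa	1	1	0	0	1	1	1	0	R	0	0	1	1	0	1	0	0	0	R	1	1
Schistosoma mansoni	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
Schistosoma haematobium	1	R	1	R	1	R	R	0	0	0	R	R	1	1	1	1	R	1	0	1	1
Schistosoma intercalatum	0	1	1	0	1	1	1	1	0	0	0	R	0	1	1	R	0	0	1	R	0
Schistosoma japonicum	R	1	1	R	R	R	R	0	0	R	0	1	R	1	1	R	0	0	1	1	0
Schistosoma mekongi	0	0	0	0	0	0	1	0	0	R	0	0	0	0	1	0	0	0	1	1	0
Clonorchis sinensis	0	1	1	R	1	1	1	1	0	0	0	1	0	1	1	1	1	R	1	1	1
Opisthorchis viverrini	R	1	1	1	1	1	1	0	0	0	1	1	0	1	1	1	1	0	1	1	0
Paragonimus africanus	0	1	0	1	1	0	1	0	0	0	1	1	1	1	1	0	1	0	1	0	0
Paragonimus compactus	0	1	1	1	0	1	1	0	0	0	R	1	R	1	1	1	1	1	1	1	0
Paragonimus ecuadoriensis	0	R	1	1	R	1	1	0	0	0	R	1	1	1	1	1	1	1	R	1	0
Paragonimus hueitungensis	1	R	1	R	0	1	R	0	1	0	1	R	1	1	R	0	1	0	1	1	0
Paragonimus heterotremus	R	0	1	0	0	1	R	0	0	1	0	1	0	0	1	0	0	0	0	0	0
Paragonimus kellicotti	0	R	R	R	R	R	R	0	R	0	0	R	R	R	R	R	R	0	R	R	0
Paragonimus mexicanus	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
Paragonimus miyazakii	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0	R	0
Paragonimus szechuanensis	0	R	R	R	1	R	1	1	0	1	0	1	1	R	1	1	R	0	1	1	0
Paragonimus tuanshanensis	0	0	0	0	0	0	R	0	0	0	0	0	0	0	0	0	1	0	0	1	0
Paragonimus uterobilateralis	0	1	1	R	1	0	R	0	0	1	0	1	1	1	1	1	1	0	R	1	0
Paragonimus westermani	0	0	0	0	0	0	0	0	0	R	0	R	0	0	1	0	0	0	1	0	0
Fasciolopsis buski	0	1	1	1	1	1	1	0	1	0	0	0	1	R	R	0	1	0	1	1	0
Fasciola hepatica	0	R	1	1	1	R	0	1	1	0	0	1	1	R	1	1	1	0	1	0	0
Taenia solium	1	1	1	R	1	1	1	R	0	1	1	1	1	1	1	R	1	0	1	R	0
Taenia saginata	0	1	0	0	R	0	0	0	0	0	0	0	1	1	0	0	0	0	0	R	0
Enterobius vermicularis	R	R	1	1	R	1	1	R	0	0	1	1	R	1	R	1	1	0	1	1	0
Strongyloides stercoralis	1	1	0	R	0	1	R	0	0	0	0	1	0	1	0	1	R	1	1	R	1
Trichinella spiralis	R	1	0	1	1	0	1	1	0	0	1	1	0	0	1	R	R	0	R	1	0
Echinococcus granulosus	R	1	R	1	R	1	1	0	1	0	0	1	1	0	1	R	0	1	0	0	0
Echinococcus multilocularis	0	1	1	1	1	1	1	R	0	R	0	1	1	0	1	R	1	0	1	R	0
Hymenolepis nana	0	1	1	R	1	1	1	R	1	0	0	R	0	R	1	1	1	R	0	1	0
Hymenolepis diminuta	R	R	R	R	R	R	R	0	0	0	0	R	R	0	R	0	R	0	R	R	0
Diphyllobothrium latum	0	1	1	0	0	1	1	0	1	0	1	1	0	1	R	R	1	R	0	R	0
Dracunculus medinensis	0	0	0	0	0	1	1	0	0	0	0	0	1	0	0	0	R	0	0	1	0
Anisakis simplex	0	R	1	R	1	1	1	0	R	0	0	0	1	0	1	1	0	0	R	R	1
Toxocara canis	0	0	1	R	1	0	0	0	0	0	0	1	0	0	0	0	0	1	0	0	0
Angiostrongylus cantonensis	1	0	0	1	1	0	1	0	0	0	R	1	0	0	0	0	R	0	1	0	1
Angiostrongylus costaricensis	0	1	1	0	1	R	R	0	0	0	0	R	R	1	1	1	1	0	1	0	1
Capillaria philippinensis	0	0	0	0	0	0	1	0	0	0	0	1	0	0	0	0	0	0	0	0	0
Capillaria hepatica	R	0	0	R	R	R	R	R	0	R	0	R	0	0	0	0	0	0	0	R	0
Gnathostoma spinigerum	0	1	1	1	1	1	1	0	0	0	0	R	0	1	R	0	R	1	1	1	0
Heterophyes heterophyes	0	1	0	1	R	1	1	0	1	0	1	1	1	R	1	R	1	1	0	1	0
Metagonimus yokogawai	0	R	1	R	0	1	1	0	0	0	0	R	0	1	1	1	1	1	1	1	0
Dicrocoelium dendriticum	0	1	R	0	1	0	0	0	1	1	0	1	1	1	1	0	1	0	1	1	R
Echinostoma ilocanum	0	1	R	R	R	R	1	1	0	0	0	1	1	1	R	R	1	0	1	1	1
Mansonella perstans	0	1	R	1	0	R	1	0	R	1	R	1	1	1	1	R	1	1	1	R	1
Mansonella ozzardi	0	0	1	1	1	0	1	0	1	R	1	1	R	1	1	R	1	0	1	1	0
Mansonella streptocerca	1	1	1	1	1	0	1	0	1	0	1	1	1	1	R	R	0	R	1	1	0
Brugia timori	0	0	0	0	0	0	0	0	0	R	0	1	0	0	1	0	0	0	0	0	0
Dirofilaria immitis	0	R	R	0	R	0	R	0	0	0	0	0	R	R	0	0	0	0	0	0	0
Dipylidium caninum	0	R	R	R	R	0	R	0	0	R	R	R	R	0	R	R	R	0	R	R	R
Spirometra mansoni	0	1	R	1	R	1	1	0	1	0	0	1	R	1	1	1	R	0	0	0	0
Oesophagostomum bifurcum	1	1	1	R	1	R	1	0	1	0	1	1	R	1	R	R	1	0	1	1	0
Trichostrongylus colubriformis	0	1	1	R	1	1	1	1	1	0	1	1	1	1	1	R	1	0	R	1	0
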