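test_that("diversity counts species present per country", {
  m <- presence_matrix(toy_presence())
  expect_identical(compute_diversity(m), c(c1 = 2L, c2 = 1L))

  none <- toy_presence(); none[] <- FALSE
  expect_identical(compute_diversity(presence_matrix(none)),
                   c(c1 = 0L, c2 = 0L))
  expect_error(presence_matrix(matrix(TRUE, 0, 0)), "species")
})

test_that("common-only diversity drops species that are rare everywhere", {
  pres <- toy_presence()
  rare <- pres & FALSE
  rare["sp2", "c1"] <- TRUE          # sp2 present only in c1, rare there
  pres["sp3", "c2"] <- TRUE          # give c2 a second, common species
  m <- presence_matrix(pres, rare)
  expect_identical(compute_diversity(m, common_only = TRUE),
                   c(c1 = 1L, c2 = 2L))
  # per-country: common-only never exceeds the full count
  expect_true(all(compute_diversity(m, common_only = TRUE) <=
                    compute_diversity(m)))
  # rare flagged where absent is rejected
  bad <- rare; bad["sp3", "c1"] <- TRUE
  expect_error(presence_matrix(toy_presence(), bad), "absent")
})

test_that("diversity is invariant to row/column permutation", {
  set.seed(11)
  pres <- matrix(runif(60) < 0.5, 10, 6,
                 dimnames = list(paste0("sp", 1:10), paste0("c", 1:6)))
  m <- presence_matrix(pres)
  mp <- presence_matrix(pres[sample(10), sample(6)])
  d1 <- compute_diversity(m)
  d2 <- compute_diversity(mp)
  expect_identical(d1[sort(names(d1))], d2[sort(names(d2))])
})

test_that("presence matrix TSV round-trips and rejects malformed cells", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("species\tc1\tc2", "sp1\t1\tR", "sp2\t0\t1"), f)
  m <- read_presence_matrix(f)
  expect_identical(compute_diversity(m), c(c1 = 1L, c2 = 2L))
  expect_true(m$rare["sp1", "c2"])

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("species\tc1", "sp1\t2"), bad)
  expect_error(read_presence_matrix(bad), "line")
})

test_that("survey aggregation averages per country/species, excluding HIV", {
  sv <- data.frame(country = c("c1", "c1", "c1", "c2"),
                   species = c("Ascaris", "Ascaris", "Ascaris", "Ascaris"),
                   prevalence = c(0.2, 0.4, 0.9, 0.5),
                   hiv = c(FALSE, FALSE, TRUE, TRUE))
  agg <- aggregate_prevalence(sv)
  expect_equal(nrow(agg), 1)  # (c2, Ascaris) has only an HIV survey
  expect_equal(agg$prevalence, 0.3)
  expect_equal(agg$n_surveys, 2L)

  # survey order never matters; adding an HIV survey never changes output
  set.seed(12)
  sv2 <- sv[sample(nrow(sv)), ]
  expect_equal(aggregate_prevalence(sv2), aggregate_prevalence(sv))
  extra <- rbind(sv, data.frame(country = "c1", species = "Ascaris",
                                prevalence = 0.99, hiv = TRUE))
  expect_equal(aggregate_prevalence(extra), aggregate_prevalence(sv))

  expect_error(aggregate_prevalence(transform(sv, prevalence = prevalence * 2)),
               "\\[0, 1\\]")
  only_hiv <- data.frame(country = "c1", species = "A", prevalence = 0.5,
                         hiv = TRUE)
  expect_equal(nrow(aggregate_prevalence(only_hiv)), 0)
})

test_that("group prevalence combines member species and names unmapped ones", {
  prev <- data.frame(country = c("c1", "c1", "c2"),
                     species = c("sp1", "sp2", "sp1"),
                     prevalence = c(0.2, 0.4, 0.2))
  gm <- c(sp1 = "G", sp2 = "G")
  g <- group_prevalence(prev, gm)
  expect_equal(g$value[g$country == "c1"], 0.3)
  expect_equal(g$value[g$country == "c2"], 0.2)  # only one member has data
  expect_equal(nrow(g), 2)                        # no row without data
  expect_error(group_prevalence(prev, c(sp1 = "G")), "sp2")
  # configurable combiner
  gmax <- group_prevalence(prev, gm, combiner = max)
  expect_equal(gmax$value[gmax$country == "c1"], 0.4)
})

test_that("environmental correlation runs on the shared-country intersection", {
  x <- setNames(1:12, paste0("c", 1:12))
  expect_equal(correlate_env(x, x)$tau, 1)
  expect_equal(correlate_env(x, setNames(12:1, names(x)))$tau, -1)
  # small-n fallback: exact p with a warning
  x4 <- setNames(c(1, 2, 3, 4), paste0("c", 1:4))
  y4 <- setNames(c(2, 1, 4, 3), paste0("c", 1:4))
  expect_warning(r <- correlate_env(x4, y4), "exact")
  expect_equal(r$tau, 1 / 3)
  expect_equal(r$method, "exact")
  expect_error(correlate_env(x4[1:2], y4), "3 shared")
  # extra countries in one vector are ignored
  expect_equal(correlate_env(c(x, zz = 99), x)$tau, 1)
})

test_that("broadcast and climate averaging are mutually consistent", {
  pops <- data.frame(population = c("p1", "p2", "p3"),
                     country = c("c1", "c1", "c2"))
  env <- c(c1 = 5, c2 = 3)
  b <- broadcast_to_populations(env, pops)
  expect_identical(b, c(p1 = 5, p2 = 5, p3 = 3))
  expect_error(broadcast_to_populations(env[1], pops), "c2")

  clim <- c(p1 = 10, p2 = 14, p3 = 7)
  expect_identical(average_climate(clim, pops), c(c1 = 12, c2 = 7))

  # broadcast then average over a one-population-per-country table: identity
  pops1 <- data.frame(population = c("pA", "pB"), country = c("c1", "c2"))
  expect_identical(average_climate(broadcast_to_populations(env, pops1),
                                   pops1), env)
})

test_that("the packaged curation fixture behaves like the study matrix", {
  f <- system.file("extdata", "helminth_presence_synthetic.tsv",
                   package = "helminthscan")
  m <- read_presence_matrix(f)
  expect_length(m$countries, 21)
  div <- compute_diversity(m)
  expect_true(all(div > 0))
  expect_true(all(compute_diversity(m, common_only = TRUE) <= div))
})
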