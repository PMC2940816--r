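#' Construct a pathogen presence/absence matrix
#'
#' The matrix records, for each pathogen species (or genus) and country,
#' whether the pathogen is transmitted there, plus a rarity flag: `rare` is
#' TRUE where the infection is reported as rare in humans or carries no
#' prevalence estimate. Rarity can only be flagged where the species is
#' present.
#'
#' @param present logical matrix, species x countries, dimnames required.
#' @param rare logical matrix of the same shape; default all FALSE.
#' @return an object of class `"presence_matrix"`.
#' @export
presence_matrix <- function(present, rare = NULL) {
  if (!is.matrix(present) || is.null(rownames(present)) ||
      is.null(colnames(present)))
    stop("present must be a matrix with species rownames and country colnames")
  if (nrow(present) == 0 || ncol(present) == 0)
    stop("presence matrix has no species or no countries")
  if (anyDuplicated(rownames(present)))
    stop("duplicate species labels")
  if (anyDuplicated(colnames(present)))
    stop("duplicate country labels")
  mode(present) <- "logical"
  if (is.null(rare)) {
    rare <- array(FALSE, dim(present), dimnames(present))
  } else {
    if (!identical(dim(rare), dim(present)))
      stop("rare must have the same shape as present")
    mode(rare) <- "logical"
    dimnames(rare) <- dimnames(present)
  }
  if (any(rare & !present))
    stop("rare flagged where species is absent")
  structure(list(present = present, rare = rare,
                 species = rownames(present), countries = colnames(present)),
            class = "presence_matrix")
}

#' Read a presence/absence matrix from TSV
#'
#' Expected layout: first column `species`, one further column per country,
#' cells in `{0, 1, R}` where `R` means present but rare (rare in humans, or
#' no prevalence estimate available). Labels are trimmed; matching elsewhere
#' is exact-string.
#'
#' @param path TSV file path.
#' @return a `"presence_matrix"` object.
#' @export
read_presence_matrix <- function(path) {
  if (!file.exists(path)) stop("presence matrix file not found: ", path)
  d <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(d) < 2 || names(d)[1] != "species")
    stop("malformed presence matrix ", path,
         ": first column must be 'species'")
  cells <- as.matrix(d[, -1, drop = FALSE])
  cells <- trimws(cells)
  ok <- cells %in% c("0", "1", "R")
  dim(ok) <- dim(cells)
  bad <- which(!ok, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("malformed presence matrix ", path, ": line ", bad[1, 1] + 1L,
         ", column '", colnames(cells)[bad[1, 2]],
         "': cells must be 0, 1 or R")
  rownames(cells) <- trimws(d$species)
  colnames(cells) <- trimws(colnames(cells))
  presence_matrix(cells != "0", cells == "R")
}

#' Helminth diversity per country
#'
#' Counts, for each country, the number of distinct species/genera
#' transmitted there — every species present is counted irrespective of its
#' prevalence. With `common_only = TRUE` the count is restricted to species
#' that are common in at least one country: species flagged rare everywhere
#' they occur are removed globally before counting.
#'
#' @param presence a `"presence_matrix"`.
#' @param common_only drop species that are nowhere common.
#' @return named integer vector, country -> species count.
#' @examples
#' m <- presence_matrix(matrix(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), 3, 2,
#'   dimnames = list(c("sp1", "sp2", "sp3"), c("c1", "c2"))))
#' compute_diversity(m)  # c1: 2, c2: 1
#' @export
compute_diversity <- function(presence, common_only = FALSE) {
  stopifnot(inherits(presence, "presence_matrix"))
  pres <- presence$present
  if (common_only) {
    # common in >= 1 country: present somewhere with rare = FALSE
    common <- rowSums(pres & !presence$rare) > 0
    pres <- pres[common, , drop = FALSE]
  }
  counts <- colSums(pres)
  storage.mode(counts) <- "integer"
  counts
}

#' Read prevalence survey records
#'
#' TSV with header `country species prevalence hiv`; `prevalence` is a
#' proportion in [0, 1] and `hiv` in `{0, 1}` flags surveys carried out on
#' HIV-seropositive individuals.
#'
#' @param path TSV file path.
#' @return data.frame with columns country, species, prevalence (numeric),
#'   hiv (logical).
#' @export
read_surveys <- function(path) {
  if (!file.exists(path)) stop("survey file not found: ", path)
  d <- utils::read.delim(path, check.names = FALSE)
  need <- c("country", "species", "prevalence", "hiv")
  if (!all(need %in% names(d)))
    stop("malformed survey file ", path, ": need columns ",
         paste(need, collapse = ", "))
  data.frame(country = trimws(as.character(d$country)),
             species = trimws(as.character(d$species)),
             prevalence = as.numeric(d$prevalence),
             hiv = as.logical(as.integer(d$hiv)),
             stringsAsFactors = FALSE)
}

#' Mean prevalence per country and species
#'
#' Surveys on HIV-seropositive individuals are excluded first (HIV modulates
#' susceptibility to helminth infection); the remaining surveys are averaged
#' per (country, species). Pairs with no usable survey are absent from the
#' output — countries without survey data do not enter downstream
#' correlations for that species.
#'
#' @param surveys data.frame as returned by [read_surveys()].
#' @return data.frame with columns country, species, prevalence (the mean),
#'   n_surveys.
#' @export
aggregate_prevalence <- function(surveys) {
  if (nrow(surveys) == 0) stop("no survey records")
  if (anyNA(surveys$prevalence) ||
      any(surveys$prevalence < 0 | surveys$prevalence > 1))
    stop("prevalence values must lie in [0, 1]")
  keep <- surveys[!surveys$hiv, , drop = FALSE]
  if (nrow(keep) == 0)
    return(data.frame(country = character(), species = character(),
                      prevalence = numeric(), n_surveys = integer(),
                      stringsAsFactors = FALSE))
  key <- interaction(keep$country, keep$species, drop = TRUE, sep = "\r")
  mean_prev <- tapply(keep$prevalence, key, mean)
  n <- tapply(keep$prevalence, key, length)
  parts <- do.call(rbind, strsplit(names(mean_prev), "\r", fixed = TRUE))
  out <- data.frame(country = parts[, 1], species = parts[, 2],
                    prevalence = as.numeric(mean_prev),
                    n_surveys = as.integer(n), stringsAsFactors = FALSE)
  out[order(out$country, out$species), , drop = FALSE]
}

#' Combine species prevalences into parasite-group values
#'
#' Species are grouped into major parasite classes (e.g. soil-transmitted
#' nematodes, filarial nematodes, schistosomes, food-borne trematodes) and a
#' per-country group value is computed from the member species with data.
#' The default combiner is the unweighted mean — symmetric and on the
#' prevalence scale; any summary function can be supplied.
#'
#' @param prev data.frame from [aggregate_prevalence()].
#' @param group_map named character vector, species -> group label; every
#'   species appearing in `prev` must be mapped.
#' @param combiner function reducing member-species prevalences to one value.
#' @return data.frame with columns country, group, value, n_species.
#' @export
group_prevalence <- function(prev, group_map, combiner = mean) {
  missing_sp <- setdiff(unique(prev$species), names(group_map))
  if (length(missing_sp) > 0)
    stop("species without a group: ", paste(missing_sp, collapse = ", "))
  grp <- unname(group_map[prev$species])
  key <- interaction(prev$country, grp, drop = TRUE, sep = "\r")
  val <- tapply(prev$prevalence, key, combiner)
  n <- tapply(prev$prevalence, key, length)
  parts <- do.call(rbind, strsplit(names(val), "\r", fixed = TRUE))
  out <- data.frame(country = parts[, 1], group = parts[, 2],
                    value = as.numeric(val), n_species = as.integer(n),
                    stringsAsFactors = FALSE)
  out[order(out$country, out$group), , drop = FALSE]
}

#' Correlate two country-level environmental vectors
#'
#' Kendall tau-b over the countries present in both vectors. With 11 or
#' more shared countries the normal approximation is used (the sampling
#' distribution of tau converges to normal for n > 10 even with ties);
#' below that a warning is issued and the exact permutation p is used
#' instead. Fewer than 3 shared countries is an error.
#'
#' @param x,y named numeric vectors (country -> value).
#' @return a `"kendall_cor"` object over the shared countries.
#' @export
correlate_env <- function(x, y) {
  shared <- intersect(names(x), names(y))
  if (length(shared) < 3)
    stop("need at least 3 shared countries, got ", length(shared))
  if (length(shared) < 11) {
    warning("only ", length(shared), " shared countries; normal ",
            "approximation unreliable for n <= 10, using exact permutation p")
    return(kendall_cor(x[shared], y[shared], p_method = "exact"))
  }
  kendall_cor(x[shared], y[shared], p_method = "normal")
}

#' Read a population table
#'
#' TSV with header `population country lat lon` (lat/lon optional, may be
#' empty). Each population maps to exactly one country; populations already
#' merged by the data producer (e.g. several sampling sites treated as one
#' population) arrive as single rows.
#'
#' @param path TSV file path.
#' @return data.frame with columns population, country, lat, lon.
#' @export
read_populations <- function(path) {
  if (!file.exists(path)) stop("population table not found: ", path)
  d <- utils::read.delim(path, check.names = FALSE)
  if (!all(c("population", "country") %in% names(d)))
    stop("malformed population table ", path,
         ": need columns population, country")
  out <- data.frame(population = trimws(as.character(d$population)),
                    country = trimws(as.character(d$country)),
                    lat = if ("lat" %in% names(d)) as.numeric(d$lat) else NA_real_,
                    lon = if ("lon" %in% names(d)) as.numeric(d$lon) else NA_real_,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$population))
    stop("duplicate population labels in ", path)
  out
}

#' Read a country-level environmental vector
#'
#' TSV with header `country value`.
#'
#' @param path TSV file path.
#' @return named numeric vector.
#' @export
read_env <- function(path) {
  if (!file.exists(path)) stop("environment file not found: ", path)
  d <- utils::read.delim(path, check.names = FALSE)
  if (!all(c("country", "value") %in% names(d)))
    stop("malformed environment file ", path, ": need columns country, value")
  stats::setNames(as.numeric(d$value), trimws(as.character(d$country)))
}

#' Broadcast a country-level variable to populations
#'
#' Environmental variables (diversity, climate) are defined per country;
#' the scan works per population. Every population receives its country's
#' value, so populations sharing a country share one value — this preserves
#' the tie structure that the tie-corrected Kendall statistic accounts for.
#'
#' @param env named numeric vector, country -> value.
#' @param pops population table (see [read_populations()]).
#' @return named numeric vector, population -> value.
#' @export
broadcast_to_populations <- function(env, pops) {
  unknown <- setdiff(pops$country, names(env))
  if (length(unknown) > 0)
    stop("populations mapped to countries absent from the environment ",
         "vector: ", paste(unknown, collapse = ", "))
  stats::setNames(unname(env[pops$country]), pops$population)
}

#' Average per-population values up to countries
#'
#' Climate variables retrieved per population (at sampling coordinates) are
#' averaged, unweighted, over the populations located in the same country,
#' yielding a country-level vector comparable to the diversity variable.
#'
#' @param pop_values named numeric vector, population -> value.
#' @param pops population table.
#' @return named numeric vector, country -> mean value.
#' @export
average_climate <- function(pop_values, pops) {
  unknown <- setdiff(names(pop_values), pops$population)
  if (length(unknown) > 0)
    stop("values for populations absent from the table: ",
         paste(unknown, collapse = ", "))
  ctry <- pops$country[match(names(pop_values), pops$population)]
  m <- tapply(pop_values, ctry, mean)
  stats::setNames(as.numeric(m), names(m))
}
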