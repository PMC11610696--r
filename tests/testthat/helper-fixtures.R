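# Hand-built communities and trait tables used across the tests.
# Trait scores are spread over the five 0-3 trait columns so that the
# per-species score (their sum) hits the values the closed forms need.

score_split <- function(total) {
  stopifnot(total >= 0, total <= 15)
  out <- integer(5)
  for (i in 1:5) {
    out[i] <- as.integer(min(3, total))
    total <- total - out[i]
  }
  out
}

make_traits <- function(taxon, group = NA, besito = NA, longevity = NA,
                        score = NA, protected = FALSE, mass = NA) {
  n <- length(taxon)
  rec <- function(x) rep(x, length.out = n)
  sc <- t(vapply(rec(score), function(s) {
    if (is.na(s)) rep(NA_integer_, 5) else score_split(s)
  }, integer(5)))
  tibble::tibble(
    taxon = taxon,
    ecological_group = rec(group),
    besito_group = rec(besito),
    longevity_years = rec(longevity),
    score_mobility = sc[, 1], score_fragility = sc[, 2],
    score_position = sc[, 3], score_size = sc[, 4], score_feeding = sc[, 5],
    protected = rec(protected),
    mean_individual_mass = rec(mass)
  )
}

make_community <- function(station_id, taxon, abundance, biomass = NA_real_,
                           gradient_id = "g1") {
  out <- tibble::tibble(station_id = station_id, taxon = taxon,
                        abundance = abundance,
                        biomass = rep(biomass, length.out = length(taxon)))
  attr(out, "gradient_id") <- gradient_id
  out
}

# pull one indicator value out of a tidy indicator table
ival <- function(ind, id, station = NULL) {
  x <- ind[ind$indicator == id, ]
  if (!is.null(station)) x <- x[x$station_id == station, ]
  x$value
}

ireason <- function(ind, id, station = NULL) {
  x <- ind[ind$indicator == id, ]
  if (!is.null(station)) x <- x[x$station_id == station, ]
  x$missing_reason
}

# small, fast synthetic study reused by pipeline-level tests
tiny_study <- function(seed = 42, n_trawl = 4) {
  simulate_study(seed = seed, n_trawl = n_trawl, n_species = 25)
}
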