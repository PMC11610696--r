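## Synthetic pressure-gradient communities.
##
## A shared regional species pool carries correlated life-history traits;
## along a gradient the expected abundance of species i at pressure P is
##
##   lambda_i(P) = lambda_i0 * exp(-beta * s_i * P + gamma * o_i * P)
##
## with s_i the species' sensitivity (increasing with longevity/fragility)
## and o_i its opportunism (high for short-lived group-V taxa). Counts are
## drawn per replicate from a negative binomial (overdispersed field
## counts) or Poisson observation model; biomass is counts times the
## species' mean individual mass.

#' Generate a species pool with correlated traits
#'
#' @param n_species Number of species (>= 2).
#' @param seed Integer seed; the same seed reproduces the pool exactly.
#' @param abundance_meanlog,abundance_sdlog Log-normal parameters of the
#'   baseline mean abundance across species.
#' @param abundance_longevity_slope Log-log slope of baseline abundance on
#'   longevity; the negative default makes short-lived opportunists
#'   numerically dominant, as in field communities.
#' @param mass_longevity_slope Log-log slope of mean individual mass on
#'   longevity (long-lived taxa are large-bodied and carry most biomass).
#' @param rho_longevity_sensitivity Gaussian-copula correlation between
#'   longevity and trawl sensitivity (realized rank correlation is close
#'   to this value).
#' @param rho_axes Gaussian-copula correlation between the trawl-sensitivity
#'   axis (longevity, BESITO, TDI trait scores) and the organic-enrichment
#'   sensitivity axis that sets the AMBI ecological groups; weak by
#'   default, since the group classifications target water-quality
#'   disturbance rather than physical trawl impact.
#' @param prop_protected Expected fraction of species flagged as protected
#'   (drawn among the longest-lived quartile).
#' @param trait_na_rate Fraction of species whose BESITO group and TDI
#'   trait scores are withheld, emulating partial trait coverage.
#' @return A tibble with one row per species: trait-table columns plus the
#'   generator's `baseline_abundance`, `sensitivity` and `opportunism`.
#' @export
make_species_pool <- function(n_species = 50, seed = 1,
                              abundance_meanlog = log(20),
                              abundance_sdlog = 0.9,
                              abundance_longevity_slope = -0.6,
                              mass_longevity_slope = 1.5,
                              rho_longevity_sensitivity = 0.8,
                              rho_axes = 0.3,
                              prop_protected = 0.05,
                              trait_na_rate = 0) {
  stopifnot(n_species >= 2,
            abs(rho_longevity_sensitivity) <= 1, abs(rho_axes) <= 1,
            trait_na_rate >= 0, trait_na_rate < 1)
  set.seed(seed)
  rho <- rho_longevity_sensitivity
  z1 <- rnorm(n_species)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n_species)
  ze <- rho_axes * z2 + sqrt(1 - rho_axes^2) * rnorm(n_species)
  longevity <- stats::qlnorm(stats::pnorm(z1), meanlog = log(4), sdlog = 0.8)
  s <- stats::pnorm(z2)         # trawl sensitivity in (0, 1)
  e <- stats::pnorm(ze)         # enrichment sensitivity in (0, 1)
  ## opportunists: short-lived, low-sensitivity group IV-V taxa;
  ## s and o are never both above 0.5 by construction
  o <- (1 - s) * (1 - e) * rbeta(n_species, 8, 2)
  grp <- cut(e, breaks = c(0, .2, .4, .6, .8, 1),
             labels = c("V", "IV", "III", "II", "I"), include.lowest = TRUE)
  besito <- as.integer(cut(s, breaks = c(0, .2, .4, .6, .8, 1),
                           labels = FALSE, include.lowest = TRUE))
  score_p <- pmin(pmax(s, 0.02), 0.98)
  scores <- purrr::map(1:5, function(k) {
    rbinom(n_species, 3, stats::plogis(stats::qlogis(score_p) +
                                         rnorm(n_species, 0, 0.4)))
  })
  mass <- exp(log(0.05) + mass_longevity_slope * log(longevity) +
                rnorm(n_species, 0, 0.3))
  protected <- rep(FALSE, n_species)
  long_q <- longevity >= quantile(longevity, 0.75)
  protected[long_q] <- runif(sum(long_q)) < 4 * prop_protected

  pool <- tibble::tibble(
    taxon = sprintf("sp%03d", seq_len(n_species)),
    ecological_group = as.character(grp),
    besito_group = besito,
    longevity_years = longevity,
    score_mobility = scores[[1]],
    score_fragility = scores[[2]],
    score_position = scores[[3]],
    score_size = scores[[4]],
    score_feeding = scores[[5]],
    protected = protected,
    mean_individual_mass = mass,
    baseline_abundance = rlnorm(
      n_species,
      abundance_meanlog + abundance_longevity_slope * log(longevity / 4),
      abundance_sdlog),
    sensitivity = s,
    opportunism = o
  )
  if (trait_na_rate > 0) {
    hide <- runif(n_species) < trait_na_rate
    pool$besito_group[hide] <- NA_integer_
    for (col in .score_cols) pool[[col]][hide] <- NA_integer_
  }
  pool
}

#' Gradient specification
#'
#' @param n_stations Stations along the gradient (8-52 in the emulated
#'   field designs).
#' @param pressure_max Maximum pressure value (SAR per year for trawling).
#' @param replicates Replicate samples per station (summed downstream).
#' @param gear `"trawl"` or `"grab_core"`.
#' @param beta Depletion rate per unit sensitivity and pressure; the
#'   default halves a fully exposed sensitive taxon's (s ~ 0.9) expected
#'   abundance across a SAR span of 6 per year.
#' @param gamma Opportunist boost rate.
#' @param dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); ignored for the Poisson model.
#' @param obs_model `"negative_binomial"` or `"poisson"`.
#' @param prop_present Fraction of the pool occurring on this gradient.
#' @param occupancy Range of the per-station species occupancy
#'   probability: each station draws a probability in this range and each
#'   species is independently present or absent at it. This is the
#'   station-level habitat heterogeneity that drives richness and the
#'   other diversity indices jointly, independent of pressure; random
#'   thinning leaves composition shares (and hence the biotic and
#'   trait-score indices) unbiased. Set to `c(1, 1)` for closed-form
#'   expectation checks.
#' @param site_sd Log-normal SD of a station-level abundance multiplier
#'   (overall habitat quality / sampling efficiency), acting on all
#'   species alike.
#' @return A list with class `gradient_spec`.
#' @export
gradient_spec <- function(n_stations = 12, pressure_max = 6, replicates = 1,
                          gear = c("grab_core", "trawl"),
                          beta = log(2) / (0.9 * 6), gamma = 0.25,
                          dispersion = 1,
                          obs_model = c("negative_binomial", "poisson"),
                          prop_present = 0.8,
                          occupancy = c(0.55, 0.95),
                          site_sd = 0.3) {
  gear <- match.arg(gear)
  obs_model <- match.arg(obs_model)
  stopifnot(n_stations >= 2, pressure_max >= 0, replicates >= 1,
            beta >= 0, gamma >= 0, dispersion > 0,
            prop_present > 0, prop_present <= 1,
            length(occupancy) == 2, all(occupancy > 0), all(occupancy <= 1),
            occupancy[1] <= occupancy[2], site_sd >= 0)
  structure(as.list(environment()), class = "gradient_spec")
}

.draw_counts <- function(lambda, spec) {
  if (spec$obs_model == "poisson") {
    rpois(length(lambda), lambda)
  } else {
    rnbinom(length(lambda), mu = lambda, size = 1 / spec$dispersion)
  }
}

#' Expected abundance along the gradient
#'
#' Closed-form expectation `lambda_i(P)` of the observation model, exposed
#' so tests can compare Monte-Carlo means against it.
#'
#' @param pool Species pool.
#' @param spec Gradient specification.
#' @param pressure Pressure value(s).
#' @return Matrix (species x pressure) of expected abundances.
#' @export
expected_abundance <- function(pool, spec, pressure) {
  outer(seq_len(nrow(pool)), pressure, function(i, P) {
    pool$baseline_abundance[i] *
      exp((-spec$beta * pool$sensitivity[i] + spec$gamma * pool$opportunism[i]) * P)
  })
}

#' Simulate a bottom-trawl pressure gradient
#'
#' @param pool Species pool from [make_species_pool()].
#' @param spec Gradient specification from [gradient_spec()].
#' @param seed Integer seed.
#' @param gradient_id Identifier stamped on all outputs.
#' @return A list (samples, stations, traits): sample records (zero counts
#'   dropped), station metadata with `pressure_scale = "sar"`, and the
#'   trait-table view of the pool.
#' @export
simulate_gradient <- function(pool, spec, seed = 1, gradient_id = "g1") {
  set.seed(seed)
  pressures <- spec$pressure_max * (seq_len(spec$n_stations) - 1)^1.3 /
    max(1, (spec$n_stations - 1)^1.3)
  present <- runif(nrow(pool)) < spec$prop_present
  sub <- pool[present, ]
  samples <- .draw_gradient_samples(sub, spec, pressures, gradient_id,
                                    mult = exp((-spec$beta * sub$sensitivity +
                                                  spec$gamma * sub$opportunism)))
  stations <- tibble::tibble(
    gradient_id = gradient_id,
    station_id = sprintf("%s_st%02d", gradient_id, seq_len(spec$n_stations)),
    pressure_value = pressures,
    pressure_type = "trawling",
    pressure_scale = "sar",
    gear = spec$gear,
    depth_m = round(runif(spec$n_stations, 20, 90), 1),
    sediment = "mud",
    salinity = NA_real_,
    worsening = "increasing"
  )
  list(samples = samples, stations = stations, traits = pool_traits(pool))
}

## shared sampling loop: `mult` is the per-species log-linear response
## multiplier per unit pressure, i.e. lambda = lambda0 * mult^P
.draw_gradient_samples <- function(sub, spec, pressures, gradient_id, mult) {
  recs <- purrr::map(seq_along(pressures), function(j) {
    q_j <- runif(1, spec$occupancy[1], spec$occupancy[2])
    occupied <- runif(nrow(sub)) < q_j
    h_j <- if (spec$site_sd > 0) rlnorm(1, 0, spec$site_sd) else 1
    lambda <- sub$baseline_abundance * mult^pressures[j] * h_j * occupied
    purrr::map(seq_len(spec$replicates), function(r) {
      counts <- .draw_counts(lambda, spec)
      keep <- counts > 0
      tibble::tibble(
        gradient_id = gradient_id,
        station_id = sprintf("%s_st%02d", gradient_id, j),
        replicate_id = r,
        taxon = sub$taxon[keep],
        abundance = as.numeric(counts[keep]),
        biomass = counts[keep] * sub$mean_individual_mass[keep]
      )
    }) |> purrr::list_rbind()
  })
  purrr::list_rbind(recs)
}

#' Simulate a non-trawl pressure gradient
#'
#' Depletion is keyed to the AMBI ecological groups rather than to trawl
#' traits: groups I-II decline with worsening pressure, groups IV-V are
#' boosted (organic-enrichment style response). The pressure is recorded
#' on its native scale; for oxygen depletion low values are the worst end,
#' carried as `worsening = "decreasing"` in the station metadata.
#'
#' @inheritParams simulate_gradient
#' @param pressure_type `"eutrophication"`, `"oxygen_depletion"` or
#'   `"pollution"`.
#' @return As [simulate_gradient()].
#' @export
simulate_nontrawl_gradient <- function(pool, spec, pressure_type, seed = 1,
                                       gradient_id = "ng1") {
  stopifnot(pressure_type %in% c("eutrophication", "oxygen_depletion",
                                 "pollution"))
  set.seed(seed)
  n <- spec$n_stations
  grid <- seq(0, 1, length.out = n)          # worsening intensity 0..1
  native <- switch(pressure_type,
    eutrophication = list(value = 0.05 + 0.55 * grid, scale = "concentration",
                          worsening = "increasing"),
    oxygen_depletion = list(value = 9 - 8.5 * grid, scale = "concentration",
                            worsening = "decreasing"),
    pollution = list(value = 10 * grid, scale = "index",
                     worsening = "increasing")
  )
  sens <- c(I = 1, II = 0.75, III = 0.3, IV = 0.1, V = 0)
  opp <- c(I = 0, II = 0, III = 0.1, IV = 0.6, V = 1)
  present <- runif(nrow(pool)) < spec$prop_present
  sub <- pool[present, ]
  g <- sub$ecological_group
  g[is.na(g)] <- "III"
  ## reuse the trawl machinery with pseudo-pressure = intensity * pressure_max
  mult <- exp(-spec$beta * sens[g] + spec$gamma * opp[g])
  samples <- .draw_gradient_samples(sub, spec, grid * spec$pressure_max,
                                    gradient_id, mult)
  ## station ids were stamped by grid position; record the native pressure
  stations <- tibble::tibble(
    gradient_id = gradient_id,
    station_id = sprintf("%s_st%02d", gradient_id, seq_len(n)),
    pressure_value = native$value,
    pressure_type = pressure_type,
    pressure_scale = native$scale,
    gear = spec$gear,
    depth_m = round(runif(n, 20, 90), 1),
    sediment = "mud",
    salinity = NA_real_,
    worsening = native$worsening
  )
  list(samples = samples, stations = stations, traits = pool_traits(pool))
}

#' Trait-table view of a species pool
#'
#' Drops the generator-internal columns so the result matches the trait
#' table schema consumed by [compute_indicators()].
#'
#' @param pool Species pool.
#' @return A trait tibble.
#' @export
pool_traits <- function(pool) {
  tibble::as_tibble(pool[, .trait_cols])
}

#' Simulate a multi-gradient indicator study
#'
#' Builds a miniature study with the shape of the field designs the
#' analyses expect: `n_trawl` bottom-trawl gradients (a mix of grab/core
#' and trawl gears, 8-20 stations, 1-5 replicates) plus one gradient each
#' of eutrophication, oxygen depletion and pollution, all drawn from one
#' shared species pool.
#'
#' @param seed Root seed; all randomness derives from it.
#' @param n_trawl Number of trawl gradients.
#' @param n_species Species-pool size.
#' @param beta,gamma Depletion and opportunist-boost rates passed to every
#'   gradient.
#' @param include_nontrawl Include the three non-trawl gradients?
#' @return A list (samples, stations, traits, pool).
#' @export
simulate_study <- function(seed = 1, n_trawl = 14, n_species = 120,
                           beta = log(2) / (0.9 * 6), gamma = 0.25,
                           include_nontrawl = TRUE) {
  set.seed(seed)
  pool <- make_species_pool(n_species, seed = seed + 1000L)
  n_st <- sample(8:20, n_trawl, replace = TRUE)
  gears <- rep(c("grab_core", "trawl"), length.out = n_trawl)
  reps <- ifelse(gears == "trawl", 1L, sample(1:5, n_trawl, replace = TRUE))
  sims <- purrr::map(seq_len(n_trawl), function(i) {
    spec <- gradient_spec(n_stations = n_st[i], replicates = reps[i],
                          gear = gears[i], beta = beta, gamma = gamma)
    simulate_gradient(pool, spec, seed = seed + i,
                      gradient_id = sprintf("tg%02d", i))
  })
  if (include_nontrawl) {
    nt_types <- c("eutrophication", "oxygen_depletion", "pollution")
    sims <- c(sims, purrr::map(seq_along(nt_types), function(i) {
      spec <- gradient_spec(n_stations = 12, replicates = 2,
                            gear = "grab_core", beta = beta, gamma = gamma)
      simulate_nontrawl_gradient(pool, spec, nt_types[i],
                                 seed = seed + 100L + i,
                                 gradient_id = sprintf("ng%02d", i))
    }))
  }
  list(
    samples = purrr::list_rbind(purrr::map(sims, "samples")),
    stations = purrr::list_rbind(purrr::map(sims, "stations")),
    traits = pool_traits(pool),
    pool = pool
  )
}

#' Write a synthetic study to CSV fixtures
#'
#' Emits the exact schemas consumed by [read_samples()], [read_stations()]
#' and [read_traits()].
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_fixtures <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("samples.csv", "stations.csv", "traits.csv"))
  readr::write_csv(study$samples, paths[1])
  readr::write_csv(study$stations, paths[2])
  readr::write_csv(study$traits, paths[3])
  invisible(paths)
}
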