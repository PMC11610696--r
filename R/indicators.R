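## The 18 benthic state indicators, computed per station from an
## aggregated community table and a taxon trait table.
##
## Families:
##   whole community   : B (biomass), A (abundance)
##   diversity         : R, DM (relative Margalef), H (Shannon), SI
##                       (Simpson dominance), IS (inverse Simpson)
##   biotic indices    : AMBI, MAMBI, BENTIX, DKI (ecological groups I-V)
##   trait-based       : TDI, mTDI, mT, Lm (TDI trait scores / longevity)
##   sensitive fraction: pTDI, SoS, Lf
##
## Missing values always carry a machine-readable reason.

.score_cols <- c("score_mobility", "score_fragility", "score_position",
                 "score_size", "score_feeding")

#' Reference conditions for a gradient
#'
#' Reference (good-state) values used to rescale `DM` and to anchor the
#' `MAMBI` and `DKI` indices: the best observed richness, Shannon and
#' Margalef diversity, and the lowest AMBI, among low-pressure stations
#' (SAR below the configured threshold; all stations when none qualify or
#' when pressure is on a non-SAR scale, in which case the least-pressured
#' third is used).
#'
#' @param community Output of [aggregate_replicates()].
#' @param stations Station metadata for this gradient (optional: without
#'   it, all stations are treated as the reference set).
#' @param traits Trait table (needed for the AMBI anchor).
#' @param config Indicator configuration.
#' @return A list (gradient_id, r_ref, h_ref, d_ref, ambi_good, n_reference).
#' @export
reference_conditions <- function(community, stations = NULL, traits = NULL,
                                 config = indicator_config()) {
  st_ids <- unique(community$station_id)
  ref_ids <- st_ids
  if (!is.null(stations)) {
    stations <- stations[stations$station_id %in% st_ids, ]
    p <- stations$pressure_value
    if (all(stations$pressure_scale %in% "sar") && any(!is.na(p))) {
      low <- stations$station_id[!is.na(p) & p < config$low_sar_threshold]
      if (length(low) >= 1) ref_ids <- low
    } else if (any(!is.na(p))) {
      worst_first <- !is.na(stations$worsening) &
        stations$worsening[1] == "decreasing"
      ord <- order(p, decreasing = worst_first)
      n_ref <- min(length(p), max(2, ceiling(length(p) / 3)))
      ref_ids <- stations$station_id[ord][seq_len(n_ref)]
    }
  }
  base <- .station_base(community[community$station_id %in% ref_ids, ],
                        traits, config)
  list(
    gradient_id = attr(community, "gradient_id") %||% NA,
    r_ref = max(base$R, 1, na.rm = TRUE),
    h_ref = max(base$H, na.rm = TRUE),
    d_ref = suppressWarnings(max(base$DM_raw, na.rm = TRUE)),
    ambi_good = if (all(is.na(base$AMBI))) 0 else min(base$AMBI, na.rm = TRUE),
    n_reference = length(ref_ids)
  )
}

## R, H and raw Margalef + AMBI per station, used for reference conditions
.station_base <- function(community, traits, config) {
  split(community, community$station_id) |>
    purrr::map(function(d) {
      ab <- d$abundance
      A <- sum(ab, na.rm = TRUE)
      R <- sum(ab > 0, na.rm = TRUE)
      p <- ab[which(ab > 0)] / A
      H <- if (A > 0) -sum(p * log(p, base = config$shannon_log_base)) else NA
      DM <- if (A > 1 && R >= 1) (R - 1) / log(A) else NA
      AMBI <- if (is.null(traits)) NA else
        .ambi_value(d, traits, config)$value
      tibble::tibble(R = R, H = H, DM_raw = DM, AMBI = AMBI)
    }) |>
    purrr::list_rbind()
}

#' Compute the 18 benthic indicators for one gradient
#'
#' @param community Output of [aggregate_replicates()] for one gradient.
#' @param traits Trait table covering the community's taxa (taxa without a
#'   row simply count as unscored).
#' @param refs Reference conditions from [reference_conditions()]; when
#'   `NULL` the reference-dependent indices (`DM`, `MAMBI`, `DKI`) are
#'   missing with reason `"no_reference"`.
#' @param config Indicator configuration.
#' @param pressure_type Pressure acting on this gradient; `SoS` switches
#'   its sensitivity classification on it (BESITO groups for trawling,
#'   AMBI ecological groups otherwise).
#' @return A tidy tibble (station_id, indicator, value, missing_reason)
#'   with one row per station and indicator; `indicator` is a factor in
#'   canonical order. Values are raw (unreversed): see
#'   [reverse_orientation()].
#' @export
compute_indicators <- function(community, traits, refs = NULL,
                               config = indicator_config(),
                               pressure_type = "trawling") {
  traits <- tibble::as_tibble(traits)
  out <- split(community, community$station_id) |>
    purrr::imap(function(d, sid) {
      v <- .one_station(d, traits, refs, config, pressure_type)
      v$station_id <- sid
      v
    }) |>
    purrr::list_rbind()
  out$indicator <- factor(out$indicator, levels = .indicator_levels)
  gid <- attr(community, "gradient_id")
  if (!is.null(gid)) out$gradient_id <- gid
  cols <- intersect(c("gradient_id", "station_id", "indicator", "value",
                      "missing_reason"), names(out))
  dplyr::arrange(out[, cols], .data$station_id, .data$indicator)
}

.res <- function(id, value, reason = NA_character_) {
  if (is.null(value) || length(value) == 0 || is.na(value)) {
    tibble::tibble(indicator = id, value = NA_real_,
                   missing_reason = if (is.na(reason)) "degenerate" else reason)
  } else {
    tibble::tibble(indicator = id, value = as.numeric(value),
                   missing_reason = NA_character_)
  }
}

.coverage_of <- function(d, traits, assigned, basis) {
  w <- d[[basis]]
  tot <- sum(w, na.rm = TRUE)
  if (!is.finite(tot) || tot == 0) return(NA_real_)
  sum(w[d$taxon %in% traits$taxon[assigned]], na.rm = TRUE) / tot
}

## AMBI / BENTIX shared machinery: group shares renormalized over taxa with
## an ecological group assigned, gated on coverage.
.group_shares <- function(d, traits, config, basis = "abundance") {
  assigned <- .trait_assigned(traits, "ecological_group")
  cov <- .coverage_of(d, traits, assigned, basis)
  if (is.na(cov) || cov < config$coverage_threshold) {
    return(list(ok = FALSE, reason = "coverage"))
  }
  dd <- dplyr::inner_join(d, traits[assigned, c("taxon", "ecological_group")],
                          by = "taxon")
  w <- dd[[basis]]
  keep <- !is.na(w) & w > 0
  if (!any(keep)) return(list(ok = FALSE, reason = "coverage"))
  shares <- tapply(w[keep], dd$ecological_group[keep], sum)
  shares <- shares / sum(shares)
  list(ok = TRUE, shares = shares)
}

.ambi_value <- function(d, traits, config, basis = "abundance") {
  gs <- .group_shares(d, traits, config, basis)
  if (!gs$ok) return(list(value = NA_real_, reason = gs$reason))
  w <- config$ambi_group_weights
  list(value = sum(w[names(gs$shares)] * gs$shares), reason = NA_character_)
}

.one_station <- function(d, traits, refs, config, pressure_type) {
  ab <- d$abundance
  bm <- d$biomass
  A <- sum(ab, na.rm = TRUE)
  has_bm <- !all(is.na(bm))
  B <- if (has_bm) sum(bm, na.rm = TRUE) else NA_real_
  R <- sum(ab > 0, na.rm = TRUE)

  rows <- list(
    .res("B", B, "no_biomass"),
    .res("A", A),
    .res("R", R)
  )

  ## diversity block (abundance-based)
  if (A > 0) {
    p <- ab[which(ab > 0)] / A
    H <- -sum(p * log(p, base = config$shannon_log_base))
    SI <- sum(p^2)
    rows <- c(rows, list(.res("H", H), .res("SI", SI), .res("IS", 1 / SI)))
  } else {
    rows <- c(rows, list(.res("H", NA, "degenerate"),
                         .res("SI", NA, "degenerate"),
                         .res("IS", NA, "degenerate")))
  }
  DM_raw <- if (A > 1 && R >= 1) (R - 1) / log(A) else NA_real_
  if (is.na(DM_raw)) {
    rows <- c(rows, list(.res("DM", NA, "degenerate")))
  } else if (is.null(refs) || !is.finite(refs$d_ref) || refs$d_ref <= 0) {
    rows <- c(rows, list(.res("DM", NA, "no_reference")))
  } else {
    rows <- c(rows, list(.res("DM", min(1, DM_raw / refs$d_ref))))
  }

  ## biotic indices on ecological groups
  ambi <- .ambi_value(d, traits, config)
  rows <- c(rows, list(.res("AMBI", ambi$value, ambi$reason)))

  gs <- .group_shares(d, traits, config)
  if (!gs$ok) {
    rows <- c(rows, list(.res("BENTIX", NA, gs$reason)))
  } else {
    p_sens <- sum(gs$shares[names(gs$shares) %in% c("I", "II")])
    p_tol <- sum(gs$shares[names(gs$shares) %in% c("III", "IV", "V")])
    bentix <- config$bentix_weights[["sensitive"]] * p_sens +
      config$bentix_weights[["tolerant"]] * p_tol
    rows <- c(rows, list(.res("BENTIX", bentix)))
  }

  ## multimetrics
  H_val <- rows[[which(purrr::map_chr(rows, ~ .x$indicator) == "H")]]$value
  if (is.na(ambi$value) || is.na(H_val)) {
    rows <- c(rows, list(.res("MAMBI", NA, ambi$reason %||% "degenerate"),
                         .res("DKI", NA, ambi$reason %||% "degenerate")))
  } else if (is.null(refs)) {
    rows <- c(rows, list(.res("MAMBI", NA, "no_reference"),
                         .res("DKI", NA, "no_reference")))
  } else {
    rows <- c(rows, list(
      .res("MAMBI", .mambi_value(ambi$value, H_val, R, refs)),
      .res("DKI", config$dki_salinity_normalizer(
        0.5 * ((1 - ambi$value / 7) + H_val / refs$h_ref)))
    ))
  }

  ## TDI family on species trait scores
  rows <- c(rows, .tdi_family(d, traits, config))

  ## median longevity and long-lived fraction (biomass-based)
  rows <- c(rows, .longevity_block(d, traits, config, has_bm))

  ## sensitive-fraction indices
  rows <- c(rows, list(.sos_value(d, traits, config, pressure_type, has_bm)))

  purrr::list_rbind(rows)
}

## M-AMBI as a standardized-space projection: each of (reversed AMBI, H, R)
## is rescaled so the bad anchor (AMBI = 6, H = 0, R = 0) maps to 0 and the
## high anchor (best-observed reference values) maps to 1; the station's
## position is the orthogonal projection coefficient on the bad->high
## segment, which for the rescaled space is the mean coordinate, clipped
## to [0, 1].
.mambi_value <- function(ambi, H, R, refs) {
  denom_a <- 6 - refs$ambi_good
  if (denom_a <= 0 || refs$h_ref <= 0 || refs$r_ref <= 0) return(NA_real_)
  u <- c((6 - ambi) / denom_a, H / refs$h_ref, R / refs$r_ref)
  min(1, max(0, mean(u)))
}

.tdi_family <- function(d, traits, config) {
  assigned <- .trait_assigned(traits, "tdi_trait_scores")
  basis <- config$weighting_basis[["TDI"]]
  cov <- .coverage_of(d, traits, assigned, basis)
  if (is.na(cov) || cov < config$coverage_threshold) {
    return(list(.res("TDI", NA, "coverage"), .res("mTDI", NA, "coverage"),
                .res("mT", NA, "coverage"), .res("pTDI", NA, "coverage")))
  }
  tt <- traits[assigned, c("taxon", .score_cols, "protected")]
  tt$s <- rowSums(tt[, .score_cols])
  dd <- dplyr::inner_join(d, tt, by = "taxon")
  w <- dd[[basis]]
  keep <- !is.na(w) & w > 0
  dd <- dd[keep, ]
  w <- w[keep]
  if (nrow(dd) == 0) {
    return(list(.res("TDI", NA, "coverage"), .res("mTDI", NA, "coverage"),
                .res("mT", NA, "coverage"), .res("pTDI", NA, "coverage")))
  }
  lw <- log(w + 1)
  tdi <- if (sum(lw) > 0) sum(lw * dd$s) / sum(lw) else NA_real_
  p <- w / sum(w)
  mtdi <- sum(p * dd$s)
  prot <- !is.na(dd$protected) & dd$protected
  ## mT is a vulnerability score oriented like AMBI (low = good state): the
  ## complement of the protection-adjusted community trait score. After the
  ## standard orientation reversal (max 16) the analysis-scale mT equals
  ## mTDI plus the aggravating-factor term for protected taxa.
  mt <- (config$tdi_score_max + config$protected_multiplier) -
    (mtdi + config$protected_multiplier * sum(p[prot]))
  ## pTDI: share of score-weighted basis carried by the most sensitive
  ## (top score-quantile) taxa, normalized by the maximal attainable score
  thr <- quantile(dd$s, config$ptdi_quantile, type = 1, names = FALSE)
  top <- dd$s >= thr
  ptdi <- sum(w[top] * dd$s[top]) / sum(w * config$tdi_score_max)
  list(.res("TDI", tdi), .res("mTDI", mtdi), .res("mT", mt),
       .res("pTDI", ptdi))
}

.longevity_block <- function(d, traits, config, has_bm) {
  if (!has_bm) {
    return(list(.res("Lm", NA, "no_biomass"), .res("Lf", NA, "no_biomass")))
  }
  assigned <- .trait_assigned(traits, "longevity_years")
  cov <- .coverage_of(d, traits, assigned, "biomass")
  if (is.na(cov) || cov < config$coverage_threshold) {
    return(list(.res("Lm", NA, "coverage"), .res("Lf", NA, "coverage")))
  }
  dd <- dplyr::inner_join(d, traits[assigned, c("taxon", "longevity_years")],
                          by = "taxon")
  keep <- !is.na(dd$biomass) & dd$biomass > 0
  dd <- dd[keep, ]
  if (nrow(dd) == 0) {
    return(list(.res("Lm", NA, "degenerate"), .res("Lf", NA, "degenerate")))
  }
  ord <- order(dd$longevity_years)
  cum <- cumsum(dd$biomass[ord]) / sum(dd$biomass)
  lm_val <- dd$longevity_years[ord][which(cum >= 0.5)[1]]
  lf_val <- sum(dd$biomass[dd$longevity_years > config$longevity_cutoff]) /
    sum(dd$biomass)
  list(.res("Lm", lm_val), .res("Lf", lf_val))
}

## SoS: biomass fraction of the most sensitive taxa. Under trawling the
## sensitivity classification is BESITO (fallback: longevity classes when
## BESITO coverage is insufficient); under other pressures the AMBI
## ecological groups I-II define the sensitive set.
.sos_value <- function(d, traits, config, pressure_type, has_bm) {
  if (!has_bm) return(.res("SoS", NA, "no_biomass"))
  frac_of <- function(assigned, sensitive_taxa) {
    cov <- .coverage_of(d, traits, assigned, "biomass")
    if (is.na(cov) || cov < config$coverage_threshold) return(NULL)
    dd <- d[d$taxon %in% traits$taxon[assigned], ]
    tot <- sum(dd$biomass, na.rm = TRUE)
    if (!is.finite(tot) || tot == 0) return(NULL)
    sum(dd$biomass[dd$taxon %in% sensitive_taxa], na.rm = TRUE) / tot
  }
  if (pressure_type == "trawling") {
    assigned <- .trait_assigned(traits, "besito_group")
    val <- frac_of(assigned,
                   traits$taxon[assigned &
                                  traits$besito_group >= config$besito_cutoff])
    if (!is.null(val)) return(.res("SoS", val))
    ## longevity-class fallback
    assigned <- .trait_assigned(traits, "longevity_years")
    val <- frac_of(assigned,
                   traits$taxon[assigned &
                                  traits$longevity_years > config$longevity_cutoff])
    if (!is.null(val)) return(.res("SoS", val))
    return(.res("SoS", NA, "coverage"))
  }
  assigned <- .trait_assigned(traits, "ecological_group")
  val <- frac_of(assigned,
                 traits$taxon[assigned &
                                traits$ecological_group %in% c("I", "II")])
  if (is.null(val)) .res("SoS", NA, "coverage") else .res("SoS", val)
}

#' Reverse indicator orientation
#'
#' Indicators for which low raw values indicate good state (AMBI, mT and
#' Simpson dominance by default) are reversed before all downstream
#' analyses by multiplying with minus one and adding the maximum
#' attainable value, so that a decline is the expected trawling response
#' for every indicator.
#'
#' @param values Numeric vector of raw index values.
#' @param max_value Maximum attainable value of the index (6 for AMBI).
#' @return The reversed values.
#' @export
reverse_orientation <- function(values, max_value) {
  stopifnot(is.numeric(max_value), length(max_value) == 1)
  -values + max_value
}

#' Apply the configured orientation reversals to an indicator table
#'
#' @param ind Tidy indicator table from [compute_indicators()].
#' @param config Indicator configuration (its `reversal` entry names the
#'   reversed indicators and their maxima).
#' @return The table with reversed values for the listed indicators.
#' @export
apply_reversal <- function(ind, config = indicator_config()) {
  for (id in names(config$reversal)) {
    sel <- ind$indicator == id
    ind$value[sel] <- reverse_orientation(ind$value[sel],
                                          config$reversal[[id]])
  }
  ind
}
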