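#' Indicator configuration
#'
#' Collects every tunable used by the indicator suite and the downstream
#' analyses. Defaults follow the index definitions in the source literature
#' for each indicator family; everything that the published methods leave
#' open (score cutoffs, class midpoints, coverage rules) is exposed here so
#' that a run is fully described by its config.
#'
#' @param ambi_group_weights Named weights for AMBI ecological groups I-V.
#'   The classic coefficients are 0, 1.5, 3, 4.5 and 6: the index is the
#'   weighted sum of the group shares, so 0 = fully sensitive community,
#'   6 = fully opportunistic.
#' @param bentix_weights Named weights for the BENTIX partition: sensitive
#'   taxa (groups I-II) weighted 6, tolerant taxa (groups III-V) weighted 2,
#'   giving a 2-6 range.
#' @param coverage_threshold Minimum fraction of a station's abundance (or
#'   biomass, for biomass-based indices) that must belong to taxa with the
#'   relevant trait assigned; below it the station value is missing with
#'   reason `"coverage"` rather than rescaled.
#' @param shannon_log_base Base of the logarithm in the Shannon index
#'   (natural log by default).
#' @param longevity_cutoff Years; taxa living longer count as long-lived for
#'   the `Lf` fraction and the longevity fallback of `SoS`.
#' @param besito_cutoff BESITO group (1-5 scale, 5 most sensitive to
#'   trawling) at or above which a taxon counts as sensitive for `SoS` under
#'   a trawling pressure.
#' @param ptdi_quantile Quantile of the per-species TDI score above which a
#'   taxon belongs to the "most sensitive" class used by `pTDI`.
#' @param protected_multiplier Additive weight per unit of protected-taxon
#'   share in the aggravating-factor term of `mT`.
#' @param longevity_class_midpoints Midpoints (years) used when longevity is
#'   supplied as the categorical classes `"1-3"`, `"3-10"`, `">10"`.
#' @param tdi_score_max Maximum attainable per-species TDI score (five
#'   traits scored 0-3).
#' @param reversal Named vector of maximum attainable values for the
#'   indicators whose orientation is reversed before analysis (low = good
#'   for the raw index): reversed value = max - value. AMBI spans 0-6; our
#'   mT construction spans 0-16 (score 15 plus the protected term); the
#'   Simpson dominance index spans 0-1, and its reversed form 1 - sum(p^2)
#'   is the evenness orientation under which it declines with disturbance
#'   alongside the other diversity indices. After reversal, higher = better
#'   for all 18 indicators.
#' @param dki_salinity_normalizer Monotone function applied to the raw DKI
#'   value; identity by default (no salinity calibration bundled).
#' @param weighting_basis Named character vector giving, for the indices
#'   that can use either, whether abundance or biomass weights are used.
#' @param low_sar_threshold Swept-area-ratio (per year) below which a
#'   station counts as low-pressure, both for reference conditions and for
#'   the meta-analysis contrast.
#' @param high_sar_threshold SAR above which a station is a candidate
#'   high-pressure station.
#' @param n_high_stations Number of most heavily fished stations selected
#'   when enough stations exceed `high_sar_threshold`.
#' @param n_high_relative Number of most heavily fished stations selected
#'   on gradients whose pressure is a relative intensity rather than SAR.
#' @param zero_floor Floor applied to near-zero group means before the log
#'   response-ratio, for the indicators in `floored_indicators`.
#' @param floored_indicators Indicators whose group means are floored
#'   (the fraction-valued `SoS` and `Lf` by default).
#' @param variance_floor Replacement sampling variance for degenerate
#'   (zero) effect-size variances entering the meta-analysis.
#'
#' @return A list with class `benthind_config`.
#' @export
indicator_config <- function(
    ambi_group_weights = c(I = 0, II = 1.5, III = 3, IV = 4.5, V = 6),
    bentix_weights = c(sensitive = 6, tolerant = 2),
    coverage_threshold = 0.8,
    shannon_log_base = exp(1),
    longevity_cutoff = 10,
    besito_cutoff = 4,
    ptdi_quantile = 0.8,
    protected_multiplier = 1,
    longevity_class_midpoints = c("1-3" = 2, "3-10" = 6.5, ">10" = 15),
    tdi_score_max = 15,
    reversal = c(AMBI = 6, mT = 16, SI = 1),
    dki_salinity_normalizer = identity,
    weighting_basis = c(
      AMBI = "abundance", BENTIX = "abundance", TDI = "abundance",
      mTDI = "abundance", mT = "abundance", pTDI = "abundance",
      SoS = "biomass", Lf = "biomass", Lm = "biomass"
    ),
    low_sar_threshold = 0.35,
    high_sar_threshold = 1,
    n_high_stations = 5,
    n_high_relative = 3,
    zero_floor = 0.01,
    floored_indicators = c("SoS", "Lf"),
    variance_floor = 1e-6) {
  stopifnot(
    all(is.finite(ambi_group_weights)), length(ambi_group_weights) == 5,
    length(bentix_weights) == 2,
    coverage_threshold >= 0, coverage_threshold <= 1,
    shannon_log_base > 0, longevity_cutoff > 0,
    ptdi_quantile >= 0, ptdi_quantile <= 1,
    zero_floor > 0, variance_floor > 0
  )
  structure(as.list(environment()), class = "benthind_config")
}

#' @export
print.benthind_config <- function(x, ...) {
  cat("<benthind_config>\n")
  cat("  coverage threshold:", x$coverage_threshold, "\n")
  cat("  AMBI weights:", paste(x$ambi_group_weights, collapse = ", "), "\n")
  cat("  low/high SAR thresholds:", x$low_sar_threshold, "/",
      x$high_sar_threshold, "\n")
  cat("  reversed indicators:", paste(names(x$reversal), collapse = ", "), "\n")
  invisible(x)
}
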