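## Sensitivity of indicators to trawling: low- vs high-pressure station
## contrast per gradient, log response-ratio effect sizes, and weighted
## random-effects pooling across gradients (overall and by sampling gear).

#' Select low- and high-trawling stations for the meta-analysis contrast
#'
#' Low-pressure stations are all those with SAR below the configured
#' threshold (0.35 per year); when none qualify, the two least-fished
#' stations are used. On gradients without SAR (relative intensity), the
#' zero-pressure stations are taken (again falling back to the two
#' least-fished). High-pressure stations are the five most heavily fished
#' when at least five exceed SAR 1 per year, otherwise all stations above
#' SAR 1; on non-SAR gradients, the three most heavily fished. Stations
#' between the thresholds are left out of the contrast. A contrast needs
#' at least two stations on each side to be evaluable.
#'
#' @param stations Station metadata for one trawling gradient.
#' @param config Indicator configuration (thresholds and group sizes).
#' @return A list with class `station_contrast`: `gradient_id`, `low`,
#'   `high` (station id vectors), `gear`, `evaluable`.
#' @export
select_low_high_stations <- function(stations, config = indicator_config()) {
  stopifnot(all(stations$pressure_type == "trawling"))
  p <- stations$pressure_value
  ids <- stations$station_id
  has_sar <- all(stations$pressure_scale %in% "sar") && any(!is.na(p))
  least_fished <- function(k) ids[order(p)][seq_len(min(k, length(ids)))]
  if (has_sar) {
    low <- ids[!is.na(p) & p < config$low_sar_threshold]
    if (length(low) == 0) low <- least_fished(2)
    above <- ids[!is.na(p) & p > config$high_sar_threshold]
    high <- if (length(above) >= config$n_high_stations) {
      ids[order(p, decreasing = TRUE)][seq_len(config$n_high_stations)]
    } else {
      above
    }
  } else {
    low <- ids[!is.na(p) & p == 0]
    if (length(low) < 2) low <- least_fished(2)
    high <- ids[order(p, decreasing = TRUE)][seq_len(
      min(config$n_high_relative, length(ids)))]
  }
  high <- setdiff(high, low)
  structure(list(
    gradient_id = stations$gradient_id[1],
    low = low, high = high,
    gear = stations$gear[1],
    evaluable = length(low) >= 2 && length(high) >= 2
  ), class = "station_contrast")
}

#' Log response-ratio effect size for one indicator in one contrast
#'
#' lnRR = ln(I_trawled / I_control) on the group means, with the
#' delta-method sampling variance SD_h^2/(n_h m_h^2) + SD_l^2/(n_l m_l^2).
#' For the fraction-valued indicators prone to zero means (SoS and Lf by
#' default) near-zero group means are floored at 0.01 before the ratio to
#' prevent inflated effect sizes and CIs.
#'
#' @param ind Tidy indicator table for the contrast's gradient.
#' @param contrast A `station_contrast`.
#' @param indicator Indicator id.
#' @param config Indicator configuration (`zero_floor`,
#'   `floored_indicators`).
#' @return One-row tibble (gradient_id, indicator, lnRR, v, n_low, n_high,
#'   gear, degenerate, missing_reason) or a missing-effect row.
#' @export
log_response_ratio <- function(ind, contrast, indicator,
                               config = indicator_config()) {
  miss <- function(reason) tibble::tibble(
    gradient_id = contrast$gradient_id, indicator = indicator,
    lnRR = NA_real_, v = NA_real_, n_low = NA_integer_,
    n_high = NA_integer_, gear = contrast$gear, degenerate = FALSE,
    missing_reason = reason
  )
  if (!contrast$evaluable) return(miss("non_evaluable_contrast"))
  x <- ind[ind$indicator == indicator, ]
  grab <- function(st) {
    v <- x$value[x$station_id %in% st]
    v[!is.na(v)]
  }
  lo <- grab(contrast$low)
  hi <- grab(contrast$high)
  ## indicators (TDI family) with partial coverage stay in while both
  ## groups retain information from at least two stations
  if (length(lo) < 2 || length(hi) < 2) return(miss("insufficient_stations"))
  m_l <- mean(lo); m_h <- mean(hi)
  if (indicator %in% config$floored_indicators) {
    m_l <- max(m_l, config$zero_floor)
    m_h <- max(m_h, config$zero_floor)
  }
  if (m_l <= 0 || m_h <= 0) return(miss("nonpositive_mean"))
  v <- sd(hi)^2 / (length(hi) * m_h^2) + sd(lo)^2 / (length(lo) * m_l^2)
  tibble::tibble(
    gradient_id = contrast$gradient_id, indicator = indicator,
    lnRR = log(m_h / m_l), v = v,
    n_low = length(lo), n_high = length(hi), gear = contrast$gear,
    degenerate = v <= 0, missing_reason = NA_character_
  )
}

#' Pool effect sizes by weighted random-effects meta-analysis
#'
#' Effects are pooled with weights 1/(v + tau^2); the between-gradient
#' variance tau^2 is estimated by restricted maximum likelihood (with a
#' DerSimonian-Laird fallback if REML fails to converge). Degenerate
#' (zero) sampling variances are replaced by the configured floor. A
#' single effect is returned as is, with tau^2 = 0. Significance means
#' the 95% CI excludes zero.
#'
#' @param effects Effect-size tibble (rows with missing lnRR are dropped).
#' @param config Indicator configuration.
#' @return One-row tibble (k, estimate, se, ci_lb, ci_ub, tau2,
#'   significant), or a zero-row tibble when no effects remain.
#' @export
pool_random_effects <- function(effects, config = indicator_config()) {
  e <- effects[!is.na(effects$lnRR), ]
  empty <- tibble::tibble(k = integer(), estimate = double(), se = double(),
                          ci_lb = double(), ci_ub = double(),
                          tau2 = double(), significant = logical())
  if (nrow(e) == 0) return(empty)
  v <- pmax(e$v, config$variance_floor)
  if (nrow(e) == 1) {
    se <- sqrt(v)
    return(tibble::tibble(k = 1L, estimate = e$lnRR, se = se,
                          ci_lb = e$lnRR - 1.96 * se,
                          ci_ub = e$lnRR + 1.96 * se, tau2 = 0,
                          significant = (e$lnRR - 1.96 * se) > 0 |
                            (e$lnRR + 1.96 * se) < 0))
  }
  fit <- tryCatch(
    metafor::rma(yi = e$lnRR, vi = v, method = "REML"),
    error = function(err) tryCatch(
      metafor::rma(yi = e$lnRR, vi = v, method = "DL"),
      error = function(err2) NULL
    )
  )
  if (is.null(fit)) {
    w <- 1 / v
    est <- sum(w * e$lnRR) / sum(w)
    se <- sqrt(1 / sum(w))
    tau2 <- 0
  } else {
    est <- as.numeric(fit$beta)
    se <- fit$se
    tau2 <- fit$tau2
  }
  ci <- est + c(-1.96, 1.96) * se
  tibble::tibble(k = nrow(e), estimate = est, se = se,
                 ci_lb = ci[1], ci_ub = ci[2], tau2 = tau2,
                 significant = ci[1] > 0 | ci[2] < 0)
}

#' Full meta-analytic sensitivity assessment
#'
#' Builds the low/high contrast for every trawling gradient, computes the
#' log response-ratio of every indicator, and pools across gradients:
#' overall and separately per sampling gear (trawls vs grabs/cores).
#'
#' @param ind Tidy indicator table (orientation already reversed) covering
#'   the trawl gradients.
#' @param stations Station metadata for the same gradients.
#' @param config Indicator configuration.
#' @return A list with class `benthic_meta`: `contrasts`, `effects` (per
#'   gradient x indicator) and `pooled` (indicator x subgroup).
#' @export
meta_sensitivity <- function(ind, stations, config = indicator_config()) {
  stations <- stations[stations$pressure_type == "trawling", ]
  contrasts <- purrr::map(split(stations, stations$gradient_id),
                          select_low_high_stations, config = config)
  inds <- levels(droplevels(factor(ind$indicator,
                                   levels = .indicator_levels)))
  effects <- purrr::map(contrasts, function(ct) {
    g <- ind[ind$gradient_id == ct$gradient_id, ]
    purrr::map(inds, ~ log_response_ratio(g, ct, .x, config)) |>
      purrr::list_rbind()
  }) |> purrr::list_rbind()

  pool_set <- function(e, label) {
    purrr::map(split(e, e$indicator), pool_random_effects, config = config) |>
      purrr::list_rbind(names_to = "indicator") |>
      dplyr::mutate(subgroup = label, .after = "indicator")
  }
  pooled <- dplyr::bind_rows(
    pool_set(effects, "all"),
    purrr::list_rbind(purrr::map(
      split(effects, effects$gear),
      function(e) pool_set(e, unique(e$gear))
    ))
  )
  pooled$indicator <- factor(pooled$indicator, levels = .indicator_levels)
  pooled <- dplyr::arrange(pooled, .data$subgroup, .data$indicator)
  structure(list(contrasts = contrasts, effects = effects, pooled = pooled),
            class = "benthic_meta")
}

#' @export
print.benthic_meta <- function(x, ...) {
  cat("<benthic_meta>", length(x$contrasts), "gradient contrasts,",
      sum(!is.na(x$effects$lnRR)), "effect sizes\n")
  print(x$pooled[x$pooled$subgroup == "all", ])
  invisible(x)
}

#' @rdname meta_sensitivity
#' @param x A `benthic_meta` object.
#' @param ... Unused.
#' @export
tidy.benthic_meta <- function(x, ...) x$pooled

#' @rdname meta_sensitivity
#' @export
glance.benthic_meta <- function(x, ...) {
  tibble::tibble(
    n_gradients = length(x$contrasts),
    n_evaluable = sum(purrr::map_lgl(x$contrasts, "evaluable")),
    n_effects = sum(!is.na(x$effects$lnRR)),
    n_indicators = dplyr::n_distinct(x$pooled$indicator)
  )
}
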