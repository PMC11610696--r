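## Per-gradient pressure-response trends: a linear model on
## log10(pressure + 1) for the trawl gradients, a penalized-spline GAM for
## the non-trawl (specificity) gradients, both classified against an
## intercept-only null by AIC on identical observations. A pressure model
## whose AIC is equal or higher than the null is "no effect"; otherwise
## the sign of the predicted change from the best to the worst end of the
## pressure axis gives decline or increase.

.classify_trend <- function(delta_aic, change) {
  if (is.na(delta_aic) || delta_aic <= 0 || is.na(change) || change == 0) {
    "no_effect"
  } else if (change < 0) "decline" else "increase"
}

.trend_row <- function(gradient_id = NA_character_,
                       indicator = NA_character_, model, n,
                       delta_aic = NA_real_, predicted_change = NA_real_,
                       effect_class = "not_evaluated", degenerate = FALSE,
                       nonmonotone = FALSE) {
  tibble::tibble(gradient_id = gradient_id, indicator = indicator,
                 model = model, n = n, delta_aic = delta_aic,
                 predicted_change = predicted_change,
                 effect_class = effect_class, degenerate = degenerate,
                 nonmonotone = nonmonotone)
}

#' Log-linear pressure trend for one indicator on one gradient
#'
#' Ordinary least squares of the indicator on log10(pressure + 1),
#' compared against an intercept-only null by AIC on the same
#' observations. The predicted change is the fitted value at the worst
#' end of the pressure axis minus the fitted value at the best end (for
#' trawling, highest minus lowest intensity).
#'
#' @param values Indicator values per station (missing allowed).
#' @param pressure Pressure values, same order.
#' @param worsening `"increasing"` (default) or `"decreasing"`: the
#'   direction along the pressure axis in which conditions worsen.
#' @param min_n Minimum stations with data.
#' @return A list with class `trend_fit`: `row` (one-row classification
#'   tibble as in [effect_matrix()]) plus the fitted models.
#' @export
fit_loglinear_trend <- function(values, pressure, worsening = "increasing",
                                min_n = 4) {
  stopifnot(length(values) == length(pressure))
  ok <- !is.na(values) & !is.na(pressure)
  y <- values[ok]
  p <- pressure[ok]
  out <- list(fit = NULL, null = NULL)
  if (length(y) < min_n) {
    out$row <- .trend_row(model = "loglinear", n = length(y))
  } else if (var(y) == 0) {
    out$row <- .trend_row(model = "loglinear", n = length(y),
                          effect_class = "no_effect", degenerate = TRUE)
  } else {
    x <- log10(p + 1)
    d <- data.frame(y = y, x = x)
    m1 <- lm(y ~ x, data = d)
    m0 <- lm(y ~ 1, data = d)
    ends <- if (worsening == "decreasing") {
      c(best = max(p), worst = min(p))
    } else {
      c(best = min(p), worst = max(p))
    }
    f <- predict(m1, newdata = data.frame(x = log10(ends + 1)))
    change <- unname(f[2] - f[1])
    delta <- AIC(m0) - AIC(m1)
    out$row <- .trend_row(model = "loglinear", n = length(y),
                          delta_aic = delta, predicted_change = change,
                          effect_class = .classify_trend(delta, change))
    out$fit <- m1
    out$null <- m0
  }
  structure(out, class = "trend_fit")
}

#' Penalized-spline pressure trend for one indicator on one gradient
#'
#' A GAM with a small-basis thin-plate smoother (k = 4, GCV-penalized)
#' against an intercept-only null, compared by AIC (effective degrees of
#' freedom). Used for the non-trawl specificity gradients and as the
#' flexible check on trawl gradients. The effect direction comes from the
#' predicted change along the worsening direction of the pressure axis;
#' a fitted trend whose direction changes sign is flagged nonmonotone.
#'
#' @inheritParams fit_loglinear_trend
#' @return A `trend_fit`.
#' @export
fit_smooth_trend <- function(values, pressure, worsening = "increasing",
                             min_n = 6) {
  stopifnot(length(values) == length(pressure))
  ok <- !is.na(values) & !is.na(pressure)
  y <- values[ok]
  p <- pressure[ok]
  out <- list(fit = NULL, null = NULL)
  if (length(y) < min_n) {
    out$row <- .trend_row(model = "smooth", n = length(y))
  } else if (var(y) == 0) {
    out$row <- .trend_row(model = "smooth", n = length(y),
                          effect_class = "no_effect", degenerate = TRUE)
  } else {
    d <- data.frame(y = y, x = p)
    k <- min(4, length(unique(p)))
    m1 <- mgcv::gam(y ~ s(x, k = k), data = d, method = "GCV.Cp")
    m0 <- mgcv::gam(y ~ 1, data = d)
    grid <- seq(min(p), max(p), length.out = 50)
    f <- as.numeric(predict(m1, newdata = data.frame(x = grid)))
    if (worsening == "decreasing") f <- rev(f)
    change <- f[length(f)] - f[1]
    steps <- diff(f)
    nonmono <- any(steps > 1e-8) && any(steps < -1e-8)
    delta <- AIC(m0) - AIC(m1)
    out$row <- .trend_row(model = "smooth", n = length(y),
                          delta_aic = delta, predicted_change = change,
                          effect_class = .classify_trend(delta, change),
                          nonmonotone = nonmono)
    out$fit <- m1
    out$null <- m0
  }
  structure(out, class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat("<trend_fit>", x$row$model, "n =", x$row$n, "->", x$row$effect_class,
      "\n")
  invisible(x)
}

#' @rdname fit_loglinear_trend
#' @param x A `trend_fit`.
#' @param ... Unused.
#' @export
glance.trend_fit <- function(x, ...) x$row

#' @rdname fit_loglinear_trend
#' @export
tidy.trend_fit <- function(x, ...) {
  if (is.null(x$fit)) return(tibble::tibble(term = character(),
                                            estimate = double()))
  co <- coef(x$fit)
  tibble::tibble(term = names(co), estimate = unname(co))
}

## TDI-family gradient retention: values at both the low and high half of
## the pressure axis and at no less than half of the gradient's stations.
.tdi_retained <- function(values, pressure) {
  ok <- !is.na(values)
  if (sum(ok) < length(values) / 2) return(FALSE)
  med <- median(pressure, na.rm = TRUE)
  any(ok & pressure < med) && any(ok & pressure > med)
}

#' Fit pressure trends for every indicator on every gradient
#'
#' Applies [fit_loglinear_trend()] to trawl gradients and
#' [fit_smooth_trend()] to non-trawl gradients (or as configured via
#' `model`). TDI-family indicators are retained on a gradient only when
#' they have values at both low and high intensity and for at least half
#' of the stations.
#'
#' @param ind Tidy indicator table (orientation already reversed).
#' @param stations Station metadata.
#' @param model `"auto"` (loglinear for trawling, smooth otherwise),
#'   `"loglinear"` or `"smooth"`.
#' @return Tibble of per (gradient, indicator) classifications.
#' @export
fit_gradient_trends <- function(ind, stations, model = "auto") {
  tdi_family <- c("TDI", "mTDI", "mT", "pTDI")
  purrr::map(split(stations, stations$gradient_id), function(st) {
    g <- ind[ind$gradient_id == st$gradient_id[1], ]
    use_model <- if (model == "auto") {
      if (st$pressure_type[1] == "trawling") "loglinear" else "smooth"
    } else model
    purrr::map(unique(as.character(g$indicator)), function(id) {
      x <- g[g$indicator == id, ]
      x <- x[match(st$station_id, x$station_id), ]
      row <- if (id %in% tdi_family &&
                 !.tdi_retained(x$value, st$pressure_value)) {
        .trend_row(model = use_model, n = sum(!is.na(x$value)))
      } else if (use_model == "loglinear") {
        glance(fit_loglinear_trend(x$value, st$pressure_value,
                                   st$worsening[1]))
      } else {
        glance(fit_smooth_trend(x$value, st$pressure_value,
                                st$worsening[1]))
      }
      row$gradient_id <- st$gradient_id[1]
      row$indicator <- id
      row
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
}

#' Indicator-by-gradient effect matrix and decline shares
#'
#' @param trends Output of [fit_gradient_trends()].
#' @return A list with class `effect_matrix`: `matrix` (wide tibble of
#'   classifications, indicators as rows) and `decline_share` (per
#'   indicator: declines / evaluated gradients, as a percentage).
#' @export
effect_matrix <- function(trends) {
  trends$indicator <- factor(trends$indicator, levels = .indicator_levels)
  wide <- tidyr::pivot_wider(
    trends[, c("gradient_id", "indicator", "effect_class")],
    names_from = "gradient_id", values_from = "effect_class",
    values_fill = "not_evaluated"
  ) |> dplyr::arrange(.data$indicator)
  share <- trends |>
    dplyr::group_by(.data$indicator) |>
    dplyr::summarise(
      n_evaluated = sum(.data$effect_class != "not_evaluated"),
      n_decline = sum(.data$effect_class == "decline"),
      decline_share = ifelse(.data$n_evaluated > 0,
                             100 * .data$n_decline / .data$n_evaluated,
                             NA_real_),
      .groups = "drop"
    )
  structure(list(matrix = wide, decline_share = share, trends = trends),
            class = "effect_matrix")
}

#' @export
print.effect_matrix <- function(x, ...) {
  cat("<effect_matrix>", nrow(x$matrix), "indicators x",
      ncol(x$matrix) - 1, "gradients\n")
  print(x$decline_share)
  invisible(x)
}

#' @rdname effect_matrix
#' @param x An `effect_matrix`.
#' @param ... Unused.
#' @export
tidy.effect_matrix <- function(x, ...) x$trends

#' @rdname effect_matrix
#' @export
glance.effect_matrix <- function(x, ...) x$decline_share
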