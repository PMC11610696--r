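## Indicator complementarity: Spearman rank correlations between
## indicators within each trawl gradient, averaged across gradients, and
## ordered by Ward hierarchical clustering on distance 1 - mean rho.

#' Spearman correlation matrix between indicators within one gradient
#'
#' Pairwise-complete Spearman correlations (ties mid-ranked) between all
#' indicator pairs across the gradient's stations. Pairs with fewer than
#' `min_n` jointly non-missing stations, or with a constant indicator, are
#' missing.
#'
#' @param ind Tidy indicator table for one gradient (station_id,
#'   indicator, value).
#' @param min_n Minimum joint observations per pair.
#' @return A list with class `indicator_cor`: `rho` (correlation matrix)
#'   and `n` (pairwise observation counts).
#' @export
indicator_correlations <- function(ind, min_n = 3) {
  wide <- tidyr::pivot_wider(
    ind[, c("station_id", "indicator", "value")],
    names_from = "indicator", values_from = "value"
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  n_pair <- crossprod(!is.na(m))
  rho <- suppressWarnings(
    cor(m, method = "spearman", use = "pairwise.complete.obs")
  )
  rho[n_pair < min_n] <- NA
  diag(rho) <- ifelse(diag(n_pair) >= 1, 1, NA)
  structure(list(rho = rho, n = n_pair), class = "indicator_cor")
}

#' Correlation stack across trawl gradients
#'
#' @param ind Tidy indicator table with a `gradient_id` column.
#' @param min_n Passed to [indicator_correlations()].
#' @return A list of `indicator_cor`, one per gradient, with class
#'   `correlation_stack`.
#' @export
correlation_stack <- function(ind, min_n = 3) {
  structure(
    purrr::map(split(ind, ind$gradient_id), indicator_correlations,
               min_n = min_n),
    class = "correlation_stack"
  )
}

#' Mean and SD correlation matrices over gradients
#'
#' Unweighted mean and standard deviation per indicator pair over the
#' gradients where the pair is defined.
#'
#' @param stack A `correlation_stack`.
#' @return A list with class `avg_correlations`: `mean`, `sd` and
#'   `n_gradients` matrices.
#' @export
average_correlations <- function(stack) {
  mats <- purrr::map(stack, "rho")
  all_names <- unique(unlist(purrr::map(mats, rownames)))
  arr <- array(NA_real_, dim = c(length(all_names), length(all_names),
                                 length(mats)),
               dimnames = list(all_names, all_names, NULL))
  for (i in seq_along(mats)) {
    nm <- rownames(mats[[i]])
    arr[nm, nm, i] <- mats[[i]]
  }
  structure(list(
    mean = apply(arr, c(1, 2), function(x) {
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    }),
    sd = apply(arr, c(1, 2), function(x) {
      x <- x[!is.na(x)]
      if (length(x) == 0) NA_real_ else if (length(x) == 1) 0 else sd(x)
    }),
    n_gradients = apply(arr, c(1, 2), function(x) sum(!is.na(x)))
  ), class = "avg_correlations")
}

#' Ward clustering order of the mean correlation matrix
#'
#' Indicators are ordered by agglomerative hierarchical clustering with
#' Ward linkage on a distance derived from the mean Spearman correlation.
#' The default distance is d = 1 - mean rho, so anti-correlated
#' (complementary) indicators end up far apart; this presumes all
#' indicators enter on their analysis orientation (see [apply_reversal()]).
#' The magnitude alternative d = 1 - |mean rho|, under which an index and
#' its mirror count as redundant, is available via
#' `distance = "absolute"`. Missing pairs are imputed with the column mean
#' of the available correlations (reported via the `imputed` element).
#'
#' @param avg An `avg_correlations` object, or a bare mean matrix.
#' @param distance `"signed"` (default, 1 - rho) or `"absolute"`
#'   (1 - |rho|).
#' @return A list with class `ward_order`: `order` (indicator ids, leaf
#'   order), `hclust` (the merge tree), `distance` matrix and `imputed`
#'   pair count.
#' @export
ward_cluster_order <- function(avg, distance = c("signed", "absolute")) {
  distance <- match.arg(distance)
  m <- if (inherits(avg, "avg_correlations")) avg$mean else as.matrix(avg)
  keep <- colSums(!is.na(m)) > 1          # drop never-evaluated indicators
  m <- m[keep, keep, drop = FALSE]
  if (ncol(m) < 2) stop("need at least 2 indicators to cluster", call. = FALSE)
  n_imputed <- sum(is.na(m[upper.tri(m)]))
  for (j in seq_len(ncol(m))) {
    miss <- is.na(m[, j])
    if (any(miss)) m[miss, j] <- mean(m[, j], na.rm = TRUE)
  }
  m <- (m + t(m)) / 2
  d <- if (distance == "absolute") 1 - abs(m) else 1 - m
  diag(d) <- 0
  hc <- hclust(as.dist(d), method = "ward.D2")
  structure(list(order = colnames(m)[hc$order], hclust = hc,
                 distance = d, imputed = n_imputed),
            class = "ward_order")
}

#' @export
print.ward_order <- function(x, ...) {
  cat("<ward_order> leaf order:\n ", paste(x$order, collapse = " "), "\n")
  if (x$imputed > 0) cat("  (", x$imputed, "missing pairs imputed )\n")
  invisible(x)
}
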