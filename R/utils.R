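# Shared numeric helpers.
#
# One percentile convention is used package-wide: linear interpolation between
# closest order statistics (R quantile type 7).

#' Percentiles with the package-wide convention
#'
#' Linear interpolation between closest order statistics (quantile type 7).
#' This single convention is reused for all local/global intensity percentiles
#' and expression-bin limits.
#'
#' @param x numeric vector.
#' @param probs probabilities in \[0,1\].
#' @return numeric vector of percentile values.
#' @export
pctl <- function(x, probs) {
  stats::quantile(x, probs = probs, type = 7, names = FALSE, na.rm = FALSE)
}

#' Piecewise-linear interpolation weights onto a limit grid
#'
#' Distributes one unit of weight per value onto `length(limits)` bins: values
#' at or below the first limit put their whole weight on bin 1; values above
#' the last limit on bin N; a value I with `L[k] <= I < L[k+1]` puts
#' `alpha = (L[k+1] - I) / (L[k+1] - L[k])` on bin k and `1 - alpha` on bin
#' k + 1. Cases are evaluated in this order, first match wins, so a value equal
#' to the first limit lands entirely in bin 1.
#'
#' @param values numeric vector.
#' @param limits non-decreasing numeric vector of bin limits.
#' @return list with integer vectors `bin1`, `bin2` (NA when all weight is on
#'   one bin) and numeric weights `w1`, `w2` aligned with `values`.
#' @export
interp_limit_weights <- function(values, limits) {
  n_lim <- length(limits)
  stopifnot(n_lim >= 2L, !is.unsorted(limits))
  n <- length(values)
  bin1 <- integer(n)
  bin2 <- rep(NA_integer_, n)
  w1 <- rep(1, n)
  w2 <- rep(0, n)

  low <- values <= limits[1L]
  # I == L_N satisfies none of the printed cases; by continuity of the
  # interpolation it takes the last bin (first-match order keeps I == L_1 in
  # bin 1)
  high <- !low & values >= limits[n_lim]
  mid <- !(low | high)
  bin1[low] <- 1L
  bin1[high] <- n_lim
  if (any(mid)) {
    v <- values[mid]
    # largest k with limits[k] <= v; v < limits[n_lim] here so k < n_lim
    k <- findInterval(v, limits)
    width <- limits[k + 1L] - limits[k]
    # zero-width intervals cannot be hit: findInterval returns the largest k
    # with limits[k] <= v, which skips past duplicated limits
    alpha <- (limits[k + 1L] - v) / width
    bin1[mid] <- k
    bin2[mid] <- k + 1L
    w1[mid] <- alpha
    w2[mid] <- 1 - alpha
  }
  list(bin1 = bin1, bin2 = bin2, w1 = w1, w2 = w2)
}

#' Accumulate interpolation weights by group
#'
#' Applies [interp_limit_weights()] and sums the weights within groups, giving
#' one histogram row per group.
#'
#' @param group integer group index in `1..n_groups` per value.
#' @param n_groups number of groups (rows of the result).
#' @param values,limits passed to [interp_limit_weights()].
#' @return numeric matrix `n_groups x length(limits)`.
#' @export
accumulate_limit_weights <- function(group, n_groups, values, limits) {
  w <- interp_limit_weights(values, limits)
  n_lim <- length(limits)
  res <- matrix(0, nrow = n_groups, ncol = n_lim)
  add <- function(bins, wts) {
    keep <- !is.na(bins) & wts != 0
    if (!any(keep)) return(invisible())
    key <- (bins[keep] - 1L) * n_groups + group[keep]
    s <- rowsum(wts[keep], group = key)
    res[as.integer(rownames(s))] <<- res[as.integer(rownames(s))] + s[, 1L]
    invisible()
  }
  add(w$bin1, w$w1)
  add(w$bin2, w$w2)
  res
}

# Row-wise type-7 quantiles of a numeric matrix (rows are observations sets of
# equal size). Thin wrapper so the convention is stated in one place.
row_pctl <- function(x, probs) {
  matrixStats::rowQuantiles(x, probs = probs, type = 7L, drop = FALSE)
}

# Derive a bounded child seed from a user seed and a stream label.
child_seed <- function(seed, stream) {
  (as.integer(seed) * 1009L + as.integer(stream) * 9973L) %% 2147483647L
}
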