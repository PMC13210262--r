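#' Box-plot summary of a sample
#'
#' Quartiles by linear interpolation (the type-7 convention of
#' [stats::quantile()]); whiskers extend to the most extreme observations
#' within 1.5 interquartile ranges of the quartiles, and everything beyond is
#' listed as outliers.
#'
#' @param values nonempty numeric vector.
#' @return list with `q25`, `median`, `q75`, `whisker_lo`, `whisker_hi`,
#'   `outliers`.
#' @examples
#' box_summary(c(1, 2, 3, 4, 5, 100))
#' @export
box_summary <- function(values) {
  if (length(values) == 0 || !is.numeric(values)) {
    stop("box_summary needs a nonempty numeric vector")
  }
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  list(q25 = q[1], median = q[2], q75 = q[3],
       whisker_lo = min(values[inside]), whisker_hi = max(values[inside]),
       outliers = sort(values[!inside]))
}

#' Cliff's delta effect size
#'
#' `delta = (#(x_i > y_j) - #(x_i < y_j)) / (nx * ny)`, the probability-based
#' separation of two samples; ties contribute zero. Computed in O(n log n) by
#' counting with a sorted copy of `y`, exactly equal to the all-pairs
#' definition.
#'
#' @param x,y nonempty numeric vectors.
#' @return delta in `[-1, 1]`; 1 means every `x` exceeds every `y`.
#' @examples
#' cliffs_delta(c(3, 4, 5), c(1, 2))   # complete separation: 1
#' @export
cliffs_delta <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be nonempty")
  ys <- sort(y)
  n_le <- findInterval(x, ys)                     # y <= x_i
  n_lt <- findInterval(x, ys, left.open = TRUE)   # y <  x_i
  n_gt <- length(y) - n_le                        # y >  x_i
  (sum(n_lt) - sum(n_gt)) / (length(x) * length(y))
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' `D` is the supremum over the pooled sample points of the absolute ECDF
#' difference; the p-value uses the asymptotic Kolmogorov distribution
#' `Q(lambda) = 2 * sum_k (-1)^(k-1) exp(-2 k^2 lambda^2)` at
#' `lambda = sqrt(ne) * D` with effective size `ne = nx*ny/(nx+ny)`.
#'
#' @param x,y nonempty numeric vectors.
#' @return list with `D` and `p_value`.
#' @examples
#' ks_two_sample(rnorm(50), rnorm(50, 2))
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be nonempty")
  pooled <- sort(unique(c(x, y)))
  fx <- stats::ecdf(x)(pooled)
  fy <- stats::ecdf(y)(pooled)
  D <- max(abs(fx - fy))
  ne <- length(x) * length(y) / (length(x) + length(y))
  lambda <- sqrt(ne) * D
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  list(D = D, p_value = min(max(p, 0), 1))
}

#' Bias and spread of exponent estimates
#'
#' @param estimates numeric vector of per-replicate estimates.
#' @param truth the generating value.
#' @return list with `bias` (mean estimate minus truth), `median_error`
#'   (median estimate minus truth), `q25`, `q75` (type-7 quartiles of the
#'   estimates).
#' @examples
#' exponent_bias(c(0.7, 0.75, 0.8), truth = 0.75)
#' @export
exponent_bias <- function(estimates, truth) {
  if (length(estimates) == 0) stop("no estimates supplied")
  q <- unname(stats::quantile(estimates, c(0.25, 0.75), type = 7))
  list(bias = mean(estimates) - truth,
       median_error = stats::median(estimates) - truth,
       q25 = q[1], q75 = q[2])
}
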