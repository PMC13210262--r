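#' Pediatric age groups
#'
#' The four study age groups, on an inclusive month grid matching growth-chart
#' rows: 2-5 y.o. is 24-71 months, 6-11 is 72-143, 12-17 is 144-215, and the
#' pooled 2-17 group is 24-215. Children under 24 months are outside the scope
#' of the model.
#'
#' @param label one of `"2-5"`, `"6-11"`, `"12-17"`, `"2-17"`.
#' @return a list with elements `label`, `lo`, `hi` (months, inclusive).
#' @examples
#' age_group("2-5")
#' @export
age_group <- function(label = c("2-17", "2-5", "6-11", "12-17")) {
  label <- match.arg(label)
  rng <- switch(label,
    "2-5"   = c(24L, 71L),
    "6-11"  = c(72L, 143L),
    "12-17" = c(144L, 215L),
    "2-17"  = c(24L, 215L)
  )
  list(label = label, lo = rng[1], hi = rng[2])
}

#' LMS quantile function for body weight
#'
#' Maps a standard-normal score to a body weight through growth-chart LMS
#' parameters: `weight = M * (1 + z*L*S)^(1/L)`, the Box-Cox quantile form
#' with power `L`, median `M` (kg) and generalized coefficient of variation
#' `S`. As `L -> 0` the form degenerates to the log-normal quantile
#' `M * exp(z*S)`, which is used when `|L| < 1e-8`.
#'
#' @param z standard-normal score(s).
#' @param L Box-Cox power (recycled against `z`).
#' @param M median weight in kg, `> 0`.
#' @param S generalized coefficient of variation, `> 0`.
#' @return weight(s) in kg; strictly increasing in `z`.
#' @examples
#' lms_weight(0, L = -1.5, M = 20, S = 0.12)   # the median, 20 kg
#' lms_weight(2, L = 1, M = 20, S = 0.1)       # reduces to M * (1 + z*S)
#' @export
lms_weight <- function(z, L, M, S) {
  stopifnot(all(M > 0), all(S > 0))
  n <- max(length(z), length(L), length(M), length(S))
  z <- rep_len(z, n); L <- rep_len(L, n); M <- rep_len(M, n); S <- rep_len(S, n)
  w <- numeric(n)
  lim <- abs(L) < 1e-8
  w[lim] <- M[lim] * exp(z[lim] * S[lim])
  if (any(!lim)) {
    base <- 1 + z[!lim] * L[!lim] * S[!lim]
    if (any(base <= 0)) {
      stop("z outside the valid percentile range of the chart: 1 + z*L*S <= 0")
    }
    w[!lim] <- M[!lim] * base^(1 / L[!lim])
  }
  w
}

# Draw n standard-normal scores that land inside the valid LMS domain for a
# given record, redrawing (not clipping) out-of-domain values so the retained
# distribution keeps its shape with no boundary mass. For chart-like
# parameters the rejection probability is astronomically small.
draw_valid_z <- function(n, L, S) {
  z <- stats::rnorm(n)
  if (abs(L) >= 1e-8) {
    repeat {
      bad <- (1 + z * L * S) <= 0
      if (!any(bad)) break
      z[bad] <- stats::rnorm(sum(bad))
    }
  }
  z
}

#' Generate a virtual pediatric weight pool
#'
#' For every age-month in the group's range, draws `n_per_age` standard-normal
#' scores and converts each to a weight through [lms_weight()] with that
#' month's LMS parameters, emulating growth-chart-faithful virtual cohorts.
#'
#' @param lms_table data frame with columns `age_months`, `L`, `M`, `S`
#'   covering every month of the group's range (see [read_lms_table()]).
#' @param group an [age_group()].
#' @param n_per_age subjects generated per age-month (default 100).
#' @param seed integer seed. Draws are seeded per age-month (via
#'   [child_seed()]), so pools built from the same seed are nested: the 2-17
#'   pool restricted to 24-71 months equals the 2-5 pool built from the same
#'   seed.
#' @param shared_z if `TRUE`, one set of `n_per_age` scores is drawn and reused
#'   for every age-month; the default draws independently per month.
#' @return a subject data frame with columns `id`, `cohort` (`"pediatric"`),
#'   `age_months`, `weight_kg`.
#' @examples
#' lms <- synthetic_lms_table()
#' pool <- generate_pediatric_pool(lms, age_group("2-5"), seed = 1)
#' nrow(pool) # 48 months x 100
#' @export
generate_pediatric_pool <- function(lms_table, group, n_per_age = 100L,
                                    seed = NULL, shared_z = FALSE) {
  months <- group$lo:group$hi
  idx <- match(months, lms_table$age_months)
  if (anyNA(idx)) {
    stop("LMS table is missing age-month(s): ",
         paste(months[is.na(idx)], collapse = ", "))
  }
  month_weights <- function(i) {
    L <- lms_table$L[i]; M <- lms_table$M[i]; S <- lms_table$S[i]
    z <- if (shared_z) z_shared else draw_valid_z(n_per_age, L, S)
    if (shared_z && abs(L) >= 1e-8 && any(1 + z * L * S <= 0)) {
      stop("shared z draw falls outside the valid domain for age-month ",
           lms_table$age_months[i])
    }
    lms_weight(z, L, M, S)
  }
  z_shared <- NULL
  if (shared_z) {
    z_shared <- if (is.null(seed)) stats::rnorm(n_per_age) else
      with_seed(child_seed(seed, "shared-z"), stats::rnorm(n_per_age))
  }
  w <- lapply(seq_along(idx), function(k) {
    if (is.null(seed)) month_weights(idx[k]) else
      with_seed(child_seed(seed, "lms-month", months[k]), month_weights(idx[k]))
  })
  data.frame(
    id = seq_len(n_per_age * length(months)),
    cohort = "pediatric",
    age_months = rep(months, each = n_per_age),
    weight_kg = unlist(w)
  )
}

#' Sample a study cohort from a pool
#'
#' Simple random sampling without replacement, deterministic under a fixed
#' seed.
#'
#' @param pool subject data frame.
#' @param n cohort size, `<= nrow(pool)`.
#' @param seed integer seed.
#' @return `n` rows of `pool`.
#' @export
sample_cohort <- function(pool, n, seed = NULL) {
  if (n > nrow(pool)) {
    stop("requested cohort of ", n, " from a pool of ", nrow(pool))
  }
  pick <- function() pool[sample.int(nrow(pool), n), , drop = FALSE]
  out <- if (is.null(seed)) pick() else with_seed(seed, pick())
  rownames(out) <- NULL
  out
}

#' Generate a virtual adult population
#'
#' Adult weights are drawn from a normal distribution truncated to
#' `[lo, hi]` by rejection sampling (draws outside the bounds are redrawn),
#' which reproduces the truncated density exactly. Defaults mirror a healthy
#' adult reference population: mean 70 kg, SD 10 kg, bounds 60-110 kg.
#'
#' @param n number of adults (default 200).
#' @param mean_kg,sd_kg untruncated normal parameters.
#' @param lo,hi truncation bounds in kg, `lo < hi`.
#' @param seed integer seed.
#' @return a subject data frame with `cohort = "adult"` and `age_months = NA`.
#' @export
generate_adult_population <- function(n = 200L, mean_kg = 70, sd_kg = 10,
                                      lo = 60, hi = 110, seed = NULL) {
  stopifnot(lo < hi, sd_kg > 0, n >= 1)
  gen <- function() {
    w <- stats::rnorm(n, mean_kg, sd_kg)
    repeat {
      bad <- w < lo | w > hi
      if (!any(bad)) break
      w[bad] <- stats::rnorm(sum(bad), mean_kg, sd_kg)
    }
    w
  }
  w <- if (is.null(seed)) gen() else with_seed(seed, gen())
  data.frame(id = seq_len(n), cohort = "adult",
             age_months = NA_integer_, weight_kg = w)
}

#' Sample an adult study arm
#'
#' Draws the adult arm of a pooled-analysis scenario from a virtual adult
#' population; by default 20 subjects, the size of a typical first-in-human
#' cohort of healthy volunteers.
#'
#' @inheritParams sample_cohort
#' @export
sample_adult_study <- function(pool, n = 20L, seed = NULL) {
  sample_cohort(pool, n, seed)
}
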