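#' Population PK parameters for the reference monoclonal antibody
#'
#' Constructs the population parameter set of the simulated drug: a
#' one-compartment model with first-order subcutaneous absorption, apparent
#' (per-bioavailability) parameterization, allometric body-weight scaling of
#' V/F and CL/F referenced to 70 kg, correlated log-normal inter-individual
#' variability (IIV) on all three structural parameters, and proportional
#' residual error. Defaults are the reference mAb values: V/F 18 L (46% IIV),
#' CL/F 1 L/day (49% IIV), Ka 0.9 /day (50% IIV), V-CL correlation 0.7,
#' proportional residual SD 25%, allometric exponents 1.0 (V/F) and
#' 0.75 (CL/F).
#'
#' `iiv_mapping` controls how an IIV percentage maps to the variance of the
#' normal random effect eta: `"lognormal_exact"` (default) uses
#' `var(eta) = log(1 + CV^2)`, the exact log-normal relation; `"cv_as_sd"`
#' uses the common approximation `sd(eta) = CV`. At CVs near 0.5 the two
#' differ by a few percent of the SD, enough to matter in recovery studies.
#'
#' @param tv_v,tv_cl,tv_ka typical values: L, L/day, 1/day.
#' @param cv_v,cv_cl,cv_ka fractional IIV coefficients of variation.
#' @param corr_v_cl correlation of the V and CL random effects, in (-1, 1).
#' @param sigma_prop fractional proportional residual SD.
#' @param exp_v,exp_cl allometric exponents of V/F and CL/F.
#' @param ref_weight allometric reference weight in kg.
#' @param iiv_mapping `"lognormal_exact"` or `"cv_as_sd"`.
#' @return an object of class `pedallo_pkpars` (a list).
#' @examples
#' pk_params()                      # the reference mAb
#' pk_params(cv_v = 0, cv_cl = 0, cv_ka = 0, sigma_prop = 0)  # noise-free
#' @export
pk_params <- function(tv_v = 18, tv_cl = 1, tv_ka = 0.9,
                      cv_v = 0.46, cv_cl = 0.49, cv_ka = 0.50,
                      corr_v_cl = 0.7, sigma_prop = 0.25,
                      exp_v = 1.0, exp_cl = 0.75, ref_weight = 70,
                      iiv_mapping = c("lognormal_exact", "cv_as_sd")) {
  iiv_mapping <- match.arg(iiv_mapping)
  stopifnot(tv_v > 0, tv_cl > 0, tv_ka > 0, ref_weight > 0,
            cv_v >= 0, cv_cl >= 0, cv_ka >= 0,
            abs(corr_v_cl) < 1, sigma_prop >= 0)
  structure(list(tv_v = tv_v, tv_cl = tv_cl, tv_ka = tv_ka,
                 cv_v = cv_v, cv_cl = cv_cl, cv_ka = cv_ka,
                 corr_v_cl = corr_v_cl, sigma_prop = sigma_prop,
                 exp_v = exp_v, exp_cl = exp_cl, ref_weight = ref_weight,
                 iiv_mapping = iiv_mapping),
            class = "pedallo_pkpars")
}

cv_to_eta_sd <- function(cv, mapping) {
  if (mapping == "lognormal_exact") sqrt(log(1 + cv^2)) else cv
}

eta_sd_to_cv <- function(sd, mapping) {
  if (mapping == "lognormal_exact") sqrt(exp(sd^2) - 1) else sd
}

#' Random-effect covariance matrix
#'
#' The 3x3 covariance of `(eta_V, eta_CL, eta_Ka)` implied by the population
#' parameters: diagonal variances from the IIV CVs via the configured mapping,
#' covariance `corr * sd_V * sd_CL` between V and CL, Ka independent.
#'
#' @param pop a [pk_params()] object.
#' @return 3x3 covariance matrix.
#' @export
eta_cov <- function(pop) {
  s <- c(cv_to_eta_sd(pop$cv_v, pop$iiv_mapping),
         cv_to_eta_sd(pop$cv_cl, pop$iiv_mapping),
         cv_to_eta_sd(pop$cv_ka, pop$iiv_mapping))
  om <- diag(s^2, 3)
  om[1, 2] <- om[2, 1] <- pop$corr_v_cl * s[1] * s[2]
  dimnames(om) <- list(c("eta_v", "eta_cl", "eta_ka"),
                       c("eta_v", "eta_cl", "eta_ka"))
  om
}

#' Draw inter-individual random effects
#'
#' Draws `n` independent mean-zero trivariate-normal eta vectors with the
#' covariance implied by the population parameters.
#'
#' @param n number of subjects.
#' @param pop a [pk_params()] object.
#' @param seed integer seed.
#' @return an `n x 3` matrix with columns `eta_v`, `eta_cl`, `eta_ka`.
#' @export
draw_etas <- function(n, pop, seed = NULL) {
  om <- eta_cov(pop)
  ev <- eigen(om, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-12)) stop("eta covariance is not positive semi-definite")
  gen <- function() {
    if (all(om == 0)) {
      matrix(0, n, 3)
    } else {
      MASS::mvrnorm(n, mu = c(0, 0, 0), Sigma = om)
    }
  }
  e <- if (is.null(seed)) gen() else with_seed(seed, gen())
  e <- matrix(e, n, 3)
  colnames(e) <- c("eta_v", "eta_cl", "eta_ka")
  e
}

#' Individual PK parameters from weight and random effects
#'
#' Applies the allometric covariate model and log-normal IIV:
#' `V/F  = TV  * exp(eta_V)  * (WT/ref)^exp_v`,
#' `CL/F = TCL * exp(eta_CL) * (WT/ref)^exp_cl`,
#' `Ka   = TKa * exp(eta_Ka)`.
#'
#' @param weight_kg body weight(s) in kg.
#' @param pop a [pk_params()] object.
#' @param eta matrix (or length-3 vector) of random effects, columns
#'   `(eta_v, eta_cl, eta_ka)`; defaults to zeros (the typical subject).
#' @return data frame with columns `v`, `cl`, `ka`.
#' @examples
#' individual_params(70, pk_params())   # 18 L, 1 L/day, 0.9 /day
#' @export
individual_params <- function(weight_kg, pop, eta = NULL) {
  stopifnot(all(weight_kg > 0))
  n <- length(weight_kg)
  if (is.null(eta)) eta <- matrix(0, n, 3)
  if (is.null(dim(eta))) eta <- matrix(eta, ncol = 3)
  wr <- weight_kg / pop$ref_weight
  data.frame(
    v  = pop$tv_v  * exp(eta[, 1]) * wr^pop$exp_v,
    cl = pop$tv_cl * exp(eta[, 2]) * wr^pop$exp_cl,
    ka = pop$tv_ka * exp(eta[, 3])
  )
}

#' Closed-form concentration profile
#'
#' One-compartment, first-order absorption after a single extravascular dose
#' at time zero, apparent parameterization:
#' `C(t) = dose*ka / (v*(ka - ke)) * (exp(-ke*t) - exp(-ka*t))` with
#' `ke = cl/v`. When `ka` and `ke` coincide to within a relative 1e-8 the
#' degenerate limit `C(t) = dose*ka*t/v * exp(-ka*t)` is used.
#'
#' @param times days, `>= 0` (vector).
#' @param dose_mg dose in mg.
#' @param v,cl,ka individual parameters (L, L/day, 1/day), all `> 0`.
#' @return concentrations in mg/L at `times`.
#' @examples
#' p <- individual_params(70, pk_params())
#' conc_profile(c(0, 4, 14, 56), dose_mg = 140, v = p$v, cl = p$cl, ka = p$ka)
#' @export
conc_profile <- function(times, dose_mg, v, cl, ka) {
  stopifnot(all(times >= 0), dose_mg > 0, v > 0, cl > 0, ka > 0)
  ke <- cl / v
  if (abs(ka - ke) < 1e-8 * ke) {
    dose_mg * ka * times / v * exp(-ka * times)
  } else {
    dose_mg * ka / (v * (ka - ke)) * (exp(-ke * times) - exp(-ka * times))
  }
}

#' PK sampling schemes
#'
#' Builds a sampling scheme: nominal sampling days within the 56-day horizon
#' plus a total sampling-window width (default 0.6 days, i.e. each realized
#' time is uniform within +/- 0.3 days of nominal). Built-in schemes:
#' \describe{
#'   \item{`ped_sparse`}{days 4, 14, 28 — peak plus two terminal-phase samples.}
#'   \item{`ped_standard`}{days 1, 2, 4, 14, 28.}
#'   \item{`ped_dense`}{days 1, 2, 4, 7, 14, 28, 42, 56.}
#'   \item{`adult_dense`}{days 1, 2, 4, 7, 14, 28, 42, 56 (intensive phase-1).}
#'   \item{`adult_dense_7pt`}{days 1, 2, 4, 7, 14, 28, 56.}
#' }
#'
#' @param scheme a built-in name or a numeric vector of nominal days.
#' @param window_days total window width in days (default 0.6).
#' @return an object of class `pedallo_scheme`.
#' @examples
#' sampling_scheme("ped_sparse")
#' sampling_scheme(c(7, 28), window_days = 0)
#' @export
sampling_scheme <- function(scheme = "ped_standard", window_days = 0.6) {
  builtin <- list(
    ped_sparse     = c(4, 14, 28),
    ped_standard   = c(1, 2, 4, 14, 28),
    ped_dense      = c(1, 2, 4, 7, 14, 28, 42, 56),
    adult_dense    = c(1, 2, 4, 7, 14, 28, 42, 56),
    adult_dense_7pt = c(1, 2, 4, 7, 14, 28, 56)
  )
  if (is.character(scheme)) {
    if (!scheme %in% names(builtin)) {
      stop("unknown scheme '", scheme, "'; built-ins: ",
           paste(names(builtin), collapse = ", "))
    }
    days <- builtin[[scheme]]
    name <- scheme
  } else {
    days <- sort(as.numeric(scheme))
    name <- paste(days, collapse = "_")
  }
  stopifnot(all(days >= 0), all(days <= 56), window_days >= 0)
  structure(list(name = name, nominal_days = days, window_days = window_days),
            class = "pedallo_scheme")
}

#' Realize jittered sampling times
#'
#' Draws each subject's actual sampling time for nominal day `d` uniformly on
#' `[d - w/2, d + w/2]` (total window `w`), floored at zero; within a subject
#' the times must be strictly increasing, and draws breaking monotonicity are
#' redrawn (impossible for the built-in schemes, whose nominal days are more
#' than one window apart).
#'
#' @param scheme a [sampling_scheme()].
#' @param n_subjects number of subjects.
#' @param seed integer seed.
#' @return matrix `n_subjects x length(nominal_days)` of times in days.
#' @export
realize_sampling_times <- function(scheme, n_subjects, seed = NULL) {
  d <- scheme$nominal_days
  w <- scheme$window_days / 2
  gen <- function() {
    tm <- matrix(stats::runif(n_subjects * length(d),
                              rep(d, each = n_subjects) - w,
                              rep(d, each = n_subjects) + w),
                 n_subjects, length(d))
    tm[tm < 0] <- 0
    if (length(d) > 1) {
      repeat {
        bad <- which(t(apply(tm, 1, diff)) <= 0, arr.ind = TRUE)
        if (length(bad) == 0) break
        j <- bad[, 2] + 1L # redraw the later of each offending pair
        tm[cbind(bad[, 1], j)] <-
          pmax(0, stats::runif(nrow(bad), d[j] - w, d[j] + w))
      }
    }
    tm
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Simulate a PK study dataset
#'
#' Runs the full simulation for one cohort: per-subject random effects,
#' weight-based dosing (`dose_per_kg * weight` mg subcutaneously at time 0),
#' jittered sampling times, closed-form concentrations, and proportional
#' residual error `DV = C * (1 + eps)`, `eps ~ N(0, sigma_prop^2)` independent
#' per sample (no truncation at zero and no quantification limit).
#'
#' @param cohort subject data frame (see [generate_pediatric_pool()]).
#' @param pop a [pk_params()] object.
#' @param scheme a [sampling_scheme()].
#' @param dose_per_kg mg/kg (default 2).
#' @param seed integer seed.
#' @return a NONMEM-style rectangular data frame with columns `ID`, `TIME`,
#'   `AMT`, `DV`, `EVID`, `MDV`, `WT`, `COHORT`, `NOMDAY`: one dose row
#'   (`EVID = 1`, `MDV = 1`, `DV = NA`) then one observation row per sample
#'   (`EVID = 0`, `MDV = 0`, `AMT = NA`) per subject.
#' @examples
#' kids <- generate_pediatric_pool(synthetic_lms_table(), age_group("2-17"),
#'                                 n_per_age = 2, seed = 1)
#' ds <- simulate_dataset(sample_cohort(kids, 6, seed = 2), pk_params(),
#'                        sampling_scheme("ped_sparse"), seed = 3)
#' head(ds)
#' @export
simulate_dataset <- function(cohort, pop, scheme, dose_per_kg = 2,
                             seed = NULL) {
  stopifnot(nrow(cohort) > 0)
  run <- function() {
    n <- nrow(cohort)
    eta <- draw_etas(n, pop)
    ip <- individual_params(cohort$weight_kg, pop, eta)
    tms <- realize_sampling_times(scheme, n)
    k <- length(scheme$nominal_days)
    dose <- dose_per_kg * cohort$weight_kg
    rows <- lapply(seq_len(n), function(i) {
      conc <- conc_profile(tms[i, ], dose[i], ip$v[i], ip$cl[i], ip$ka[i])
      dv <- conc * (1 + stats::rnorm(k, 0, pop$sigma_prop))
      data.frame(
        ID = i,
        TIME = c(0, tms[i, ]),
        AMT = c(dose[i], rep(NA_real_, k)),
        DV = c(NA_real_, dv),
        EVID = c(1L, rep(0L, k)),
        MDV = c(1L, rep(0L, k)),
        WT = cohort$weight_kg[i],
        COHORT = cohort$cohort[i],
        NOMDAY = c(NA_real_, scheme$nominal_days)
      )
    })
    do.call(rbind, rows)
  }
  out <- if (is.null(seed)) run() else with_seed(seed, run())
  rownames(out) <- NULL
  out
}
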