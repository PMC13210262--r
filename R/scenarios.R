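#' Define one design cell of the simulation-estimation study
#'
#' A scenario is one cell of the design grid: an age group, a pediatric sample
#' size, a sampling scheme, optionally a pooled densely-sampled adult arm, and
#' a replicate count. Each replicate regenerates the weight pool, samples a
#' cohort, simulates a dataset, and refits the population model with the
#' allometric exponents free.
#'
#' @param age_group age-group label (see [age_group()]).
#' @param n_pediatric pediatric sample size; the study menu is
#'   30, 60, 120, 200, 240 (other values are allowed but flagged).
#' @param scheme pediatric [sampling_scheme()] or built-in name.
#' @param pool_adults append an intensively sampled adult arm (default FALSE).
#' @param n_adults adult arm size (default 20, from a 200-adult pool).
#' @param adult_scheme adult [sampling_scheme()] or name (default
#'   `"adult_dense"`).
#' @param n_replicates replicates of the full cycle (default 100).
#' @param master_seed master seed; replicate seeds are derived with
#'   [child_seed()].
#' @param pop generating [pk_params()].
#' @param lms_table LMS table (default: the packaged synthetic table).
#' @param n_per_age pool draws per age-month (default 100).
#' @param dose_per_kg mg/kg (default 2, both cohorts).
#' @param estimation an [estimation_spec()].
#' @param id scenario identifier; auto-built from the design factors.
#' @return an object of class `pedallo_scenario_spec`.
#' @examples
#' scenario_spec("2-17", n_pediatric = 60, scheme = "ped_standard",
#'               n_replicates = 5, master_seed = 42)
#' @export
scenario_spec <- function(age_group = "2-17", n_pediatric = 60,
                          scheme = "ped_sparse", pool_adults = FALSE,
                          n_adults = 20L, adult_scheme = "adult_dense",
                          n_replicates = 100L, master_seed = 1L,
                          pop = pk_params(), lms_table = NULL,
                          n_per_age = 100L, dose_per_kg = 2,
                          estimation = estimation_spec(), id = NULL) {
  grp <- if (is.list(age_group)) age_group else pedallo::age_group(age_group)
  if (!inherits(scheme, "pedallo_scheme")) scheme <- sampling_scheme(scheme)
  if (!inherits(adult_scheme, "pedallo_scheme")) {
    adult_scheme <- sampling_scheme(adult_scheme)
  }
  if (!n_pediatric %in% c(30, 60, 120, 200, 240)) {
    warning("n_pediatric = ", n_pediatric,
            " is outside the study menu {30, 60, 120, 200, 240}")
  }
  if (is.null(lms_table)) lms_table <- synthetic_lms_table()
  if (is.null(id)) {
    id <- paste0(grp$label, "_n", n_pediatric, "_", scheme$name,
                 if (pool_adults) "_adult" else "")
  }
  structure(list(age_group = grp, n_pediatric = as.integer(n_pediatric),
                 scheme = scheme, pool_adults = isTRUE(pool_adults),
                 n_adults = as.integer(n_adults), adult_scheme = adult_scheme,
                 n_replicates = as.integer(n_replicates),
                 master_seed = as.integer(master_seed), pop = pop,
                 lms_table = lms_table, n_per_age = as.integer(n_per_age),
                 dose_per_kg = dose_per_kg, estimation = estimation, id = id),
            class = "pedallo_scenario_spec")
}

# stage seeds are keyed by the design factors that shape the pediatric data
# only, so a pooled and an unpooled scenario share identical pediatric draws
# at the same replicate
replicate_seeds <- function(spec, replicate) {
  key <- paste(spec$age_group$label, spec$n_pediatric, spec$scheme$name,
               sep = "|")
  s <- function(stage) child_seed(spec$master_seed, key, replicate, stage)
  list(ped_pool = s(1L), ped_cohort = s(2L), ped_sim = s(3L),
       adult_pool = s(4L), adult_cohort = s(5L), adult_sim = s(6L),
       fit = s(7L))
}

#' Run one replicate of a scenario
#'
#' One full cycle — regenerate the pediatric pool, sample the cohort, simulate
#' the dataset (plus the adult arm when pooling), fit, extract the exponents.
#' Fully determined by `(master_seed, replicate)`.
#'
#' @param spec a [scenario_spec()].
#' @param replicate replicate index (1-based).
#' @return list with `exp_v`, `exp_cl`, `fit` (a `pedallo_fit`), and `dataset`.
#' @export
run_replicate <- function(spec, replicate) {
  seeds <- replicate_seeds(spec, replicate)
  pool <- generate_pediatric_pool(spec$lms_table, spec$age_group,
                                  n_per_age = spec$n_per_age,
                                  seed = seeds$ped_pool)
  cohort <- sample_cohort(pool, spec$n_pediatric, seed = seeds$ped_cohort)
  ds <- simulate_dataset(cohort, spec$pop, spec$scheme,
                         dose_per_kg = spec$dose_per_kg, seed = seeds$ped_sim)
  if (spec$pool_adults) {
    apop <- generate_adult_population(seed = seeds$adult_pool)
    astudy <- sample_adult_study(apop, spec$n_adults, seed = seeds$adult_cohort)
    ads <- simulate_dataset(astudy, spec$pop, spec$adult_scheme,
                            dose_per_kg = spec$dose_per_kg,
                            seed = seeds$adult_sim)
    ads$ID <- ads$ID + max(ds$ID)
    ds <- rbind(ds, ads)
  }
  fit <- fit_nlme(ds, spec$estimation, seed = seeds$fit)
  list(exp_v = fit$exp_v, exp_cl = fit$exp_cl, fit = fit, dataset = ds)
}

#' Run a scenario
#'
#' Executes `n_replicates` independent replicates and summarizes the exponent
#' estimates over the converged ones: median, quartiles (type-7), IQR width
#' and bias against the generating values. A scenario with more than 50%
#' non-convergence is flagged unreliable.
#'
#' @param spec a [scenario_spec()].
#' @param verbose print one line per replicate.
#' @return an object of class `pedallo_scenario_result`: list with `spec`,
#'   `replicates` (a data frame of per-replicate estimates), `summary`
#'   (one row per exponent), `convergence_rate`, `reliable`.
#' @export
run_scenario <- function(spec, verbose = FALSE) {
  reps <- lapply(seq_len(spec$n_replicates), function(i) {
    r <- run_replicate(spec, i)
    if (verbose) {
      message(sprintf("[%s] replicate %d/%d: exp_v=%.3f exp_cl=%.3f %s",
                      spec$id, i, spec$n_replicates, r$exp_v, r$exp_cl,
                      if (r$fit$converged) "converged" else "FAILED"))
    }
    data.frame(replicate = i, exp_v = r$exp_v, exp_cl = r$exp_cl,
               converged = r$fit$converged, objective = r$fit$objective)
  })
  reps <- do.call(rbind, reps)
  conv <- reps[reps$converged & is.finite(reps$exp_v) & is.finite(reps$exp_cl),
               , drop = FALSE]
  summarize_exp <- function(est, truth, name) {
    if (nrow(conv) == 0) {
      return(data.frame(exponent = name, truth = truth, n_converged = 0L,
                        median = NA_real_, q25 = NA_real_, q75 = NA_real_,
                        iqr_width = NA_real_, bias = NA_real_))
    }
    b <- exponent_bias(est, truth)
    data.frame(exponent = name, truth = truth, n_converged = nrow(conv),
               median = stats::median(est), q25 = b$q25, q75 = b$q75,
               iqr_width = b$q75 - b$q25, bias = b$bias)
  }
  summ <- rbind(
    summarize_exp(conv$exp_v, spec$pop$exp_v, "exp_v"),
    summarize_exp(conv$exp_cl, spec$pop$exp_cl, "exp_cl")
  )
  rate <- mean(reps$converged)
  structure(list(spec = spec, replicates = reps, summary = summ,
                 convergence_rate = rate, reliable = rate >= 0.5),
            class = "pedallo_scenario_result")
}

#' @export
print.pedallo_scenario_result <- function(x, ...) {
  cat(sprintf("Scenario %s: %d replicates, %.0f%% converged%s\n",
              x$spec$id, x$spec$n_replicates, 100 * x$convergence_rate,
              if (!x$reliable) " [UNRELIABLE]" else ""))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Run a grid of scenarios
#'
#' Maps [run_scenario()] over a list of specs, assembling one tidy results
#' table (one row per scenario and exponent). Individual scenario failures
#' are recorded and the grid continues.
#'
#' @param specs list of [scenario_spec()] objects.
#' @param verbose forwarded to [run_scenario()].
#' @return list with `table` (data frame) and `results` (the per-scenario
#'   result objects, `NULL` where a scenario errored).
#' @export
run_grid <- function(specs, verbose = FALSE) {
  results <- vector("list", length(specs))
  rows <- list()
  for (k in seq_along(specs)) {
    spec <- specs[[k]]
    res <- tryCatch(run_scenario(spec, verbose = verbose), error = identity)
    if (inherits(res, "error")) {
      warning("scenario ", spec$id, " failed: ", conditionMessage(res))
      next
    }
    results[[k]] <- res
    s <- res$summary
    rows[[length(rows) + 1L]] <- data.frame(
      scenario = spec$id, age_group = spec$age_group$label,
      n_pediatric = spec$n_pediatric, scheme = spec$scheme$name,
      pool_adults = spec$pool_adults,
      convergence_rate = res$convergence_rate, reliable = res$reliable,
      exponent = s$exponent, truth = s$truth, median = s$median,
      q25 = s$q25, q75 = s$q75, iqr_width = s$iqr_width, bias = s$bias
    )
  }
  tab <- if (length(rows)) do.call(rbind, rows) else data.frame()
  rownames(tab) <- NULL
  list(table = tab, results = results)
}
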