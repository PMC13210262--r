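# Shared fixtures and a memoised scenario-cell runner (several acceptance
# checks read different aspects of the same design cells; each cell is
# computed once per test run).

fixture_lms <- synthetic_lms_table()

make_tiny_cohort <- function(weights, cohort = "pediatric") {
  data.frame(id = seq_along(weights), cohort = cohort,
             age_months = ifelse(cohort == "pediatric", 100L, NA_integer_),
             weight_kg = weights)
}

.acc_cells <- new.env(parent = emptyenv())

acc_cell <- function(age, n, scheme, pooled = FALSE, reps = 25,
                     seed = 20260515) {
  key <- paste(age, n, scheme, pooled, reps, seed, sep = "|")
  if (is.null(.acc_cells[[key]])) {
    sp <- scenario_spec(age, n_pediatric = n, scheme = scheme,
                        pool_adults = pooled, n_replicates = reps,
                        master_seed = seed)
    .acc_cells[[key]] <- run_scenario(sp)
  }
  .acc_cells[[key]]
}

cell_width <- function(cell, exponent) {
  s <- cell$summary
  s$iqr_width[s$exponent == exponent]
}
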