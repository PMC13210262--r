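# Delimited-text interchange: NONMEM-style datasets, subject tables, study
# configuration, and the run manifest. Everything is plain UTF-8 text with
# '.' as the decimal point; missing fields are written empty.

#' Write a PK dataset as NONMEM-style CSV
#'
#' Columns `ID, TIME, AMT, DV, EVID, MDV, WT, COHORT, NOMDAY`; dose rows carry
#' `EVID = 1`, `MDV = 1` and an empty `DV`; observation rows carry `EVID = 0`,
#' `MDV = 0` and an empty `AMT`. The round trip through [read_dataset()] is
#' exact.
#'
#' @param dataset data frame from [simulate_dataset()] or [read_dataset()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  cols <- c("ID", "TIME", "AMT", "DV", "EVID", "MDV", "WT", "COHORT", "NOMDAY")
  stopifnot(all(cols %in% names(dataset)))
  out <- dataset[, cols]
  fmt <- function(x) {
    s <- vapply(x, function(v) {
      if (is.na(v)) "" else format(v, digits = 17, scientific = FALSE)
    }, character(1))
    s
  }
  lines <- c(paste(cols, collapse = ","),
             apply(cbind(fmt(out$ID), fmt(out$TIME), fmt(out$AMT), fmt(out$DV),
                         fmt(out$EVID), fmt(out$MDV), fmt(out$WT),
                         ifelse(is.na(out$COHORT), "", out$COHORT),
                         fmt(out$NOMDAY)),
                   1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a NONMEM-style CSV dataset
#'
#' Validates the column contract of [write_dataset()]: observation rows
#' (`EVID = 0`) must have a `DV` and `MDV = 0`; dose rows (`EVID = 1`) must
#' have an `AMT` and `MDV = 1`. Violations are reported with their line
#' numbers.
#'
#' @param path input file.
#' @return the dataset data frame.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("dataset not found: ", path)
  ds <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  req <- c("ID", "TIME", "AMT", "DV", "EVID", "MDV", "WT")
  miss <- setdiff(req, names(ds))
  if (length(miss)) stop("dataset lacks columns: ", paste(miss, collapse = ", "))
  line <- seq_len(nrow(ds)) + 1L # header is line 1
  bad_obs <- ds$EVID == 0 & (is.na(ds$DV) | ds$MDV != 0)
  if (any(bad_obs)) {
    stop("observation rows with missing DV or MDV != 0 at line(s): ",
         paste(line[bad_obs], collapse = ", "))
  }
  bad_dose <- ds$EVID == 1 & (is.na(ds$AMT) | ds$MDV != 1)
  if (any(bad_dose)) {
    stop("dose rows with missing AMT or MDV != 1 at line(s): ",
         paste(line[bad_dose], collapse = ", "))
  }
  if (!"COHORT" %in% names(ds)) ds$COHORT <- NA_character_
  if (!"NOMDAY" %in% names(ds)) ds$NOMDAY <- NA_real_
  for (col in c("TIME", "AMT", "DV", "WT", "NOMDAY")) ds[[col]] <- as.numeric(ds[[col]])
  for (col in c("ID", "EVID", "MDV")) ds[[col]] <- as.integer(ds[[col]])
  ds
}

#' Write / read a subject table
#'
#' Delimited text with header `id, cohort, age_months, weight_kg`.
#'
#' @param subjects subject data frame.
#' @param path file path.
#' @return `path` (write) or the subject data frame (read).
#' @export
write_subjects <- function(subjects, path) {
  utils::write.csv(subjects[, c("id", "cohort", "age_months", "weight_kg")],
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_subjects
#' @export
read_subjects <- function(path) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  stopifnot(all(c("id", "cohort", "age_months", "weight_kg") %in% names(s)))
  s
}

#' Load a study configuration
#'
#' Reads a YAML study definition into a list of [scenario_spec()]s. Top-level
#' keys `master_seed`, `n_replicates`, `lms_table` (a path; omitted means the
#' packaged synthetic table), `sex_mode`, and `pop` (overrides for
#' [pk_params()]) set defaults; each entry of `scenarios:` takes
#' `age_group`, `n_pediatric`, `scheme`, `pool_adults`, `n_adults`,
#' `adult_scheme`, `n_replicates`, `id`. Unknown keys are warned about and
#' ignored.
#'
#' @param path YAML file.
#' @return list of `pedallo_scenario_spec`.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known_top <- c("master_seed", "n_replicates", "lms_table", "sex_mode",
                 "pop", "scenarios")
  extra <- setdiff(names(cfg), known_top)
  if (length(extra)) warning("ignoring unknown config keys: ",
                             paste(extra, collapse = ", "))
  if (is.null(cfg$scenarios)) stop("config has no 'scenarios' list")
  lms <- if (!is.null(cfg$lms_table)) {
    read_lms_table(cfg$lms_table,
                   sex_mode = if (is.null(cfg$sex_mode)) "combined" else cfg$sex_mode)
  } else {
    synthetic_lms_table()
  }
  pop <- do.call(pk_params, if (is.null(cfg$pop)) list() else cfg$pop)
  lapply(cfg$scenarios, function(sc) {
    known <- c("age_group", "n_pediatric", "scheme", "pool_adults", "n_adults",
               "adult_scheme", "n_replicates", "id")
    extra <- setdiff(names(sc), known)
    if (length(extra)) warning("ignoring unknown scenario keys: ",
                               paste(extra, collapse = ", "))
    scenario_spec(
      age_group = if (is.null(sc$age_group)) "2-17" else sc$age_group,
      n_pediatric = if (is.null(sc$n_pediatric)) 60 else sc$n_pediatric,
      scheme = if (is.null(sc$scheme)) "ped_sparse" else sc$scheme,
      pool_adults = isTRUE(sc$pool_adults),
      n_adults = if (is.null(sc$n_adults)) 20L else sc$n_adults,
      adult_scheme = if (is.null(sc$adult_scheme)) "adult_dense" else sc$adult_scheme,
      n_replicates = if (!is.null(sc$n_replicates)) sc$n_replicates
                     else if (!is.null(cfg$n_replicates)) cfg$n_replicates
                     else 100L,
      master_seed = if (is.null(cfg$master_seed)) 1L else cfg$master_seed,
      pop = pop, lms_table = lms, id = sc$id
    )
  })
}

#' Write a run manifest
#'
#' Records what a study run did — package version, master seed, the scenario
#' grid, per-scenario convergence rates, and the files written — as YAML,
#' sufficient to reproduce the run.
#'
#' @param path output file.
#' @param specs list of scenario specs that were run.
#' @param grid result of [run_grid()].
#' @param files character vector of output files written.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, specs, grid, files = character()) {
  manifest <- list(
    package = "pedallo",
    version = as.character(utils::packageVersion("pedallo")),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    scenarios = lapply(specs, function(s) {
      list(id = s$id, age_group = s$age_group$label,
           n_pediatric = s$n_pediatric, scheme = s$scheme$name,
           pool_adults = s$pool_adults, n_replicates = s$n_replicates,
           master_seed = s$master_seed)
    }),
    convergence_rates = if (nrow(grid$table)) {
      stats::setNames(as.list(
        grid$table$convergence_rate[!duplicated(grid$table$scenario)]),
        grid$table$scenario[!duplicated(grid$table$scenario)])
    } else {
      list()
    },
    files = as.list(files)
  )
  yaml::write_yaml(manifest, path)
  invisible(path)
}
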