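#' Synthetic LMS weight-for-age table
#'
#' A smooth, monotone-in-age LMS parameterization covering 24-215 months,
#' emulating the shape of combined-sex weight-for-age growth-chart curves:
#' a near-linear childhood median with a logistic pubertal acceleration, a
#' coefficient of variation that peaks around puberty, and a moderately
#' negative (right-skew) Box-Cox power. The table is synthetic: it is not the
#' official CDC chart, and analyses meant to reproduce chart-faithful weight
#' distributions should load the official table with [read_lms_table()].
#'
#' A copy of this table ships as `inst/extdata/lms_synthetic.csv`.
#'
#' @param months integer vector of age-months (default 24:215).
#' @return data frame with columns `age_months`, `L`, `M`, `S`.
#' @examples
#' head(synthetic_lms_table())
#' @export
synthetic_lms_table <- function(months = 24:215) {
  m <- as.integer(months)
  data.frame(
    age_months = m,
    L = -1.1 - 0.5 / (1 + exp(-(m - 120) / 40)),
    M = 12.2 + 0.10 * (m - 24) + 42 / (1 + exp(-(m - 168) / 26)),
    S = 0.11 + 0.045 * exp(-((m - 150) / 55)^2)
  )
}

#' Read an LMS weight-for-age table
#'
#' Reads a delimited LMS parameter table. Two layouts are accepted:
#' the packaged synthetic layout (`age_months, L, M, S`) and the official
#' CDC weight-for-age layout (`Sex, Agemos, L, M, S`, sex coded 1 = male,
#' 2 = female, `Agemos` possibly on a half-month grid, which is floored to
#' integer months). Rows are restricted to the pediatric range 24-215 months.
#'
#' When the table is sex-stratified, `sex_mode = "combined"` (the default)
#' averages `L`, `M` and `S` across the sexes per age-month; `"male"` or
#' `"female"` selects one sex.
#'
#' @param path path to a comma/tab-delimited text file with a header.
#' @param sex_mode `"combined"`, `"male"` or `"female"`.
#' @return data frame with columns `age_months`, `L`, `M`, `S`, one row per
#'   age-month, sorted by age.
#' @examples
#' path <- system.file("extdata", "lms_synthetic.csv", package = "pedallo")
#' lms <- read_lms_table(path)
#' range(lms$age_months)
#' @export
read_lms_table <- function(path, sex_mode = c("combined", "male", "female")) {
  sex_mode <- match.arg(sex_mode)
  if (!file.exists(path)) stop("LMS table not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = guess_sep(path),
                           stringsAsFactors = FALSE)
  names(raw) <- tolower(names(raw))
  age_col <- intersect(c("age_months", "agemos"), names(raw))[1]
  if (is.na(age_col) || !all(c("l", "m", "s") %in% names(raw))) {
    stop("LMS table must have columns age_months (or Agemos), L, M, S; got: ",
         paste(names(raw), collapse = ", "))
  }
  tab <- data.frame(
    age_months = as.integer(floor(as.numeric(raw[[age_col]]))),
    L = as.numeric(raw$l), M = as.numeric(raw$m), S = as.numeric(raw$s),
    sex = if ("sex" %in% names(raw)) as.integer(raw$sex) else NA_integer_
  )
  if (sex_mode != "combined") {
    if (all(is.na(tab$sex))) {
      stop("sex_mode = '", sex_mode, "' requested but the table has no Sex column")
    }
    tab <- tab[tab$sex == if (sex_mode == "male") 1L else 2L, , drop = FALSE]
  }
  tab <- tab[tab$age_months >= 24 & tab$age_months <= 215, , drop = FALSE]
  if (nrow(tab) == 0) stop("LMS table has no rows in the 24-215 month range")
  # collapse duplicates (the two sexes in combined mode, or sub-month grids)
  out <- do.call(rbind, lapply(split(tab, tab$age_months), function(d) {
    data.frame(age_months = d$age_months[1],
               L = mean(d$L), M = mean(d$M), S = mean(d$S))
  }))
  out <- out[order(out$age_months), , drop = FALSE]
  rownames(out) <- NULL
  if (any(out$M <= 0) || any(out$S <= 0)) {
    stop("LMS table contains nonpositive M or S values")
  }
  if (any(diff(out$age_months) <= 0)) stop("LMS ages are not strictly increasing")
  out
}

guess_sep <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\t", first)) "\t" else if (grepl(";", first)) ";" else ","
}
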