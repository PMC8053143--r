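#' Synthetic female life table (Gompertz-Makeham)
#'
#' Generates a single-year life table of annual death probabilities from a
#' Gompertz-Makeham hazard, `qx(age) = 1 - exp(-(c + a * exp(b * age)))`.
#' This is a calibrated stand-in for an official abridged life table so that
#' the whole pipeline can run and be tested without external data; it is a
#' synthetic fixture, not an estimate of Japanese mortality. Under the default
#' calibration the probability of dying by age 105 from any starting age of
#' 70, 75 or 80 exceeds 99%.
#'
#' @param a Gompertz level parameter (> 0).
#' @param b Gompertz slope per year of age (> 0).
#' @param c Makeham age-independent hazard (>= 0).
#' @param from,to First and last tabulated age.
#' @return A `life_table` object: data frame with columns `age` and `qx`.
#' @export
#' @examples
#' lt <- make_synthetic_life_table()
#' head(lt)
make_synthetic_life_table <- function(a = 1.0e-5, b = 0.11, c = 2.0e-4,
                                      from = 60, to = 105) {
  if (!(a > 0) || !(b > 0)) stop("Gompertz parameters a and b must be > 0")
  if (c < 0) stop("Makeham constant c must be >= 0")
  ages <- as.integer(seq(from, to))
  haz <- c + a * exp(b * ages)
  qx <- pmin(1, 1 - exp(-haz))
  new_life_table(data.frame(age = ages, qx = qx))
}

new_life_table <- function(df) {
  structure(df, class = c("life_table", "data.frame"))
}

validate_life_table <- function(df, require_cover = c(70, 105)) {
  if (!all(c("age", "qx") %in% names(df)))
    stop("life table must have columns 'age' and 'qx'")
  if (nrow(df) < 2 || any(diff(df$age) != 1))
    stop("life table ages must be contiguous single years, strictly increasing")
  missing_cover <- setdiff(seq(require_cover[1], require_cover[2]), df$age)
  if (length(missing_cover) > 0)
    stop(sprintf("life table must cover ages %d..%d; missing: %s",
                 require_cover[1], require_cover[2],
                 paste(utils::head(missing_cover, 5), collapse = ", ")))
  if (any(df$qx <= 0) || any(df$qx > 1))
    stop("qx values must lie in (0, 1]")
  invisible(df)
}

#' Read a life table from CSV
#'
#' Expects a UTF-8 CSV with header `age,qx` and no thousands separators. A
#' single-year table (ages increasing by 1) is validated and returned as is.
#' An abridged table (ages increasing by 5) is expanded to single years by
#' assuming a constant `qx` within each 5-year band; the last listed age opens
#' the terminal band, which is extended to age 105.
#'
#' @param path CSV file path.
#' @return A validated `life_table` object covering at least ages 70-105.
#' @export
read_life_table <- function(path) {
  df <- utils::read.csv(path, colClasses = "numeric")
  if (!all(c("age", "qx") %in% names(df)))
    stop("life table CSV must have header 'age,qx'")
  df <- df[order(df$age), c("age", "qx"), drop = FALSE]
  df$age <- as.integer(df$age)
  steps <- diff(df$age)
  if (length(steps) > 0 && all(steps == 5)) {
    # abridged table: constant qx within each band, terminal band to 105
    upper <- max(df$age[length(df$age)] + 4L, 105L)
    ages <- as.integer(seq(df$age[1], upper))
    idx <- findInterval(ages, df$age)
    df <- data.frame(age = ages, qx = df$qx[idx])
  }
  validate_life_table(df)
  new_life_table(df)
}

#' Write a life table to CSV
#'
#' Inverse of [read_life_table()] for single-year tables; the `qx` column is
#' written at full precision so that a read/write round-trip is exact.
#'
#' @param life_table A `life_table` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(life_table, path) {
  df <- as.data.frame(life_table)
  df$qx <- format(df$qx, digits = 17, trim = TRUE, scientific = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Death probabilities at given ages
#'
#' @param life_table A `life_table` object.
#' @param ages Integer ages, all covered by the table.
#' @return Numeric vector of annual death probabilities.
#' @export
life_table_qx <- function(life_table, ages) {
  idx <- match(ages, life_table$age)
  if (anyNA(idx))
    stop(sprintf("ages not covered by life table: %s",
                 paste(ages[is.na(idx)], collapse = ", ")))
  life_table$qx[idx]
}

#' Parameter set with scaled fracture incidence
#'
#' Returns the default parameters with every hip and vertebral fracture
#' incidence rate multiplied by `scale`. Used by tests and by the joint
#' incidence sweep.
#'
#' @param scale Positive multiplier on all incidence rates.
#' @return A `cea_params` object.
#' @export
make_fixture_cohort_params <- function(scale = 1) {
  if (!(scale > 0)) stop("scale must be > 0")
  params <- default_parameters()
  params$epi$hip_rates$rate <- params$epi$hip_rates$rate * scale
  params$epi$vert_rates$rate <- params$epi$vert_rates$rate * scale
  params
}
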