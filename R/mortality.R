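#' Gompertz-Makeham hazard parameters
#'
#' Parameters of the synthetic period life table: the annual mortality
#' hazard at age x is `A + B * exp(C * x)` (Makeham background term plus
#' Gompertz senescence). Defaults approximate modern German female
#' mortality (life expectancy at birth near 80 years); the male table
#' scales the female hazard by `sex_ratio_adjust`.
#'
#' @param A Background (age-independent) hazard per year.
#' @param B Baseline senescent hazard per year.
#' @param C Senescence rate per year.
#' @return An object of class `gm_params`.
#' @export
gm_params <- function(A = 2.2e-4, B = 2.7e-5, C = 0.098) {
  check_number(A, "A", lo = 0)
  check_number(B, "B")
  check_number(C, "C")
  if (B <= 0 || C <= 0) stop_config("B and C must be > 0")
  structure(list(A = A, B = B, C = C), class = "gm_params")
}

new_life_table <- function(qx_female, qx_male, max_age) {
  structure(
    list(max_age = as.integer(max_age),
         qx_female = qx_female, qx_male = qx_male),
    class = "life_table"
  )
}

#' Generate a synthetic Gompertz-Makeham life table
#'
#' Builds a deterministic period life table with annual death probabilities
#' `qx(age) = 1 - exp(-(A + B * exp(C * age)))` for integer ages
#' `0..max_age`, capped at 1 and forced to 1 at `max_age` so every
#' trajectory terminates. This is a synthetic stand-in for a national
#' period life table; a real table drops in through [read_life_table()].
#'
#' @param params A [gm_params()].
#' @param sex_ratio_adjust Multiplier applied to the female hazard to form
#'   the male table (default 1.5, a typical male/female all-cause hazard
#'   ratio).
#' @param max_age Terminal age (absorbing; `qx = 1`).
#' @return A `life_table`.
#' @examples
#' lt <- make_life_table()
#' annual_death_prob(lt, 30, "female")
#' @export
make_life_table <- function(params = gm_params(), sex_ratio_adjust = 1.5,
                            max_age = 100L) {
  stopifnot(inherits(params, "gm_params"))
  check_number(sex_ratio_adjust, "sex_ratio_adjust", lo = 0)
  ages <- 0:max_age
  hz <- params$A + params$B * exp(params$C * ages)
  qf <- pmin(1 - exp(-hz), 1)
  qm <- pmin(1 - exp(-hz * sex_ratio_adjust), 1)
  qf[length(qf)] <- 1
  qm[length(qm)] <- 1
  new_life_table(qf, qm, max_age)
}

#' Annual probability of death
#'
#' Looks up the sex-specific annual death probability at `floor(age)`.
#' Ages above the table's terminal age return 1.
#'
#' @param table A `life_table`.
#' @param age Age in years (may be fractional); must be >= 0. Vectorised.
#' @param sex `"female"` or `"male"`; recycled against `age`.
#' @return Probability in `[0, 1]`.
#' @export
annual_death_prob <- function(table, age, sex) {
  stopifnot(inherits(table, "life_table"))
  if (any(age < 0)) stop("age must be >= 0")
  if (!all(sex %in% c("female", "male"))) stop("sex must be 'female' or 'male'")
  n <- max(length(age), length(sex))
  age <- rep_len(age, n)
  sex <- rep_len(sex, n)
  i <- pmin(floor(age), table$max_age) + 1L
  q <- ifelse(sex == "female", table$qx_female[i], table$qx_male[i])
  q[age > table$max_age] <- 1
  q
}

#' Survival curve and life expectancy from a life table
#'
#' `survival_curve` returns the probability of surviving from birth to each
#' integer age (`S(0) = 1`); `life_expectancy` sums the survival products,
#' i.e. expected whole life-years lived from age 0.
#'
#' @param table A `life_table`.
#' @param sex `"female"` or `"male"`.
#' @return `survival_curve`: numeric vector of length `max_age + 2` (ages
#'   `0..max_age+1`); `life_expectancy`: a scalar in years.
#' @export
survival_curve <- function(table, sex = "female") {
  qx <- if (sex == "female") table$qx_female else table$qx_male
  c(1, cumprod(1 - qx))
}

#' @rdname survival_curve
#' @export
life_expectancy <- function(table, sex = "female") {
  s <- survival_curve(table, sex)
  sum(s[-1])
}

#' Life-table CSV interface
#'
#' CSV format: header `age,qx_female,qx_male`, consecutive integer ages
#' from 0, probabilities as decimals in `[0, 1]`. `write_life_table` and
#' `read_life_table` round-trip a table at full precision; validation
#' errors name the offending row.
#'
#' @param table A `life_table`.
#' @param path File path.
#' @return `read_life_table` returns a `life_table`; `write_life_table`
#'   its input, invisibly.
#' @export
write_life_table <- function(table, path) {
  df <- data.frame(
    age = 0:table$max_age,
    qx_female = sprintf("%.17g", table$qx_female),
    qx_male = sprintf("%.17g", table$qx_male)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(table)
}

#' @rdname write_life_table
#' @export
read_life_table <- function(path) {
  df <- utils::read.csv(path)
  if (!identical(names(df), c("age", "qx_female", "qx_male"))) {
    stop_config("life table CSV must have header age,qx_female,qx_male")
  }
  if (nrow(df) < 2L) stop_config("life table must cover at least ages 0-1")
  expect_ages <- seq.int(0L, nrow(df) - 1L)
  bad <- which(df$age != expect_ages)
  if (length(bad)) {
    stop_config("life table ages must be consecutive from 0; first gap at row ",
                bad[1])
  }
  for (col in c("qx_female", "qx_male")) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] < 0 | df[[col]] > 1)
    if (length(bad)) {
      stop_config(col, " outside [0,1] at row ", bad[1],
                  " (value ", df[[col]][bad[1]], ")")
    }
  }
  max_age <- nrow(df) - 1L
  qf <- df$qx_female
  qm <- df$qx_male
  qf[length(qf)] <- 1
  qm[length(qm)] <- 1
  new_life_table(qf, qm, max_age)
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf(
    "<life_table> ages 0-%d; e0 female %.1f y, male %.1f y\n",
    x$max_age, life_expectancy(x, "female"), life_expectancy(x, "male")))
  invisible(x)
}
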