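#' Cohort specification
#'
#' Baseline characteristics of the simulated treatment-naive cohort,
#' defaulting to the phase-III trial population: mean age 15.1 +/- 10.9
#' years truncated to 4-44, 58% female, and arm-specific baseline
#' best-corrected visual acuity (BCVA, logMAR) and Goldmann III4e visual
#' field (VF, sum total degrees). Natural BCVA decline begins at a
#' per-patient onset age drawn uniformly on `onset_window`.
#'
#' @param n_patients Cohort size; must be even (patients are split equally
#'   between the voretigene neparvovec (VN) and standard-of-care (SoC) arms).
#' @param fraction_female Probability a patient is female.
#' @param age_mean,age_sd Mean and SD of the (untruncated) normal age
#'   distribution, years.
#' @param age_range Truncation bounds for age, years.
#' @param bcva_mean,bcva_sd Named numeric vectors with elements `VN` and
#'   `SoC`: baseline BCVA distribution per arm, logMAR.
#' @param vf_mean,vf_sd Named numeric vectors with elements `VN` and `SoC`:
#'   baseline VF distribution per arm, degrees.
#' @param onset_window Range of the BCVA-decline onset age, years.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 70L,
                        fraction_female = 0.58,
                        age_mean = 15.1,
                        age_sd = 10.9,
                        age_range = c(4, 44),
                        bcva_mean = c(VN = 1.137, SoC = 0.987),
                        bcva_sd = c(VN = 0.369, SoC = 0.306),
                        vf_mean = c(VN = 332.9, SoC = 427.1),
                        vf_sd = c(VN = 413.3, SoC = 372.0),
                        onset_window = c(15, 20)) {
  n_patients <- as.integer(n_patients)
  if (length(n_patients) != 1L || is.na(n_patients) || n_patients < 2L ||
      n_patients %% 2L != 0L) {
    stop_config("n_patients must be a positive even integer (equal arm split)")
  }
  check_number(fraction_female, "fraction_female", 0, 1)
  check_number(age_sd, "age_sd", lo = 0)
  check_number(age_range, "age_range", len = 2L)
  if (age_range[1] > age_range[2]) {
    stop_config("age_range must satisfy min <= max")
  }
  check_number(onset_window, "onset_window", len = 2L)
  if (onset_window[1] > onset_window[2]) {
    stop_config("onset_window must satisfy min <= max")
  }
  for (nm in c("bcva_mean", "bcva_sd", "vf_mean", "vf_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || !all(c("VN", "SoC") %in% names(v))) {
      stop_config(nm, " must be a numeric vector with names 'VN' and 'SoC'")
    }
  }
  if (any(bcva_sd < 0) || any(vf_sd < 0)) {
    stop_config("baseline SDs must be >= 0")
  }
  structure(
    list(
      n_patients = n_patients, fraction_female = fraction_female,
      age_mean = age_mean, age_sd = age_sd, age_range = age_range,
      bcva_mean = bcva_mean[c("VN", "SoC")], bcva_sd = bcva_sd[c("VN", "SoC")],
      vf_mean = vf_mean[c("VN", "SoC")], vf_sd = vf_sd[c("VN", "SoC")],
      onset_window = onset_window
    ),
    class = "cohort_spec"
  )
}

#' Sample a treatment-naive patient cohort
#'
#' Draws `n_patients` patients: ages from a truncated normal (inverse-CDF
#' sampling on `age_range`), sex as Bernoulli(`fraction_female`), baseline
#' BCVA/VF from the arm-specific normals clamped to the model bounds, and
#' the BCVA-decline onset age uniformly on `onset_window`. Arms are
#' assigned by random permutation with exactly half the cohort per arm.
#'
#' @param spec A [cohort_spec()].
#' @param prog A [progression_params()] supplying the BCVA bounds and VF
#'   floor used to clamp baseline draws.
#' @return A `data.frame` of class `vn_cohort` with columns
#'   `id, age, sex, bcva, vf, onset_age, arm`.
#' @examples
#' set.seed(1)
#' head(sample_cohort(cohort_spec()))
#' @export
sample_cohort <- function(spec = cohort_spec(), prog = progression_params()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  half <- n %/% 2L
  arm <- sample(rep(c("VN", "SoC"), each = half))
  age <- rtruncnorm(n, spec$age_mean, spec$age_sd,
                    spec$age_range[1], spec$age_range[2])
  sex <- ifelse(stats::runif(n) < spec$fraction_female, "female", "male")
  bcva <- stats::rnorm(n, spec$bcva_mean[arm], spec$bcva_sd[arm])
  vf <- stats::rnorm(n, spec$vf_mean[arm], spec$vf_sd[arm])
  onset <- stats::runif(n, spec$onset_window[1], spec$onset_window[2])
  out <- data.frame(
    id = seq_len(n),
    age = age,
    sex = sex,
    bcva = clamp(bcva, prog$bcva_floor, prog$bcva_cap),
    vf = pmax(vf, prog$vf_floor),
    onset_age = onset,
    arm = arm,
    stringsAsFactors = FALSE
  )
  class(out) <- c("vn_cohort", "data.frame")
  out
}

#' Write / read a cohort as CSV
#'
#' Round-trips the cohort table (`id,age,sex,bcva,vf,onset_age,arm`) at full
#' double precision for reproducibility and external checking.
#'
#' @param cohort A `vn_cohort` data.frame.
#' @param path File path.
#' @return `read_cohort` returns the `vn_cohort`; `write_cohort` its input,
#'   invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  df$age <- sprintf("%.17g", df$age)
  df$bcva <- sprintf("%.17g", df$bcva)
  df$vf <- sprintf("%.17g", df$vf)
  df$onset_age <- sprintf("%.17g", df$onset_age)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(cohort)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "age", "sex", "bcva", "vf", "onset_age", "arm")
  if (!identical(names(df), need)) {
    stop_config("cohort CSV must have header ", paste(need, collapse = ","))
  }
  if (!all(df$arm %in% c("VN", "SoC")) || !all(df$sex %in% c("female", "male"))) {
    stop_config("cohort CSV has invalid arm or sex labels")
  }
  class(df) <- c("vn_cohort", "data.frame")
  df
}

#' @export
print.vn_cohort <- function(x, ...) {
  cat(sprintf("<vn_cohort> %d patients (%d VN / %d SoC), ages %.1f-%.1f\n",
              nrow(x), sum(x$arm == "VN"), sum(x$arm == "SoC"),
              min(x$age), max(x$age)))
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
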