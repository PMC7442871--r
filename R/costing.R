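#' Direct cost schedule
#'
#' Treatment-bundle and follow-up reimbursements in EUR. The VN arm's first
#' year bundles both eyes (drug + pharmacy + DRG G18Z, doubled) plus four
#' quarterly outpatient fees; every later VN year and every SoC year is one
#' reimbursed annual check.
#'
#' @param drug_per_eye Voretigene neparvovec price per eye.
#' @param pharmacy_per_eye Pharmacy surcharge per eye.
#' @param drg_per_eye DRG G18Z reimbursement per eye.
#' @param outpatient_per_quarter Outpatient reimbursement per quarter.
#' @param vn_year1_quarters Outpatient quarters billed in the VN year 1.
#' @param followup_visits_per_year Reimbursed annual checks from year 2
#'   (and in every SoC year).
#' @return An object of class `direct_cost_schedule`.
#' @export
direct_cost_schedule <- function(drug_per_eye = 410550,
                                 pharmacy_per_eye = 2000,
                                 drg_per_eye = 2840,
                                 outpatient_per_quarter = 220,
                                 vn_year1_quarters = 4,
                                 followup_visits_per_year = 1) {
  vals <- c(drug_per_eye, pharmacy_per_eye, drg_per_eye,
            outpatient_per_quarter, vn_year1_quarters, followup_visits_per_year)
  if (any(vals < 0)) stop_config("direct cost components must be >= 0")
  structure(
    list(drug_per_eye = drug_per_eye, pharmacy_per_eye = pharmacy_per_eye,
         drg_per_eye = drg_per_eye,
         outpatient_per_quarter = outpatient_per_quarter,
         vn_year1_quarters = vn_year1_quarters,
         followup_visits_per_year = followup_visits_per_year),
    class = "direct_cost_schedule"
  )
}

#' Indirect cost table by visual-impairment band
#'
#' Six-monthly indirect medical, nonmedical and general costs (EUR) for the
#' three decimal-acuity bands `A` (< 0.02), `B` (0.02-0.05) and `C`
#' (0.05-0.3), with their reported SDs.
#'
#' @param means,sds 3x3 numeric matrices, rows `A`,`B`,`C`, columns
#'   `medical`,`nonmedical`,`general`; EUR per 6 months.
#' @return An object of class `indirect_cost_table`.
#' @export
indirect_cost_table <- function(
    means = matrix(c(5116, 10868, 3948,
                     3342, 3940, 3934,
                     2400, 1207, 3061),
                   nrow = 3, byrow = TRUE,
                   dimnames = list(c("A", "B", "C"),
                                   c("medical", "nonmedical", "general"))),
    sds = matrix(c(9938, 115022, 7437,
                   4854, 21011, 7892,
                   5483, 6442, 6891),
                 nrow = 3, byrow = TRUE,
                 dimnames = list(c("A", "B", "C"),
                                 c("medical", "nonmedical", "general")))) {
  for (m in list(means, sds)) {
    if (!is.matrix(m) || !identical(dim(m), c(3L, 3L)) || any(m < 0)) {
      stop_config("indirect cost means/sds must be nonnegative 3x3 matrices")
    }
  }
  structure(list(means = means, sds = sds), class = "indirect_cost_table")
}

#' Discounting parameters
#'
#' @param rate_costs,rate_qalys Annual discount rates (default 0.03 each).
#' @return An object of class `discount_params`.
#' @export
discount_params <- function(rate_costs = 0.03, rate_qalys = 0.03) {
  check_number(rate_costs, "rate_costs", lo = 0)
  check_number(rate_qalys, "rate_qalys", lo = 0)
  structure(list(rate_costs = rate_costs, rate_qalys = rate_qalys),
            class = "discount_params")
}

#' Direct cost of one model year
#'
#' @param arm `"VN"` or `"SoC"`.
#' @param year_index 1-based model year. Vectorised.
#' @param s A [direct_cost_schedule()].
#' @return EUR: the two-eye treatment bundle plus quarterly outpatient fees
#'   in VN year 1; otherwise the annual check fee.
#' @examples
#' direct_cost("VN", 1) # 831660
#' @export
direct_cost <- function(arm = c("VN", "SoC"), year_index,
                        s = direct_cost_schedule()) {
  arm <- match.arg(arm)
  if (any(year_index < 1)) stop("year_index must be >= 1")
  annual <- s$followup_visits_per_year * s$outpatient_per_quarter
  if (arm == "SoC") {
    return(rep(annual, length(year_index)))
  }
  year1 <- 2 * (s$drug_per_eye + s$pharmacy_per_eye + s$drg_per_eye) +
    s$vn_year1_quarters * s$outpatient_per_quarter
  ifelse(year_index == 1, year1, annual)
}

#' Visual-impairment band from BCVA
#'
#' Converts logMAR to decimal acuity (`10^-bcva`) and bins it into the
#' indirect-cost bands: `A` below 0.02, `B` in `[0.02, 0.05)`, `C` in
#' `[0.05, 0.3)`, `none` at 0.3 or better (no indirect costs).
#'
#' @param bcva BCVA, logMAR. Vectorised.
#' @return Character vector in `{"A","B","C","none"}`.
#' @export
bcva_band <- function(bcva) {
  dec <- 10^(-bcva)
  out <- rep("none", length(dec))
  out[dec < 0.3] <- "C"
  out[dec < 0.05] <- "B"
  out[dec < 0.02] <- "A"
  out
}

#' Annual indirect cost for a visual-impairment band
#'
#' The band tables are per 6 months, so annual cost is twice the band sum.
#' `mode = "mean"` (default) is deterministic; `mode = "sampled"` draws the
#' three components from zero-truncated normals, which inflates expected
#' costs well above the printed means for the heavy-tailed bands and is
#' therefore off by default.
#'
#' @param band `"A"`, `"B"`, `"C"` or `"none"`. Vectorised.
#' @param table An [indirect_cost_table()].
#' @param mode `"mean"` or `"sampled"`.
#' @return EUR per year; 0 for band `"none"`.
#' @export
indirect_annual_cost <- function(band, table = indirect_cost_table(),
                                 mode = c("mean", "sampled")) {
  mode <- match.arg(mode)
  stopifnot(all(band %in% c("A", "B", "C", "none")))
  out <- numeric(length(band))
  idx <- band != "none"
  if (!any(idx)) return(out)
  if (mode == "mean") {
    out[idx] <- 2 * rowSums(table$means)[band[idx]]
  } else {
    rows <- match(band[idx], c("A", "B", "C"))
    draws <- vapply(seq_along(rows), function(j) {
      r <- rows[j]
      sum(vapply(1:3, function(k) {
        rtruncnorm(1, table$means[r, k], table$sds[r, k], lower = 0)
      }, numeric(1)))
    }, numeric(1))
    out[idx] <- 2 * draws
  }
  out
}

#' Discount factor for a model year
#'
#' @param year_index 1-based model year; year 1 is undiscounted. Vectorised.
#' @param rate Annual discount rate (>= 0).
#' @return `(1 + rate)^-(year_index - 1)`.
#' @export
discount_factor <- function(year_index, rate) {
  if (any(year_index < 1)) stop("year_index must be >= 1")
  if (rate < 0) stop("rate must be >= 0")
  (1 + rate)^(-(year_index - 1))
}
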