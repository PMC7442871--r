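# Internal helpers shared across modules.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @noRd
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("vncua_config_error", "error")))
}

#' Truncated-normal draws by inverse-CDF
#'
#' One uniform per draw, so the consuming random stream has fixed length
#' regardless of how hard the truncation bites (unlike rejection sampling).
#' @noRd
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) {
    return(rep(clamp(mean, lower, upper), n))
  }
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}

# Mean of a normal(mean, sd) truncated to [lower, upper]; closed form used
# as an oracle for cohort age sampling.
truncnorm_mean <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# Derive a fixed number of child seeds from a parent seed without touching
# the caller's RNG state.
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

check_number <- function(x, name, lo = -Inf, hi = Inf, len = 1L) {
  if (!is.numeric(x) || length(x) != len || anyNA(x)) {
    stop_config(name, " must be a numeric vector of length ", len)
  }
  if (any(x < lo) || any(x > hi)) {
    stop_config(name, " must lie in [", lo, ", ", hi, "]")
  }
  invisible(x)
}
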