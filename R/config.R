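#' Scenario configuration
#'
#' Bundles every model parameter — cohort, natural history, first-cycle
#' trial effects, effect-duration scenario, utility mapping, costs,
#' discounting, mortality — together with the Monte Carlo design
#' (`n_sims`, `master_seed`). All defaults are the published base case.
#'
#' @param cohort A [cohort_spec()].
#' @param progression A [progression_params()].
#' @param effects A [trial_effect()].
#' @param scenario An [effect_scenario()].
#' @param utility A [utility_params()].
#' @param direct_costs A [direct_cost_schedule()].
#' @param indirect_costs An [indirect_cost_table()].
#' @param discount A [discount_params()].
#' @param include_indirect Accrue visual-impairment-banded indirect costs?
#' @param indirect_mode `"mean"` (deterministic band means) or `"sampled"`.
#' @param life_table A `life_table` (see [make_life_table()],
#'   [read_life_table()]).
#' @param n_sims Monte Carlo replicates (default 1000).
#' @param master_seed Master seed; per-replicate seeds and per-replicate
#'   cohort/effect/mortality substreams are derived from it.
#' @return An object of class `scenario_config`.
#' @examples
#' cfg <- scenario_config(n_sims = 10)
#' @export
scenario_config <- function(cohort = cohort_spec(),
                            progression = progression_params(),
                            effects = trial_effect(),
                            scenario = effect_scenario(),
                            utility = utility_params(),
                            direct_costs = direct_cost_schedule(),
                            indirect_costs = indirect_cost_table(),
                            discount = discount_params(),
                            include_indirect = TRUE,
                            indirect_mode = c("mean", "sampled"),
                            life_table = make_life_table(),
                            n_sims = 1000L,
                            master_seed = 1L) {
  indirect_mode <- match.arg(indirect_mode)
  stopifnot(inherits(cohort, "cohort_spec"),
            inherits(progression, "progression_params"),
            inherits(effects, "trial_effect"),
            inherits(scenario, "effect_scenario"),
            inherits(utility, "utility_params"),
            inherits(direct_costs, "direct_cost_schedule"),
            inherits(indirect_costs, "indirect_cost_table"),
            inherits(discount, "discount_params"),
            inherits(life_table, "life_table"))
  n_sims <- as.integer(n_sims)
  if (is.na(n_sims) || n_sims < 1L) stop_config("n_sims must be >= 1")
  structure(
    list(cohort = cohort, progression = progression, effects = effects,
         scenario = scenario, utility = utility,
         direct_costs = direct_costs, indirect_costs = indirect_costs,
         discount = discount, include_indirect = isTRUE(include_indirect),
         indirect_mode = indirect_mode, life_table = life_table,
         n_sims = n_sims, master_seed = as.integer(master_seed)),
    class = "scenario_config"
  )
}

#' Scale the monetary components of a direct cost schedule
#'
#' Multiplies the EUR components (drug, pharmacy, DRG, outpatient fee) by
#' `factor`, leaving visit counts untouched; used for the +/-10% direct-cost
#' sensitivity analyses.
#'
#' @param s A [direct_cost_schedule()].
#' @param factor Positive multiplier.
#' @return A `direct_cost_schedule`.
#' @export
scale_direct_costs <- function(s, factor) {
  check_number(factor, "factor", lo = 0)
  direct_cost_schedule(
    drug_per_eye = s$drug_per_eye * factor,
    pharmacy_per_eye = s$pharmacy_per_eye * factor,
    drg_per_eye = s$drg_per_eye * factor,
    outpatient_per_quarter = s$outpatient_per_quarter * factor,
    vn_year1_quarters = s$vn_year1_quarters,
    followup_visits_per_year = s$followup_visits_per_year
  )
}

# Plain-list view of a config (life table summarised by its generator-free
# contents) for serialisation and fingerprinting.
as_config_list <- function(config) {
  lt <- config$life_table
  list(
    cohort = unclass(config$cohort),
    progression = unclass(config$progression),
    effects = lapply(unclass(config$effects), as.list),
    scenario = unclass(config$scenario),
    utility = unclass(config$utility),
    costs = list(
      direct = unclass(config$direct_costs),
      indirect = list(
        means = as.list(as.data.frame(config$indirect_costs$means)),
        sds = as.list(as.data.frame(config$indirect_costs$sds))
      ),
      discount = unclass(config$discount),
      include_indirect = config$include_indirect,
      indirect_mode = config$indirect_mode
    ),
    mortality = list(max_age = lt$max_age,
                     qx_female = lt$qx_female, qx_male = lt$qx_male),
    n_sims = config$n_sims,
    master_seed = config$master_seed
  )
}

#' Fingerprint a scenario configuration
#'
#' MD5 of the canonical JSON serialisation of the fully-resolved config
#' (life table values included). Together with the master seed this
#' determines every output of the pipeline.
#'
#' @param config A [scenario_config()].
#' @return A 32-character hex string.
#' @export
config_fingerprint <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(as_config_list(config), auto_unbox = TRUE,
                              digits = NA), tf)
  unname(tools::md5sum(tf))
}

#' Echo a resolved configuration to disk
#'
#' Writes the fully-resolved configuration (with its fingerprint) as JSON,
#' so a run directory records exactly the parameters that produced it.
#'
#' @param config A [scenario_config()].
#' @param path Output file path.
#' @return The fingerprint, invisibly.
#' @export
write_config <- function(config, path) {
  fp <- config_fingerprint(config)
  obj <- c(list(fingerprint = fp), as_config_list(config))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  invisible(fp)
}

named_arm_vec <- function(x, key) {
  if (is.null(x)) return(NULL)
  x <- unlist(x)
  if (!all(c("VN", "SoC") %in% names(x))) {
    stop_config(key, " must provide VN and SoC entries")
  }
  x
}

check_known_keys <- function(x, known, where) {
  bad <- setdiff(names(x), known)
  if (length(bad)) {
    stop_config("unknown configuration key '", bad[1], "' in ", where)
  }
}

merge_args <- function(defaults_fun, overrides, where) {
  known <- names(formals(defaults_fun))
  check_known_keys(overrides, known, where)
  do.call(defaults_fun, overrides)
}

#' Load a scenario configuration from YAML or JSON
#'
#' Missing sections and fields fall back to the published defaults, so an
#' empty file yields the base-case configuration. Unknown keys, type
#' mismatches and invariant violations raise an error naming the offending
#' key. Sections: `cohort`, `progression`, `effects`, `scenario`,
#' `utility`, `costs` (subkeys `direct`, `indirect`, `discount`,
#' `include_indirect`, `indirect_mode`), `mortality` (`table_path`, or
#' `gm: {A,B,C}` with `sex_ratio_adjust`, `max_age`), `n_sims`,
#' `master_seed`. Per-arm fields are maps with `VN`/`SoC` entries; the
#' indirect table is a map band -> `{medical, nonmedical, general}`.
#'
#' @param path Path to a YAML (or JSON) file; may be empty.
#' @param echo_dir Optional directory; if given, the resolved config (with
#'   fingerprint) is written there as `config_resolved.json`.
#' @return A validated [scenario_config()].
#' @export
load_config <- function(path, echo_dir = NULL) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  check_known_keys(raw, c("cohort", "progression", "effects", "scenario",
                          "utility", "costs", "mortality", "n_sims",
                          "master_seed"), "top level")

  for (sec in c("cohort", "progression", "effects", "scenario", "utility")) {
    if (!is.null(raw[[sec]]) && !is.list(raw[[sec]])) {
      stop_config("section '", sec, "' must be a mapping")
    }
  }
  co <- raw$cohort %||% list()
  for (k in c("bcva_mean", "bcva_sd", "vf_mean", "vf_sd")) {
    if (!is.null(co[[k]])) co[[k]] <- named_arm_vec(co[[k]], paste0("cohort.", k))
  }
  cohort <- merge_args(cohort_spec, co, "cohort")
  progression <- merge_args(progression_params, raw$progression %||% list(),
                            "progression")
  ef <- raw$effects %||% list()
  for (k in names(ef)) ef[[k]] <- named_arm_vec(ef[[k]], paste0("effects.", k))
  effects <- merge_args(trial_effect, ef, "effects")
  scenario <- merge_args(effect_scenario, raw$scenario %||% list(), "scenario")
  utility <- merge_args(utility_params, raw$utility %||% list(), "utility")

  costs <- raw$costs %||% list()
  check_known_keys(costs, c("direct", "indirect", "discount",
                            "include_indirect", "indirect_mode"), "costs")
  direct <- merge_args(direct_cost_schedule, costs$direct %||% list(),
                       "costs.direct")
  indirect <- indirect_cost_table()
  if (!is.null(costs$indirect)) {
    check_known_keys(costs$indirect, c("A", "B", "C"), "costs.indirect")
    means <- indirect$means
    sds <- indirect$sds
    for (b in names(costs$indirect)) {
      row <- costs$indirect[[b]]
      check_known_keys(row, c("medical", "nonmedical", "general",
                              "medical_sd", "nonmedical_sd", "general_sd"),
                       paste0("costs.indirect.", b))
      for (k in c("medical", "nonmedical", "general")) {
        if (!is.null(row[[k]])) means[b, k] <- row[[k]]
        if (!is.null(row[[paste0(k, "_sd")]])) sds[b, k] <- row[[paste0(k, "_sd")]]
      }
    }
    indirect <- indirect_cost_table(means, sds)
  }
  discount <- merge_args(discount_params, costs$discount %||% list(),
                         "costs.discount")
  include_indirect <- costs$include_indirect %||% TRUE
  if (!is.logical(include_indirect)) {
    stop_config("costs.include_indirect must be true/false")
  }
  indirect_mode <- costs$indirect_mode %||% "mean"
  if (!indirect_mode %in% c("mean", "sampled")) {
    stop_config("costs.indirect_mode must be 'mean' or 'sampled'")
  }

  mort <- raw$mortality %||% list()
  check_known_keys(mort, c("table_path", "gm", "sex_ratio_adjust", "max_age"),
                   "mortality")
  life_table <- if (!is.null(mort$table_path)) {
    read_life_table(mort$table_path)
  } else {
    gm <- merge_args(gm_params, mort$gm %||% list(), "mortality.gm")
    make_life_table(gm, mort$sex_ratio_adjust %||% 1.5,
                    mort$max_age %||% 100L)
  }

  config <- scenario_config(
    cohort = cohort, progression = progression, effects = effects,
    scenario = scenario, utility = utility, direct_costs = direct,
    indirect_costs = indirect, discount = discount,
    include_indirect = include_indirect, indirect_mode = indirect_mode,
    life_table = life_table,
    n_sims = raw$n_sims %||% 1000L,
    master_seed = raw$master_seed %||% 1L
  )
  if (!is.null(echo_dir)) {
    if (!dir.exists(echo_dir)) dir.create(echo_dir, recursive = TRUE)
    write_config(config, file.path(echo_dir, "config_resolved.json"))
  }
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    paste0("<scenario_config> %d patients x %d replicates, seed %d\n",
           "  effect: %s; discount costs %.0f%% / QALYs %.0f%%; ",
           "indirect: %s (%s)\n  fingerprint %s\n"),
    x$cohort$n_patients, x$n_sims, x$master_seed, x$scenario$kind,
    100 * x$discount$rate_costs, 100 * x$discount$rate_qalys,
    if (x$include_indirect) "on" else "off", x$indirect_mode,
    config_fingerprint(x)))
  invisible(x)
}
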