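#' Default run configuration
#'
#' Nested list of every threshold and dialect used across the pipeline.
#' A YAML file loaded with [load_config()] may override any subset of these
#' keys; unknown keys are rejected so typos never silently fall back to a
#' default.
#'
#' Key groups:
#' * `dialect` / `report_dialect`: logical-column to file-column name maps for
#'   the sample table and the precursor report.
#' * `mod_tokens`: bracketed modification tag -> canonical modification class
#'   (`dtb`, `oxidation`, `carbamidomethyl`, `acetyl`). Unrecognised tags are
#'   retained verbatim and treated as distinct variable modifications.
#' * `competition`: hit-calling thresholds (see [competition_params()]).
#' * `dose_response`: 4PL bounds, minimum concentrations with data, and
#'   curve-quality thresholds (see [fit_4pl()], [assess_fit()]).
#' * `selectivity`, `digest`, `pockets`, `simulate`: see the respective
#'   functions.
#'
#' @return Named nested list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    dialect = list(
      sample_id = "sample_id", role = "role", compound_id = "compound_id",
      concentration_um = "concentration_um",
      replicate_index = "replicate_index",
      context = "context", experiment_id = "experiment_id"
    ),
    report_dialect = list(
      sample_id = "sample_id", protein_accession = "accession",
      modified_sequence = "modified_sequence", charge = "charge",
      intensity = "intensity"
    ),
    mod_tokens = list(
      "DTB" = "dtb", "IA-DTB" = "dtb",
      "Oxidation" = "oxidation", "MetOx" = "oxidation",
      "Carbamidomethyl" = "carbamidomethyl", "CAM" = "carbamidomethyl",
      "Acetyl" = "acetyl"
    ),
    normalize_median = FALSE,
    aggregation = list(
      cleavage_form_rule = "most_abundant_mean_all_samples",
      single_dtb_required = TRUE
    ),
    competition = list(
      log2cr_min = 1.0, neglog10p_min = 1.3,
      min_treated_detected = 2L, min_frac_detected_all = 0.90,
      max_control_cv = 0.40,
      test_scale = "log2", cr_mode = "per_replicate_log",
      report_qvalues = FALSE
    ),
    dose_response = list(
      n_conc_min = 5L,
      e0_bounds = c(60, 140), e_inf_min = 0, slope_bounds = c(-50, 0),
      log10_te50_margin = 3,
      quality = list(
        r2_min = 0.8, span_min = 30,
        stderr_log10_te50_max = 1.0, potency_margin = 0.5
      )
    ),
    selectivity = list(top_n = 5L, scale = "log2"),
    digest = list(
      detect_length = c(7L, 40L),
      search_length = c(7L, 52L), search_missed_cleavages = 2L
    ),
    pockets = list(cutoff_a = 1.5, convention = "center"),
    simulate = sim_defaults()
  )
}

#' Load and validate a YAML run configuration
#'
#' Reads a nested YAML document and merges it over [default_config()].
#' Any key not present in the defaults is rejected (validation error), so a
#' run log plus the config file fully determine every threshold in effect.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return Merged configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) {
    return(cfg)
  }
  user <- yaml::read_yaml(path)
  if (!is.list(user)) stop_format("config file must be a YAML mapping")
  check_known_keys(user, cfg, "config")
  merged <- modifyList(cfg, user)
  validate_config(merged)
  merged
}

check_known_keys <- function(user, ref, where) {
  if (!is.list(user) || !is.list(ref)) {
    return(invisible(TRUE))
  }
  unknown <- setdiff(names(user), names(ref))
  # mod_tokens / dialects are open maps: arbitrary tag or column names allowed
  open_maps <- c("mod_tokens", "dialect", "report_dialect", "spikes")
  if (length(unknown) > 0 && !basename(where) %in% open_maps) {
    stop_validation(sprintf(
      "unknown config key(s) under '%s': %s",
      where, paste(unknown, collapse = ", ")
    ))
  }
  for (k in intersect(names(user), names(ref))) {
    check_known_keys(user[[k]], ref[[k]], paste0(where, "/", k))
  }
  invisible(TRUE)
}

validate_config <- function(cfg) {
  cp <- cfg$competition
  if (cp$log2cr_min <= 0 || cp$neglog10p_min <= 0) {
    stop_validation("competition thresholds must be positive")
  }
  if (cp$min_frac_detected_all <= 0 || cp$min_frac_detected_all > 1) {
    stop_validation("min_frac_detected_all must lie in (0, 1]")
  }
  if (cp$max_control_cv <= 0 || cp$max_control_cv > 1) {
    stop_validation("max_control_cv must lie in (0, 1]")
  }
  sim_validate(do.call(sim_config, cfg$simulate))
  invisible(cfg)
}
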