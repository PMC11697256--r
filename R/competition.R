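#' Welch's two-sample t-test (unequal variances)
#'
#' Two-sided Welch test as used for control-vs-treated intensity comparison:
#' `t = (mean(x) - mean(y)) / sqrt(sx^2/nx + sy^2/ny)` with
#' Welch–Satterthwaite degrees of freedom. Degenerate inputs follow fixed
#' conventions: both variances zero with equal means gives `p = 1`; both
#' zero with different means gives `p = 0` and a `degenerate` flag (the
#' difference is infinitely significant relative to zero noise).
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return List with `t`, `df`, `p` (two-sided) and `degenerate`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop_validation("welch_t requires at least two values per group")
  }
  res <- welch_stats(
    mean(x), var(x), length(x),
    mean(y), var(y), length(y)
  )
  lapply(res, `[[`, 1)
}

# vectorised Welch statistics from sufficient statistics
welch_stats <- function(mx, vx, nx, my, vy, ny) {
  se2 <- vx / nx + vy / ny
  t <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * pt(-abs(t), df)
  degenerate <- rep(FALSE, length(t))
  zero <- !is.na(vx) & !is.na(vy) & vx == 0 & vy == 0
  eq <- zero & mx == my
  ne <- zero & mx != my
  t[eq] <- 0
  df[eq] <- nx[eq] + ny[eq] - 2
  p[eq] <- 1
  t[ne] <- sign(mx[ne] - my[ne]) * Inf
  df[ne] <- nx[ne] + ny[ne] - 2
  p[ne] <- 0
  degenerate[ne] <- TRUE
  list(t = t, df = df, p = p, degenerate = degenerate)
}

#' Hit-calling parameters
#'
#' Thresholds of the liganding-event filter cascade. A (compound, site)
#' record is a hit only if its mean log2 competition ratio and Welch
#' significance clear `log2cr_min` / `neglog10p_min` AND the peptide is
#' robustly detected: in at least `min_treated_detected` treated replicates,
#' in at least `min_frac_detected_all` of all samples of the experiment,
#' with control coefficient of variation at most `max_control_cv`, carrying
#' exactly one DTB modification, and being the selected (most abundant)
#' cleavage form for its site.
#'
#' @param log2cr_min Minimum mean log2(CR); default 1 (50% competition).
#' @param neglog10p_min Minimum -log10(p); default 1.3 (p <= 0.05).
#' @param min_treated_detected Minimum detected treated replicates; default 2.
#' @param min_frac_detected_all Minimum detection fraction over all samples
#'   of the experiment; default 0.90.
#' @param max_control_cv Maximum raw-scale CV among detected control
#'   replicates; default 0.40.
#' @param test_scale Scale for the Welch test: `"log2"` (default; variance
#'   stabilisation for lognormal MS intensities) or `"raw"`.
#' @param cr_mode `"per_replicate_log"` (default): per-treated-replicate
#'   log2 ratios against the control mean, then averaged; or
#'   `"ratio_of_means"`.
#' @param report_qvalues Add a Benjamini-Hochberg `q_value` column
#'   (default `FALSE`; the screen's published thresholds are on raw p).
#' @return Validated parameter list.
#' @export
competition_params <- function(log2cr_min = 1.0, neglog10p_min = 1.3,
                               min_treated_detected = 2L,
                               min_frac_detected_all = 0.90,
                               max_control_cv = 0.40,
                               test_scale = c("log2", "raw"),
                               cr_mode = c("per_replicate_log",
                                           "ratio_of_means"),
                               report_qvalues = FALSE) {
  p <- list(
    log2cr_min = log2cr_min, neglog10p_min = neglog10p_min,
    min_treated_detected = as.integer(min_treated_detected),
    min_frac_detected_all = min_frac_detected_all,
    max_control_cv = max_control_cv,
    test_scale = match.arg(test_scale),
    cr_mode = match.arg(cr_mode),
    report_qvalues = isTRUE(report_qvalues)
  )
  if (p$log2cr_min <= 0 || p$neglog10p_min <= 0 ||
      p$min_treated_detected <= 0) {
    stop_validation("competition thresholds must be positive")
  }
  if (p$min_frac_detected_all <= 0 || p$min_frac_detected_all > 1 ||
      p$max_control_cv <= 0 || p$max_control_cv > 1) {
    stop_validation("fraction thresholds must lie in (0, 1]")
  }
  p
}

#' Compute competition records and call hits for a whole screen
#'
#' For every (compound, concentration, cysteine-site peptide) combination of
#' an experiment, computes the mean log2 competition ratio
#' (CR = intensity_DMSO / intensity_compound), Welch's two-sided t-test of
#' control vs treated intensities, the detection/CV filter flags, and the
#' final hit call. No imputation is performed anywhere: only detected
#' intensities enter every statistic, and the detection filters substitute
#' for missing-value handling.
#'
#' If `quants` still contains several peptide forms per site (i.e.
#' [dedupe_cleavage_forms()] was not applied), all forms are scored but the
#' non-selected ones are flagged `redundant_form` and can never be hits.
#'
#' @param quants Site-mapped peptide quantities ([map_sites()], ideally
#'   after [dedupe_cleavage_forms()]).
#' @param meta Sample table ([read_sample_table()]).
#' @param params [competition_params()].
#' @return Tibble with one row per (compound, concentration, peptide):
#'   identities, `n_treated_detected`, `n_control_detected`, `mean_log2_cr`,
#'   `t`, `df`, `p_value`, `neglog10_p`, `cv_control`, `frac_detected_all`,
#'   `filter_flags` (comma-joined, `""` when clean), `degenerate_p`,
#'   `is_hit`.
#' @export
call_hits <- function(quants, meta, params = competition_params()) {
  validate_sample_meta(meta)
  if (nrow(quants) == 0) {
    return(empty_competition_record())
  }
  unknown <- setdiff(unique(quants$sample_id), meta$sample_id)
  if (length(unknown) > 0) {
    stop_validation(sprintf(
      "quantities reference sample_id(s) absent from metadata: %s",
      paste(head(unknown, 5), collapse = ", ")
    ))
  }
  if (!"residue_index" %in% names(quants)) {
    stop_validation("quants must be site-mapped; run map_sites() first")
  }
  mapped <- filter(quants, !is.na(.data$residue_index))
  dat <- inner_join(mapped, meta, by = "sample_id")

  pep_cols <- c("protein_accession", "residue_index", "stripped_sequence",
                "dtb_positions", "dtb_count", "other_mod_key")

  # cleavage-form selection per site (no-op when dedupe already applied)
  sel <- mapped %>%
    group_by(across(all_of(pep_cols))) %>%
    summarise(abundance = mean(.data$intensity), .groups = "drop") %>%
    group_by(.data$protein_accession, .data$residue_index) %>%
    arrange(
      dplyr::desc(.data$abundance), nchar(.data$stripped_sequence),
      .data$stripped_sequence, .data$other_mod_key,
      .by_group = TRUE
    ) %>%
    mutate(selected_form = row_number() == 1L) %>%
    ungroup() %>%
    select(all_of(pep_cols), "selected_form")

  n_samples <- meta %>% count(.data$experiment_id, name = "n_samples_exp")

  completeness <- dat %>%
    group_by(across(all_of(c(pep_cols, "experiment_id")))) %>%
    summarise(n_detected_all = n(), .groups = "drop") %>%
    left_join(n_samples, by = "experiment_id") %>%
    mutate(frac_detected_all = .data$n_detected_all / .data$n_samples_exp)

  ctrl <- dat %>%
    filter(.data$role == "control") %>%
    group_by(across(all_of(c(pep_cols, "experiment_id")))) %>%
    summarise(
      n_control_detected = n(),
      ctrl_mean_raw = mean(.data$intensity),
      ctrl_var_raw = if (n() > 1) var(.data$intensity) else NA_real_,
      ctrl_mean_log2 = mean(log2(.data$intensity)),
      ctrl_var_log2 = if (n() > 1) var(log2(.data$intensity)) else NA_real_,
      .groups = "drop"
    ) %>%
    mutate(cv_control = sqrt(.data$ctrl_var_raw) / .data$ctrl_mean_raw)

  trt <- dat %>%
    filter(.data$role == "treated") %>%
    group_by(across(all_of(c(
      pep_cols, "experiment_id", "compound_id", "concentration_um"
    )))) %>%
    summarise(
      n_treated_detected = n(),
      trt_mean_raw = mean(.data$intensity),
      trt_var_raw = if (n() > 1) var(.data$intensity) else NA_real_,
      trt_mean_log2 = mean(log2(.data$intensity)),
      trt_var_log2 = if (n() > 1) var(log2(.data$intensity)) else NA_real_,
      .groups = "drop"
    )

  # full grid: every peptide of an experiment x every treatment condition
  conditions <- meta %>%
    filter(.data$role == "treated") %>%
    distinct(.data$experiment_id, .data$compound_id, .data$concentration_um)
  grid <- completeness %>%
    inner_join(conditions, by = "experiment_id",
               relationship = "many-to-many") %>%
    left_join(trt, by = c(pep_cols, "experiment_id", "compound_id",
                          "concentration_um")) %>%
    left_join(ctrl, by = c(pep_cols, "experiment_id")) %>%
    left_join(sel, by = pep_cols) %>%
    mutate(
      n_treated_detected = dplyr::coalesce(.data$n_treated_detected, 0L),
      n_control_detected = dplyr::coalesce(.data$n_control_detected, 0L)
    )

  grid$mean_log2_cr <- if (params$cr_mode == "per_replicate_log") {
    log2(grid$ctrl_mean_raw) - grid$trt_mean_log2
  } else {
    log2(grid$ctrl_mean_raw / grid$trt_mean_raw)
  }

  testable <- grid$n_control_detected >= 2 & grid$n_treated_detected >= 2
  if (params$test_scale == "log2") {
    w <- welch_stats(
      grid$ctrl_mean_log2, grid$ctrl_var_log2, grid$n_control_detected,
      grid$trt_mean_log2, grid$trt_var_log2, grid$n_treated_detected
    )
  } else {
    w <- welch_stats(
      grid$ctrl_mean_raw, grid$ctrl_var_raw, grid$n_control_detected,
      grid$trt_mean_raw, grid$trt_var_raw, grid$n_treated_detected
    )
  }
  grid$t <- ifelse(testable, w$t, NA_real_)
  grid$df <- ifelse(testable, w$df, NA_real_)
  grid$p_value <- ifelse(testable, w$p, NA_real_)
  grid$degenerate_p <- testable & w$degenerate
  grid$neglog10_p <- -log10(grid$p_value)

  flag <- function(cond, name) ifelse(!is.na(cond) & cond, name, NA_character_)
  flags <- cbind(
    flag(grid$n_treated_detected < params$min_treated_detected,
         "low_treated_n"),
    flag(grid$frac_detected_all < params$min_frac_detected_all,
         "low_completeness"),
    flag(is.na(grid$cv_control) | grid$cv_control > params$max_control_cv,
         "high_cv"),
    flag(grid$dtb_count != 1L, "multi_dtb"),
    flag(!grid$selected_form, "redundant_form")
  )
  grid$filter_flags <- apply(flags, 1, function(r) {
    paste(r[!is.na(r)], collapse = ",")
  })

  grid$is_hit <- grid$filter_flags == "" &
    !is.na(grid$mean_log2_cr) & grid$mean_log2_cr >= params$log2cr_min &
    !is.na(grid$neglog10_p) & grid$neglog10_p >= params$neglog10p_min

  out <- grid %>%
    select(
      "compound_id", "concentration_um", "experiment_id",
      "protein_accession", "residue_index",
      "stripped_sequence", "dtb_positions", "dtb_count", "other_mod_key",
      "n_treated_detected", "n_control_detected",
      "mean_log2_cr", "t", "df", "p_value", "neglog10_p", "degenerate_p",
      "cv_control", "frac_detected_all", "filter_flags", "is_hit"
    ) %>%
    arrange(
      .data$compound_id, .data$concentration_um,
      .data$protein_accession, .data$residue_index
    )
  if (isTRUE(params$report_qvalues)) {
    out$q_value <- p.adjust(out$p_value, method = "BH")
  }
  out
}

#' Competition record for a single peptide and compound
#'
#' Convenience wrapper around [call_hits()] for one site quantity: all rows
#' of `quants` must belong to a single peptide form.
#'
#' @param quant Long tibble of one peptide's detected intensities (same
#'   schema as [map_sites()] output).
#' @param meta Sample table.
#' @param compound Compound id to score against the controls.
#' @param params [competition_params()].
#' @return One-row (per concentration) competition record tibble.
#' @export
site_competition <- function(quant, meta, compound,
                             params = competition_params()) {
  n_pep <- nrow(distinct(
    quant, .data$protein_accession, .data$stripped_sequence,
    .data$dtb_positions, .data$other_mod_key
  ))
  if (n_pep != 1) {
    stop_validation("site_competition expects exactly one peptide form")
  }
  call_hits(quant, meta, params) %>%
    filter(.data$compound_id == compound)
}

empty_competition_record <- function() {
  tibble(
    compound_id = character(), concentration_um = numeric(),
    experiment_id = character(),
    protein_accession = character(), residue_index = integer(),
    stripped_sequence = character(), dtb_positions = character(),
    dtb_count = integer(), other_mod_key = character(),
    n_treated_detected = integer(), n_control_detected = integer(),
    mean_log2_cr = numeric(), t = numeric(), df = numeric(),
    p_value = numeric(), neglog10_p = numeric(), degenerate_p = logical(),
    cv_control = numeric(), frac_detected_all = numeric(),
    filter_flags = character(), is_hit = logical()
  )
}
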