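#' Four-parameter logistic (variable-slope) engagement model
#'
#' `y(x) = e_inf + (e0 - e_inf) / (1 + 10^(slope_n * (log10_te50 - x)))`
#' where `x` is log10 concentration (uM), `y` the peptide intensity as
#' percent of the DMSO control, `e0` the top plateau (no compound), `e_inf`
#' the bottom plateau (saturating compound), `slope_n <= 0` the Hill-type
#' slope, and `log10_te50` the midpoint: `y(log10_te50) = (e0 + e_inf) / 2`.
#'
#' @param x Log10 concentration(s) in uM.
#' @param e0,e_inf,slope_n,log10_te50 Model parameters.
#' @return Modelled relative intensity (%).
#' @export
logistic4 <- function(x, e0, e_inf, slope_n, log10_te50) {
  e_inf + (e0 - e_inf) / (1 + 10^(slope_n * (log10_te50 - x)))
}

#' Per-concentration relative intensities for one peptide and compound
#'
#' Computes the mean detected treated intensity at each concentration as a
#' percentage of the mean detected control intensity. A concentration with
#' no detected treated replicate contributes no point; a peptide with fewer
#' than two detected controls is skipped (`NULL` with a message).
#'
#' @param quant Long tibble of one peptide's detected intensities.
#' @param meta Sample table (dose-response design).
#' @param compound Compound id.
#' @return Tibble with `concentration_um`, `x` (log10 uM), `y` (percent of
#'   control), `n_treated`; or `NULL` when no control baseline exists.
#' @export
response_points <- function(quant, meta, compound) {
  dat <- inner_join(quant, meta, by = "sample_id")
  ctrl <- dat$intensity[dat$role == "control"]
  if (length(ctrl) < 2) {
    message("response_points: fewer than two detected controls; skipped")
    return(NULL)
  }
  dat %>%
    filter(.data$role == "treated", .data$compound_id == compound) %>%
    group_by(.data$concentration_um) %>%
    summarise(
      y = 100 * mean(.data$intensity) / mean(ctrl),
      n_treated = n(), .groups = "drop"
    ) %>%
    mutate(x = log10(.data$concentration_um)) %>%
    select("concentration_um", "x", "y", "n_treated") %>%
    arrange(.data$x)
}

#' Fit the bounded 4-parameter logistic to a concentration series
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt via
#' [minpack.lm::nlsLM()]) of [logistic4()] to per-concentration relative
#' intensities, under the constraints `60 <= e0 <= 140`, `e_inf >= 0`,
#' `-50 <= slope_n <= 0`, and `log10_te50` within `log10_te50_margin`
#' (default 3) log units of the tested concentration range. Initialisation
#' is deterministic (`e0 = 100`, `e_inf = 0`, `slope_n = -1`,
#' `log10_te50 = median(x)`), so the fit is reproducible. Standard errors
#' come from the estimated parameter covariance; `pte50 = 6 - log10_te50`
#' converts the uM-scale midpoint to -log10 molar.
#'
#' @param points Tibble with `x` (log10 uM) and `y` (% of control), one row
#'   per concentration (see [response_points()]).
#' @param n_conc_min Minimum number of concentrations with data (default 5);
#'   below it no fit is attempted.
#' @param e0_bounds,e_inf_min,slope_bounds,log10_te50_margin Box constraints.
#' @return One-row tibble: parameter estimates and standard errors,
#'   `pte50`, `r_squared`, `n_conc_used`, `converged`, `at_bound`
#'   (comma-joined names of active bounds, `""` if none), `reason` (why a
#'   fit is absent, `""` otherwise).
#' @export
fit_4pl <- function(points, n_conc_min = 5L,
                    e0_bounds = c(60, 140), e_inf_min = 0,
                    slope_bounds = c(-50, 0), log10_te50_margin = 3) {
  no_fit <- function(reason, n) {
    tibble(
      e0 = NA_real_, e_inf = NA_real_, slope_n = NA_real_,
      log10_te50 = NA_real_, pte50 = NA_real_,
      se_e0 = NA_real_, se_e_inf = NA_real_, se_slope_n = NA_real_,
      se_log10_te50 = NA_real_, r_squared = NA_real_,
      n_conc_used = n, converged = FALSE, at_bound = "", reason = reason
    )
  }
  if (is.null(points) || nrow(points) < n_conc_min) {
    return(no_fit("too_few_concentrations",
                  if (is.null(points)) 0L else nrow(points)))
  }
  x <- points$x
  y <- points$y
  lower <- c(e0 = e0_bounds[1], e_inf = e_inf_min,
             slope_n = slope_bounds[1], log10_te50 = min(x) - log10_te50_margin)
  upper <- c(e0 = e0_bounds[2], e_inf = Inf,
             slope_n = slope_bounds[2], log10_te50 = max(x) + log10_te50_margin)
  # deterministic start ladder: the canonical start first, then fallbacks
  # spanning shallow/steep slopes and off-centre midpoints for curves the
  # primary start cannot reach (no random restarts)
  mid_guess <- x[which.min(abs(y - (max(y) + min(y)) / 2))]
  starts <- list(
    list(e0 = 100, e_inf = 0, slope_n = -1, log10_te50 = median(x)),
    list(e0 = 100, e_inf = 0, slope_n = -1, log10_te50 = mid_guess),
    list(e0 = 100, e_inf = 0, slope_n = -0.3,
         log10_te50 = unname(stats::quantile(x, 0.25))),
    list(e0 = 100, e_inf = 0, slope_n = -3,
         log10_te50 = unname(stats::quantile(x, 0.75)))
  )
  try_start <- function(start) {
    start <- Map(function(s, lo, up) min(max(s, lo), up), start, lower, upper)
    tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        y ~ logistic4(x, e0, e_inf, slope_n, log10_te50),
        data = data.frame(x = x, y = y),
        start = start, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )),
      error = function(e) NULL
    )
  }
  fit <- try_start(starts[[1]])
  if (is.null(fit) || !isTRUE(fit$convInfo$isConv)) {
    for (st in starts[-1]) {
      cand <- try_start(st)
      if (is.null(cand)) next
      if (is.null(fit) || stats::deviance(cand) < stats::deviance(fit)) {
        fit <- cand
      }
      if (isTRUE(fit$convInfo$isConv)) break
    }
  }
  if (is.null(fit)) {
    return(no_fit("fit_failed", nrow(points)))
  }
  est <- coef(fit)
  se <- tryCatch(
    summary(fit)$coefficients[, "Std. Error"],
    error = function(e) setNames(rep(NA_real_, 4), names(est))
  )
  resid <- y - logistic4(x, est["e0"], est["e_inf"],
                         est["slope_n"], est["log10_te50"])
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  tol <- 1e-6
  at <- c(
    if (est["e0"] <= lower["e0"] + tol) "e0_low",
    if (est["e0"] >= upper["e0"] - tol) "e0_high",
    if (est["e_inf"] <= lower["e_inf"] + tol) "e_inf_low",
    if (est["slope_n"] <= lower["slope_n"] + tol) "slope_low",
    if (est["slope_n"] >= upper["slope_n"] - tol) "slope_high",
    if (est["log10_te50"] <= lower["log10_te50"] + tol) "te50_low",
    if (est["log10_te50"] >= upper["log10_te50"] - tol) "te50_high"
  )
  tibble(
    e0 = unname(est["e0"]), e_inf = unname(est["e_inf"]),
    slope_n = unname(est["slope_n"]),
    log10_te50 = unname(est["log10_te50"]),
    pte50 = 6 - unname(est["log10_te50"]),
    se_e0 = unname(se["e0"]), se_e_inf = unname(se["e_inf"]),
    se_slope_n = unname(se["slope_n"]),
    se_log10_te50 = unname(se["log10_te50"]),
    r_squared = r2, n_conc_used = nrow(points),
    converged = fit$convInfo$isConv %||% TRUE,
    at_bound = paste(at, collapse = ","), reason = ""
  )
}

#' Curve-quality assessment for a 4PL fit
#'
#' A fit passes when it converged with `r_squared >= r2_min`, the midpoint
#' standard error is at most `stderr_log10_te50_max`, the midpoint lies no
#' more than `potency_margin` log units above the highest tested
#' concentration (in-range potency), and the dynamic span `e0 - e_inf` is at
#' least `span_min` percentage points. These defaults are this package's own
#' operating point; all are configurable.
#'
#' @param fit One-row tibble from [fit_4pl()].
#' @param max_log10_conc Log10 of the highest tested concentration (uM).
#' @param r2_min,span_min,stderr_log10_te50_max,potency_margin Thresholds.
#' @return Logical: passes quality filtering.
#' @export
assess_fit <- function(fit, max_log10_conc,
                       r2_min = 0.8, span_min = 30,
                       stderr_log10_te50_max = 1.0, potency_margin = 0.5) {
  isTRUE(fit$converged) &&
    !is.na(fit$r_squared) && fit$r_squared >= r2_min &&
    !is.na(fit$se_log10_te50) &&
    fit$se_log10_te50 <= stderr_log10_te50_max &&
    fit$log10_te50 <= max_log10_conc + potency_margin &&
    (fit$e0 - fit$e_inf) >= span_min
}

#' Fit all concentration-response curves of an experiment
#'
#' Runs [response_points()] + [fit_4pl()] + [assess_fit()] for every
#' (compound, site) pair with treated detections.
#'
#' @param quants Site-mapped, deduplicated peptide quantities.
#' @param meta Dose-response sample table.
#' @param n_conc_min,quality See [fit_4pl()], [assess_fit()].
#' @return Tibble, one row per (compound, site), of fit parameters plus
#'   `passes_quality`.
#' @export
fit_dose_response <- function(quants, meta, n_conc_min = 5L,
                              quality = list()) {
  q <- modifyList(
    list(r2_min = 0.8, span_min = 30, stderr_log10_te50_max = 1.0,
         potency_margin = 0.5),
    quality
  )
  max_x <- log10(max(meta$concentration_um, na.rm = TRUE))
  compounds <- unique(meta$compound_id[meta$role == "treated"])
  peptides <- quants %>%
    filter(!is.na(.data$residue_index)) %>%
    distinct(
      .data$protein_accession, .data$residue_index, .data$stripped_sequence,
      .data$dtb_positions, .data$other_mod_key
    )
  res <- list()
  for (i in seq_len(nrow(peptides))) {
    quant <- semi_join(quants, peptides[i, ],
                       by = names(peptides))
    for (cmp in compounds) {
      pts <- suppressMessages(response_points(quant, meta, cmp))
      if (is.null(pts) || nrow(pts) == 0) next
      fit <- fit_4pl(pts, n_conc_min = n_conc_min)
      fit$passes_quality <- assess_fit(
        fit, max_x,
        r2_min = q$r2_min, span_min = q$span_min,
        stderr_log10_te50_max = q$stderr_log10_te50_max,
        potency_margin = q$potency_margin
      )
      res[[length(res) + 1]] <- dplyr::bind_cols(
        tibble(compound_id = cmp), peptides[i, ], fit
      )
    }
  }
  if (length(res) == 0) {
    return(tibble())
  }
  bind_rows(res)
}

#' Count off-targets within a potency window of a reference site
#'
#' Among a compound's quality-passing fits, counts the sites other than the
#' reference whose pTE50 is within `window` log units below the reference
#' potency or above it (i.e. `pte50 >= pte50(reference) - window`).
#'
#' @param fits Tibble of passing fits for ONE compound (must carry
#'   `protein_accession`, `residue_index`, `pte50`).
#' @param reference_accession,reference_residue Reference site key.
#' @param window Potency window in pTE50 units (default 0.5).
#' @return Integer count.
#' @export
count_off_targets <- function(fits, reference_accession, reference_residue,
                              window = 0.5) {
  is_ref <- fits$protein_accession == reference_accession &
    fits$residue_index == reference_residue
  if (!any(is_ref)) {
    stop_validation("reference site has no passing fit for this compound")
  }
  ref_pte50 <- fits$pte50[is_ref][1]
  sum(!is_ref & fits$pte50 >= ref_pte50 - window)
}
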