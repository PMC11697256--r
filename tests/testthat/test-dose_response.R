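te50_series <- function() log10(200 / 2^(9:0))

test_that("relative intensities are percent of the control mean", {
  meta <- make_meta(n_ctrl = 4, conc = c(2, 10, 50), n_trt = 1)
  intens <- setNames(
    c(rep(200, 4), 160, 100, 40), meta$sample_id
  )
  pts <- response_points(make_quant(intens), meta, "CMP001")
  expect_equal(pts$y, c(80, 50, 20))
  expect_equal(pts$x, log10(c(2, 10, 50)))

  # treated equal to control mean -> 100%
  pts2 <- response_points(
    make_quant(setNames(c(rep(200, 4), 200, 200, 200), meta$sample_id)),
    meta, "CMP001"
  )
  expect_equal(pts2$y, rep(100, 3))

  # a concentration with no detections contributes no point
  pts3 <- response_points(
    make_quant(intens[-6]), meta, "CMP001"
  )
  expect_equal(nrow(pts3), 2)
  expect_equal(pts3$concentration_um, c(2, 50))

  # fewer than two detected controls: peptide skipped
  expect_message(
    out <- response_points(make_quant(intens[-(1:3)]), meta, "CMP001"),
    "fewer than two"
  )
  expect_null(out)
})

test_that("noiseless 4PL series is recovered to 1e-3", {
  x <- te50_series()
  truth <- list(e0 = 100, e_inf = 0, slope_n = -1, log10_te50 = 1)
  y <- logistic4(x, truth$e0, truth$e_inf, truth$slope_n, truth$log10_te50)
  fit <- fit_4pl(tibble::tibble(x = x, y = y))
  expect_true(fit$converged)
  expect_equal(fit$e0, truth$e0, tolerance = 1e-3)
  expect_equal(fit$e_inf, truth$e_inf, tolerance = 1e-3)
  expect_equal(fit$slope_n, truth$slope_n, tolerance = 1e-3)
  expect_equal(fit$log10_te50, truth$log10_te50, tolerance = 1e-3)
  expect_gte(fit$r_squared, 0.999999)
  expect_equal(fit$pte50, 6 - fit$log10_te50)
})

test_that("the curve midpoint equals (e0 + e_inf) / 2 exactly", {
  expect_equal(logistic4(1.3, 104, 12, -1.7, 1.3), (104 + 12) / 2)
  expect_equal(logistic4(-2, 80, 5, -49, -2), (80 + 5) / 2)
})

test_that("the model is monotone non-increasing for negative slope", {
  x <- seq(-3, 4, length.out = 200)
  y <- logistic4(x, 120, 10, -2.3, 0.7)
  expect_true(all(diff(y) <= 0))
})

test_that("fits honour the parameter bounds and flag at-bound solutions", {
  x <- te50_series()
  # a 170% top plateau drives e0 onto its upper bound
  y_high <- logistic4(x, 170, 0, -1, 1)
  fit <- fit_4pl(tibble::tibble(x = x, y = y_high))
  expect_true(fit$converged)
  expect_equal(fit$e0, 140)
  expect_match(fit$at_bound, "e0_high")
  # a negative bottom plateau drives e_inf onto its lower bound
  y_neg <- logistic4(x, 100, -40, -1, 1)
  fit2 <- fit_4pl(tibble::tibble(x = x, y = y_neg))
  expect_true(fit2$converged)
  expect_equal(fit2$e_inf, 0)
  expect_match(fit2$at_bound, "e_inf_low")
  for (f in list(fit, fit2)) {
    expect_gte(f$e0, 60); expect_lte(f$e0, 140)
    expect_gte(f$e_inf, 0)
    expect_gte(f$slope_n, -50); expect_lte(f$slope_n, 0)
    expect_gte(f$log10_te50, min(x) - 3)
    expect_lte(f$log10_te50, max(x) + 3)
  }
})

test_that("too few concentrations yields no fit with a recorded reason", {
  x <- te50_series()[1:4]
  y <- logistic4(x, 100, 0, -1, 1)
  fit <- fit_4pl(tibble::tibble(x = x, y = y))
  expect_false(fit$converged)
  expect_equal(fit$reason, "too_few_concentrations")
  expect_true(is.na(fit$pte50))
})

test_that("quality assessment applies the stated rules", {
  x <- te50_series()
  good <- fit_4pl(tibble::tibble(x = x, y = logistic4(x, 100, 0, -1, 1)))
  expect_true(assess_fit(good, max_log10_conc = log10(200)))

  # flat curve: span below 30 fails
  set.seed(3)
  flat <- fit_4pl(tibble::tibble(
    x = x, y = logistic4(x, 100, 95, -1, 1) + rnorm(10, 0, 0.2)
  ))
  expect_false(assess_fit(flat, max_log10_conc = log10(200)))

  # midpoint far beyond the tested range fails on potency
  late <- fit_4pl(tibble::tibble(x = x, y = logistic4(x, 100, 0, -1, 6)))
  expect_false(assess_fit(late, max_log10_conc = log10(200)))
})

test_that("off-target counting matches a brute-force scan", {
  fits <- tibble::tibble(
    protein_accession = c("REF", letters[1:2]),
    residue_index = 1L,
    pte50 = c(5.4, 5.2, 4.0)
  )
  expect_equal(count_off_targets(fits, "REF", 1, window = 0.5), 1)
  expect_equal(count_off_targets(fits[1, ], "REF", 1), 0)
  expect_error(count_off_targets(fits, "MISSING", 1),
               class = "covscreen_validation_error")

  set.seed(17)
  many <- tibble::tibble(
    protein_accession = c("REF", sprintf("T%02d", 1:10)),
    residue_index = 1L,
    pte50 = c(5.0, runif(10, 3.5, 6.0))
  )
  brute <- sum(many$pte50[-1] >= many$pte50[1] - 0.5)
  expect_equal(count_off_targets(many, "REF", 1), brute)
})

test_that("fit_dose_response fits every responding compound-site pair", {
  spikes <- tibble::tibble(
    compound_index = 1:2, site_index = c(2L, 5L),
    te50_um = c(10, 3), max_engagement = 1
  )
  cfg <- sim_config(
    design = "dose_response", n_proteins = 3, n_sites = 6, n_compounds = 2,
    cv = 0, detect_midpoint = -Inf, spikes = spikes, seed = 4
  )
  sim <- simulate_dose_response(cfg)
  quants <- map_sites(
    collapse_precursors(covscreen:::read_precursor_report_tibble(sim$report)),
    sim$proteome
  )
  fits <- fit_dose_response(quants, sim$meta)
  expect_equal(nrow(fits), 12)  # 6 sites x 2 compounds
  hit1 <- fits[fits$compound_id == "CMP001" &
                 fits$protein_accession == sim$truth$protein_accession[1] &
                 fits$residue_index == sim$truth$residue_index[1], ]
  expect_equal(hit1$log10_te50, 1, tolerance = 1e-3)
  expect_true(hit1$passes_quality)
  # unspiked pairs are flat: they must fail the span criterion
  flat <- fits[!paste(fits$compound_id, fits$protein_accession,
                      fits$residue_index) %in%
                 paste(sim$truth$compound_id, sim$truth$protein_accession,
                       sim$truth$residue_index), ]
  expect_true(all(!flat$passes_quality))
})
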