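test_that("welch_t matches R's t.test and honours its conventions", {
  # identical samples: no effect
  w <- welch_t(c(10, 12, 11, 13), c(10, 12, 11, 13))
  expect_equal(w$t, 0)
  expect_equal(w$p, 1)

  # textbook example against the independent implementation
  x <- c(5.0, 5.2, 4.8)
  y <- c(3.0, 3.1, 2.9)
  w <- welch_t(x, y)
  o <- oracle_welch(x, y)
  expect_equal(w$t, o$t, tolerance = 1e-12)
  expect_equal(w$df, o$df, tolerance = 1e-12)
  expect_equal(w$p, o$p, tolerance = 1e-12)

  # antisymmetry: swapping groups negates t, preserves df and p
  w2 <- welch_t(y, x)
  expect_equal(w2$t, -w$t)
  expect_equal(w2$df, w$df)
  expect_equal(w2$p, w$p)

  # degenerate conventions: zero variance in both groups
  same <- welch_t(c(5, 5, 5), c(5, 5))
  expect_equal(same$p, 1)
  expect_false(same$degenerate)
  diff <- welch_t(c(5, 5, 5), c(4, 4))
  expect_equal(diff$p, 0)
  expect_true(diff$degenerate)

  expect_error(welch_t(1, c(1, 2)), class = "covscreen_validation_error")
})

test_that("a pure 4-fold competition gives mean log2 CR of exactly 2", {
  meta <- make_meta(n_ctrl = 16, n_trt = 4)
  intens <- setNames(
    c(rep(100, 16), rep(25, 4)), meta$sample_id
  )
  rec <- call_hits(make_quant(intens), meta)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$mean_log2_cr, 2)
  expect_equal(rec$n_treated_detected, 4L)
  expect_equal(rec$n_control_detected, 16L)
  expect_equal(rec$frac_detected_all, 1)
  expect_equal(rec$filter_flags, "")
  # zero-variance convention: infinitely significant difference
  expect_true(rec$degenerate_p)
  expect_true(rec$is_hit)

  # treated identical to controls: no competition, no hit
  rec0 <- call_hits(make_quant(setNames(rep(100, 20), meta$sample_id)), meta)
  expect_equal(rec0$mean_log2_cr, 0)
  expect_false(rec0$is_hit)
})

test_that("competition statistics match a from-scratch recomputation", {
  meta <- make_meta(n_ctrl = 16, n_trt = 4)
  set.seed(99)
  sdlog <- sqrt(log(1 + 0.25^2))
  ctrl <- rlnorm(16, log(100), sdlog)
  trt <- rlnorm(4, log(100), sdlog) * 0.25
  q <- make_quant(setNames(c(ctrl, trt), meta$sample_id))
  rec <- call_hits(q, meta)

  # brute-force recomputation from the same drawn numbers
  expect_equal(rec$mean_log2_cr,
               mean(log2(mean(ctrl)) - log2(trt)), tolerance = 1e-10)
  o <- oracle_welch(log2(ctrl), log2(trt))
  expect_equal(rec$p_value, o$p, tolerance = 1e-10)
  expect_equal(rec$t, o$t, tolerance = 1e-10)
  expect_equal(rec$cv_control, sd(ctrl) / mean(ctrl), tolerance = 1e-12)

  # ratio-of-means mode
  rec2 <- call_hits(q, meta, competition_params(cr_mode = "ratio_of_means"))
  expect_equal(rec2$mean_log2_cr, log2(mean(ctrl) / mean(trt)),
               tolerance = 1e-10)

  # raw-scale test option
  rec3 <- call_hits(q, meta, competition_params(test_scale = "raw"))
  o3 <- oracle_welch(ctrl, trt)
  expect_equal(rec3$p_value, o3$p, tolerance = 1e-10)
})

test_that("intensity rescaling acts on log2 CR and p as expected", {
  meta <- make_meta(n_ctrl = 8, n_trt = 4)
  set.seed(5)
  base <- setNames(rlnorm(12, log(500), 0.3), meta$sample_id)
  r1 <- call_hits(make_quant(base), meta)

  # unit change (all samples scaled together): CR and p both invariant
  r_all <- call_hits(make_quant(base * 1000), meta)
  expect_equal(r_all$mean_log2_cr, r1$mean_log2_cr, tolerance = 1e-12)
  expect_equal(r_all$p_value, r1$p_value, tolerance = 1e-12)

  # scaling the treated set alone shifts mean log2 CR by exactly -log2(f)
  trt_ids <- meta$sample_id[meta$role == "treated"]
  scaled <- base
  scaled[trt_ids] <- scaled[trt_ids] / 8
  r2 <- call_hits(make_quant(scaled), meta)
  expect_equal(r2$mean_log2_cr - r1$mean_log2_cr, 3, tolerance = 1e-12)
  # the log-scale test sees the same within-group spread: same Welch df
  expect_equal(r2$df, r1$df, tolerance = 1e-12)
})

test_that("each filter in the cascade forces a non-hit on its own", {
  meta <- make_meta(n_ctrl = 16, n_trt = 4)
  trt_ids <- meta$sample_id[meta$role == "treated"]
  ctrl_ids <- meta$sample_id[meta$role == "control"]
  set.seed(31)
  jitter <- function(n, mu) rlnorm(n, log(mu), 0.1)
  clean <- setNames(c(jitter(16, 100), jitter(4, 25)), meta$sample_id)

  expect_true(call_hits(make_quant(clean), meta)$is_hit)

  # only one treated detection
  q <- make_quant(clean[c(ctrl_ids, trt_ids[1])])
  r <- call_hits(q, meta)
  expect_match(r$filter_flags, "low_treated_n")
  expect_false(r$is_hit)

  # detected in < 90% of all samples (drop 3 of 20)
  q <- make_quant(clean[-(1:3)])
  r <- call_hits(q, meta)
  expect_match(r$filter_flags, "low_completeness")
  expect_false(r$is_hit)

  # control CV above 40%
  noisy <- clean
  noisy[ctrl_ids] <- c(rep(20, 8), rep(200, 8))
  r <- call_hits(make_quant(noisy), meta)
  expect_gt(r$cv_control, 0.4)
  expect_match(r$filter_flags, "high_cv")
  expect_false(r$is_hit)

  # more than one DTB modification
  q <- make_quant(clean, stripped = "ACDCEK", dtb_pos = "2,4", dtb_count = 2)
  r <- call_hits(q, meta)
  expect_match(r$filter_flags, "multi_dtb")
  expect_false(r$is_hit)

  # redundant cleavage form (dedupe skipped): weaker form can never be a hit
  q <- dplyr::bind_rows(
    make_quant(clean, stripped = "ACDEFK"),
    make_quant(clean / 10, stripped = "ACDEFKLLR")
  )
  r <- call_hits(q, meta)
  weak <- r[r$stripped_sequence == "ACDEFKLLR", ]
  expect_match(weak$filter_flags, "redundant_form")
  expect_false(weak$is_hit)
  expect_true(r[r$stripped_sequence == "ACDEFK", ]$is_hit)
})

test_that("zero treated detections yields a scored-but-unhittable record", {
  meta <- make_meta(n_ctrl = 4, n_trt = 2)
  ctrl_only <- setNames(rep(100, 4), meta$sample_id[meta$role == "control"])
  rec <- call_hits(make_quant(ctrl_only), meta)
  expect_equal(rec$n_treated_detected, 0L)
  expect_true(is.na(rec$p_value))
  expect_false(rec$is_hit)
})

test_that("empty input produces an empty record table", {
  meta <- make_meta(n_ctrl = 2, n_trt = 2)
  rec <- call_hits(make_quant(c(s_none = 1))[0, ], meta)
  expect_equal(nrow(rec), 0)
})

test_that("site_competition scores a single peptide against one compound", {
  meta <- make_meta(n_ctrl = 16, compounds = c("CMP001", "CMP002"), n_trt = 4)
  intens <- setNames(
    c(rep(100, 16), rep(25, 4), rep(100, 4)), meta$sample_id
  )
  rec <- site_competition(make_quant(intens), meta, "CMP001")
  expect_equal(nrow(rec), 1)
  expect_equal(rec$compound_id, "CMP001")
  expect_equal(rec$mean_log2_cr, 2)
  q2 <- dplyr::bind_rows(
    make_quant(intens), make_quant(intens, stripped = "GGCDDK")
  )
  expect_error(site_competition(q2, meta, "CMP001"),
               class = "covscreen_validation_error")
})
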