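test_that("collapse sums charge states and Met-oxidation variants only", {
  rep_rows <- make_report_rows(
    sample_id = c("s1", "s1", "s1", "s1", "s1", "s1"),
    acc = "P1",
    modified = c(
      "AC[DTB]DEFK", "AC[DTB]DEFK",                 # charges 2 and 3
      "AC[DTB]DM[Oxidation]EK", "AC[DTB]DMEK",      # oxidation variants
      "AC[DTB]DEFR", "[Acetyl]AC[DTB]DEFK"          # distinct peptides
    ),
    charge = c(2, 3, 2, 2, 2, 2),
    intensity = c(70, 30, 10, 5, 7, 3)
  )
  q <- collapse_precursors(rep_rows)
  get <- function(seq, other = "") {
    q$intensity[q$stripped_sequence == seq & q$other_mod_key == other]
  }
  expect_equal(get("ACDEFK"), 100)       # 70 + 30 across charges
  expect_equal(get("ACDMEK"), 15)        # 10 + 5 across oxidation states
  expect_equal(get("ACDEFR"), 7)         # one-residue difference: separate
  expect_equal(length(get("ACDEFK", other = "1:acetyl")), 1)  # acetyl kept apart
})

test_that("collapse conserves intensity and is order-invariant", {
  set.seed(11)
  n <- 200
  rep_rows <- make_report_rows(
    sample_id = sample(sprintf("s%d", 1:6), n, replace = TRUE),
    acc = sample(c("P1", "P2"), n, replace = TRUE),
    modified = sample(
      c("AC[DTB]DEFK", "GC[DTB]LMNPK", "AC[DTB]DM[Oxidation]EK"),
      n, replace = TRUE
    ),
    charge = sample(2:4, n, replace = TRUE),
    intensity = rlnorm(n, log(100), 1)
  )
  q <- collapse_precursors(rep_rows)
  tot_in <- tapply(rep_rows$intensity, rep_rows$sample_id, sum)
  tot_out <- tapply(q$intensity, q$sample_id, sum)
  expect_equal(as.numeric(tot_out[names(tot_in)]), as.numeric(tot_in))

  shuffled <- rep_rows[sample(n), ]
  expect_equal(collapse_precursors(shuffled), q,
               ignore_attr = "n_non_dtb_dropped")
})

test_that("non-DTB peptides are excluded from the site-level matrix", {
  rep_rows <- make_report_rows(
    sample_id = c("s1", "s1"), acc = "P1",
    modified = c("AC[DTB]DEFK", "AC[Carbamidomethyl]DEFK"),
    charge = 2, intensity = c(10, 20)
  )
  q <- collapse_precursors(rep_rows)
  expect_equal(nrow(q), 1)
  expect_equal(attr(q, "n_non_dtb_dropped"), 1)
})

test_that("site mapping converts peptide positions to protein residues", {
  proteome <- c(P1 = "MACDEKGGG", P2 = "MWACDEKWACDEKL")
  q <- collapse_precursors(make_report_rows(
    sample_id = "s1", acc = c("P1", "P2", "P1"),
    modified = c("AC[DTB]DEK", "AC[DTB]DEK", "QQC[DTB]QQK"),
    charge = 2, intensity = c(1, 1, 1)
  ))
  m <- map_sites(q, proteome)
  p1 <- m[m$protein_accession == "P1" & m$stripped_sequence == "ACDEK", ]
  # peptide starts at protein position 2; C is peptide position 2 -> residue 3
  expect_equal(p1$residue_index, 3L)
  expect_false(p1$ambiguous)
  # repeated subsequence: leftmost occurrence used, ambiguity flagged
  p2 <- m[m$protein_accession == "P2", ]
  expect_equal(p2$residue_index, 4L)
  expect_true(p2$ambiguous)
  # peptide absent from the protein: unmapped
  p3 <- m[m$stripped_sequence == "QQCQQK", ]
  expect_true(p3$unmapped)
  expect_true(is.na(p3$residue_index))
})

test_that("cleavage-form resolution keeps the most abundant form per site", {
  meta_samples <- sprintf("s%d", 1:4)
  # two cleavage forms of the same site: A (mean 200) and B (mean 50)
  q <- dplyr::bind_rows(
    make_quant(setNames(c(200, 210, 190, 200), meta_samples),
               stripped = "ACDEFK", residue = 3),
    make_quant(setNames(c(50, 55, 45, 50), meta_samples),
               stripped = "ACDEFKLLR", residue = 3),
    make_quant(setNames(c(5, 5, 5, 5), meta_samples),
               acc = "P2", stripped = "GGCDDK", dtb_pos = "3", residue = 3)
  )
  dd <- dedupe_cleavage_forms(q)
  kept <- unique(dd$quants$stripped_sequence[
    dd$quants$protein_accession == "P1"
  ])
  expect_equal(kept, "ACDEFK")
  expect_equal(dd$audit$stripped_sequence, "ACDEFKLLR")
  expect_equal(dd$audit$reason, "redundant_cleavage_form")
  # single-form site is untouched
  expect_true("GGCDDK" %in% dd$quants$stripped_sequence)
  # each site now has exactly one peptide form
  forms <- dplyr::distinct(
    dd$quants, protein_accession, residue_index, stripped_sequence
  )
  expect_equal(nrow(forms),
               nrow(dplyr::distinct(forms, protein_accession, residue_index)))
})

test_that("exact abundance ties break to the shorter peptide", {
  # same abundance, lengths 12 vs 9
  q <- dplyr::bind_rows(
    make_quant(c(s1 = 100), stripped = "ACDEFKLLLQQR", residue = 3),
    make_quant(c(s1 = 100), stripped = "ACDEFKLLR", residue = 3)
  )
  dd <- dedupe_cleavage_forms(q)
  expect_equal(unique(dd$quants$stripped_sequence), "ACDEFKLLR")
})

test_that("summed-abundance rule can override the mean rule", {
  # form A: detected once at 300 (mean 300, total 300)
  # form B: detected 4x at 100 (mean 100, total 400)
  q <- dplyr::bind_rows(
    make_quant(c(s1 = 300), stripped = "ACDEFK", residue = 3),
    make_quant(setNames(rep(100, 4), sprintf("s%d", 1:4)),
               stripped = "ACDEFKLLR", residue = 3)
  )
  keep_mean <- dedupe_cleavage_forms(q)$quants
  keep_total <- dedupe_cleavage_forms(q, "most_abundant_total")$quants
  expect_equal(unique(keep_mean$stripped_sequence), "ACDEFK")
  expect_equal(unique(keep_total$stripped_sequence), "ACDEFKLLR")
})
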