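# defaults shared between sim_config() and default_config()
sim_defaults <- function() {
  list(
    design = "single_dose",
    n_proteins = 60L, n_sites = 300L, n_compounds = 8L,
    concentrations_um = NULL,
    n_treated_reps = 4L, n_control_reps = NULL,
    cv = 0.25,
    baseline_log10_mean = 4.5, baseline_log10_sd = 0.8,
    detect_midpoint = 3.62, detect_scale = 0.30,
    charge_split = TRUE,
    spikes = NULL,
    seed = 1L
  )
}

#' Configure a synthetic screen
#'
#' Builds a validated simulation configuration emulating the platform's
#' study conditions. The single-dose design defaults to one 50 uM dose with
#' n = 4 treated vs n = 16 control replicates; the dose-response design to
#' a 10-point two-fold dilution series 200 -> 0.39 uM in quadruplicate
#' against n = 25 shared controls. Intensities are lognormal around a
#' per-peptide baseline (log10 baseline ~ N(4.5, 0.8)) with multiplicative
#' noise of raw-scale CV 25% by default; detection is an
#' intensity-dependent logistic (probability `plogis((log10 I - 3.62)/0.30)`)
#' calibrated so that the mean pairwise replicate overlap of detected
#' peptides is ~0.82, the completeness regime of the real platform. Setting
#' `detect_midpoint = -Inf` forces complete detection.
#'
#' @param design `"single_dose"` or `"dose_response"`.
#' @param n_proteins,n_sites,n_compounds Screen dimensions.
#' @param concentrations_um Dose series (uM); `NULL` picks the design
#'   default.
#' @param n_treated_reps Treated replicates per compound and concentration.
#' @param n_control_reps Control replicates; `NULL` -> 16 (single dose) or
#'   25 (dose response).
#' @param cv Raw-scale coefficient of variation of the intensity noise.
#' @param baseline_log10_mean,baseline_log10_sd Per-peptide baseline
#'   log10-intensity distribution.
#' @param detect_midpoint,detect_scale Detection logistic in log10
#'   intensity.
#' @param charge_split Emit each peptide as two charge-state precursors
#'   whose intensities sum to the peptide intensity (default `TRUE`).
#' @param spikes Tibble of ground-truth liganding events:
#'   `compound_index`, `site_index`, `te50_um`, `max_engagement`.
#' @param seed Integer RNG seed; the whole simulation is deterministic
#'   given it.
#' @return Validated `sim_config` list.
#' @export
sim_config <- function(design = c("single_dose", "dose_response"),
                       n_proteins = 60L, n_sites = 300L, n_compounds = 8L,
                       concentrations_um = NULL,
                       n_treated_reps = 4L, n_control_reps = NULL,
                       cv = 0.25,
                       baseline_log10_mean = 4.5, baseline_log10_sd = 0.8,
                       detect_midpoint = 3.62, detect_scale = 0.30,
                       charge_split = TRUE, spikes = NULL, seed = 1L) {
  design <- match.arg(design)
  if (is.null(concentrations_um)) {
    concentrations_um <- if (design == "dose_response") {
      200 / 2^(9:0)
    } else {
      50
    }
  }
  if (is.null(n_control_reps)) {
    n_control_reps <- if (design == "dose_response") 25L else 16L
  }
  if (!is.null(spikes)) {
    spikes <- as_tibble(spikes)
  }
  cfg <- list(
    design = design,
    n_proteins = as.integer(n_proteins), n_sites = as.integer(n_sites),
    n_compounds = as.integer(n_compounds),
    concentrations_um = as.numeric(concentrations_um),
    n_treated_reps = as.integer(n_treated_reps),
    n_control_reps = as.integer(n_control_reps),
    cv = cv,
    baseline_log10_mean = baseline_log10_mean,
    baseline_log10_sd = baseline_log10_sd,
    detect_midpoint = detect_midpoint, detect_scale = detect_scale,
    charge_split = isTRUE(charge_split),
    spikes = spikes,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  sim_validate(cfg)
}

sim_validate <- function(cfg) {
  if (cfg$n_proteins <= 0 || cfg$n_sites <= 0 || cfg$n_compounds <= 0 ||
      cfg$n_treated_reps <= 0 || cfg$n_control_reps <= 0) {
    stop_validation("simulation counts must be positive")
  }
  if (cfg$n_sites < cfg$n_proteins) {
    stop_validation("n_sites must be at least n_proteins")
  }
  if (!(cfg$cv >= 0 && cfg$cv < 1)) {
    stop_validation("cv must lie in [0, 1)")
  }
  if (any(cfg$concentrations_um <= 0)) {
    stop_validation("concentrations must be strictly positive")
  }
  if (cfg$design == "dose_response" && length(cfg$concentrations_um) < 5) {
    stop_validation("dose_response design needs at least 5 concentrations")
  }
  if (!is.null(cfg$spikes)) {
    sp <- cfg$spikes
    need <- c("compound_index", "site_index", "te50_um", "max_engagement")
    if (!all(need %in% names(sp))) {
      stop_validation(sprintf(
        "spikes must have columns: %s", paste(need, collapse = ", ")
      ))
    }
    if (any(sp$compound_index < 1 | sp$compound_index > cfg$n_compounds) ||
        any(sp$site_index < 1 | sp$site_index > cfg$n_sites)) {
      stop_validation("spike refers to a non-existent compound or site")
    }
    if (any(sp$te50_um <= 0) ||
        any(sp$max_engagement <= 0 | sp$max_engagement > 1)) {
      stop_validation(
        "spike te50 must be positive and max_engagement in (0, 1]"
      )
    }
  }
  cfg
}

#' Equilibrium occupancy of a covalent site
#'
#' Saturation model consistent with the fitted logistic midpoint:
#' `occupancy = c / (c + TE50)`, so occupancy is 0.5 at `c = TE50`, 0.75 at
#' `c = 3 TE50`, and approaches 1 at saturating concentration. Expected
#' treated peptide intensity is
#' `baseline * (1 - occupancy * max_engagement)`.
#'
#' @param concentration_um,te50_um Positive concentrations (uM).
#' @return Occupied fraction in (0, 1).
#' @export
occupancy <- function(concentration_um, te50_um) {
  if (any(concentration_um <= 0) || any(te50_um <= 0)) {
    stop_validation("concentration and te50 must be positive")
  }
  concentration_um / (concentration_um + te50_um)
}

#' Simulate a competitive cysteine-profiling screen
#'
#' Generates a synthetic proteome of tryptic-like single-cysteine peptides,
#' a sample table for the configured design, and a precursor-level report
#' (parseable by [read_precursor_report()]) with known ground truth:
#' spiked (compound, site) pairs have their treated intensities reduced by
#' `occupancy(c, te50) * max_engagement`, all other pairs have engagement
#' factor exactly 1. Fully deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List: `meta` (sample table), `report` (precursor report tibble,
#'   column names matching the default report dialect), `truth` (spiked
#'   events with accession/residue resolved), `proteome` (named character
#'   vector), `sites` (per-site bookkeeping: accession, residue index,
#'   peptide sequence, baseline intensity).
#' @export
simulate_screen <- function(config = sim_config()) {
  cfg <- sim_validate(config)
  set.seed(cfg$seed)

  sites <- sim_sites(cfg)
  proteome <- attr(sites, "proteome")
  meta <- sim_meta(cfg)

  # engagement lookup: default 1, spiked pairs reduced per occupancy
  spikes <- cfg$spikes %||% tibble(
    compound_index = integer(), site_index = integer(),
    te50_um = numeric(), max_engagement = numeric()
  )
  truth <- spikes %>%
    mutate(
      compound_id = sprintf("CMP%03d", .data$compound_index),
      protein_accession = sites$protein_accession[.data$site_index],
      residue_index = sites$residue_index[.data$site_index]
    ) %>%
    select(
      "compound_id", "protein_accession", "residue_index",
      "te50_um", "max_engagement", "site_index", "compound_index"
    )

  grid <- tidyr::expand_grid(
    site_index = seq_len(cfg$n_sites),
    sample_id = meta$sample_id
  ) %>%
    left_join(meta, by = "sample_id") %>%
    left_join(
      truth %>% select("compound_id", "site_index", "te50_um",
                       "max_engagement"),
      by = c("site_index", "compound_id")
    ) %>%
    mutate(
      engagement = ifelse(
        is.na(.data$te50_um), 1,
        1 - .data$concentration_um /
          (.data$concentration_um + .data$te50_um) * .data$max_engagement
      )
    )

  sdlog <- sqrt(log(1 + cfg$cv^2))
  n <- nrow(grid)
  noise <- if (cfg$cv == 0) {
    rep(1, n)
  } else {
    rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  grid$intensity <- sites$baseline[grid$site_index] * grid$engagement * noise
  p_detect <- plogis(
    (log10(grid$intensity) - cfg$detect_midpoint) / cfg$detect_scale
  )
  detected <- runif(n) < p_detect
  peptide_rows <- grid[detected, c("site_index", "sample_id", "intensity")]

  report <- sim_report(peptide_rows, sites, cfg)
  list(
    meta = meta, report = report, truth = truth,
    proteome = proteome, sites = sites
  )
}

#' Simulate a concentration-response experiment
#'
#' [simulate_screen()] restricted to the dose-response design (shared
#' controls, the full dilution series per compound).
#'
#' @param config A [sim_config()] with `design = "dose_response"`.
#' @return Same structure as [simulate_screen()].
#' @export
simulate_dose_response <- function(config) {
  if (config$design != "dose_response") {
    stop_validation("config$design must be 'dose_response'")
  }
  simulate_screen(config)
}

# synthetic proteome: per site one tryptic-like peptide with exactly one C,
# proteins are concatenations of their sites' peptides behind an initiator M
sim_sites <- function(cfg) {
  protein_of <- sort(rep_len(seq_len(cfg$n_proteins), cfg$n_sites))
  lens <- sample(8:18, cfg$n_sites, replace = TRUE)
  body_aa <- setdiff(AA_ALPHABET[1:20], c("C", "K", "R", "P"))
  peps <- vapply(seq_len(cfg$n_sites), function(i) {
    L <- lens[i]
    chars <- sample(body_aa, L - 1L, replace = TRUE)
    cpos <- sample.int(L - 1L, 1)
    chars[cpos] <- "C"
    paste0(paste(chars, collapse = ""), sample(c("K", "R"), 1))
  }, character(1))
  cpos <- as.integer(regexpr("C", peps, fixed = TRUE))
  baseline <- 10^rnorm(cfg$n_sites, cfg$baseline_log10_mean,
                       cfg$baseline_log10_sd)
  sites <- tibble(
    site_index = seq_len(cfg$n_sites),
    protein_index = protein_of,
    peptide = peps,
    c_position_in_peptide = cpos,
    baseline = baseline
  )
  sites <- sites %>%
    group_by(.data$protein_index) %>%
    mutate(
      pep_offset = 1L + cumsum(c(0L, head(nchar(.data$peptide), -1))),
      residue_index = .data$pep_offset + .data$c_position_in_peptide - 1L +
        0L
    ) %>%
    ungroup() %>%
    mutate(
      protein_accession = sprintf("SIMP%04d", .data$protein_index),
      # +1 for the initiator methionine prepended to every protein
      peptide_start = .data$pep_offset + 1L,
      residue_index = .data$residue_index + 1L
    )
  proteome <- vapply(
    split(sites$peptide, sites$protein_index),
    function(p) paste0("M", paste(p, collapse = "")), character(1)
  )
  names(proteome) <- sprintf(
    "SIMP%04d", as.integer(names(proteome))
  )
  attr(sites, "proteome") <- proteome
  sites
}

sim_meta <- function(cfg) {
  ctrl <- tibble(
    sample_id = sprintf("S_ctrl_r%02d", seq_len(cfg$n_control_reps)),
    role = "control",
    compound_id = NA_character_, concentration_um = NA_real_,
    replicate_index = seq_len(cfg$n_control_reps)
  )
  trt <- tidyr::expand_grid(
    compound_index = seq_len(cfg$n_compounds),
    concentration_um = cfg$concentrations_um,
    replicate_index = seq_len(cfg$n_treated_reps)
  ) %>%
    mutate(
      compound_id = sprintf("CMP%03d", .data$compound_index),
      role = "treated",
      sample_id = sprintf(
        "S_%s_c%g_r%d", .data$compound_id, .data$concentration_um,
        .data$replicate_index
      )
    ) %>%
    select("sample_id", "role", "compound_id", "concentration_um",
           "replicate_index")
  bind_rows(ctrl, trt) %>%
    mutate(context = "sim_lysate", experiment_id = "sim_exp")
}

sim_report <- function(peptide_rows, sites, cfg) {
  mod_seq <- paste0(
    substr(sites$peptide, 1, sites$c_position_in_peptide), "[DTB]",
    substring(sites$peptide, sites$c_position_in_peptide + 1L)
  )
  rows <- peptide_rows %>%
    mutate(
      accession = sites$protein_accession[.data$site_index],
      modified_sequence = mod_seq[.data$site_index]
    )
  if (cfg$charge_split) {
    frac <- runif(cfg$n_sites, 0.55, 0.80)
    f <- frac[rows$site_index]
    rows <- bind_rows(
      rows %>% mutate(charge = 2L, intensity = .data$intensity * f),
      rows %>% mutate(charge = 3L, intensity = .data$intensity * (1 - f))
    )
  } else {
    rows$charge <- 2L
  }
  rows %>%
    select("sample_id", "accession", "modified_sequence", "charge",
           "intensity") %>%
    arrange(.data$sample_id, .data$accession, .data$modified_sequence,
            .data$charge)
}

#' Write a simulated screen to disk
#'
#' Writes `meta.tsv`, `report.tsv`, `truth.tsv` and `proteome.fasta` into a
#' directory, in the formats the readers of this package consume.
#'
#' @param sim Output of [simulate_screen()].
#' @param outdir Output directory (created if missing).
#' @return Named list of the written paths, invisibly.
#' @export
write_sim <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    meta = file.path(outdir, "meta.tsv"),
    report = file.path(outdir, "report.tsv"),
    truth = file.path(outdir, "truth.tsv"),
    proteome = file.path(outdir, "proteome.fasta")
  )
  write_table(sim$meta, paths$meta)
  write_table(sim$report, paths$report)
  write_table(sim$truth, paths$truth)
  writeLines(
    paste0(">", names(sim$proteome), "\n", unname(sim$proteome)),
    paths$proteome
  )
  invisible(paths)
}
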