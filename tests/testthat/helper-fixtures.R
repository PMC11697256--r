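# ---- tabular fixture builders -------------------------------------------

make_meta <- function(n_ctrl = 16, compounds = "CMP001", conc = 50,
                      n_trt = 4, experiment = "e1") {
  ctrl <- tibble::tibble(
    sample_id = sprintf("ctrl_%02d", seq_len(n_ctrl)),
    role = "control", compound_id = NA_character_,
    concentration_um = NA_real_, replicate_index = seq_len(n_ctrl)
  )
  trt <- tidyr::expand_grid(
    compound_id = compounds, concentration_um = conc,
    replicate_index = seq_len(n_trt)
  )
  trt$sample_id <- sprintf(
    "%s_c%g_r%d", trt$compound_id, trt$concentration_um, trt$replicate_index
  )
  trt$role <- "treated"
  dplyr::bind_rows(ctrl, trt[, names(ctrl)]) |>
    dplyr::mutate(context = "test", experiment_id = experiment)
}

# one mapped peptide quantity in long form, intensities named by sample_id
make_quant <- function(intensities, acc = "P1", residue = 3,
                       stripped = "ACDEFK", dtb_pos = "2", dtb_count = 1,
                       other = "") {
  tibble::tibble(
    protein_accession = acc, stripped_sequence = stripped,
    dtb_positions = dtb_pos, dtb_count = as.integer(dtb_count),
    other_mod_key = other,
    sample_id = names(intensities), intensity = unname(intensities),
    residue_index = as.integer(residue), peptide_start = 1L,
    ambiguous = FALSE, unmapped = FALSE
  )
}

# precursor-report tibble with the schema read_precursor_report() emits
make_report_rows <- function(sample_id, acc, modified, charge, intensity) {
  parsed <- parse_modified_sequences(modified)
  dplyr::bind_cols(
    tibble::tibble(
      sample_id = sample_id, protein_accession = acc,
      modified_sequence = modified, charge = as.integer(charge)
    ),
    parsed[, c("stripped_sequence", "dtb_count", "metox_count",
               "dtb_positions", "other_mod_key")],
    tibble::tibble(intensity = intensity)
  )
}

# ---- independent oracles -------------------------------------------------

# Welch oracle: R's own implementation (errors on constant data, so only
# used on non-degenerate inputs)
oracle_welch <- function(x, y) {
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

# digestion oracle: regex-based cutter, structurally independent of the
# character-scan implementation
oracle_digest <- function(seq, mc = 0) {
  cuts <- gregexpr("[KR](?!P)", seq, perl = TRUE)[[1]]
  cuts <- cuts[cuts > 0 & cuts < nchar(seq)]
  bounds <- c(0, cuts, nchar(seq))
  out <- list()
  for (m in 0:mc) {
    if (length(bounds) - 1 - m < 1) break
    for (i in seq_len(length(bounds) - 1 - m)) {
      s <- bounds[i] + 1
      e <- bounds[i + 1 + m]
      out[[length(out) + 1]] <- data.frame(
        start = s, end = e, sequence = substr(seq, s, e),
        missed_cleavages = m
      )
    }
  }
  do.call(rbind, out)
}

# selectivity oracle: naive double loop over the full record set
oracle_selectivity <- function(df, top_n = 5) {
  delta <- function(i, key) {
    others <- df$value[df[[key]] == df[[key]][i]]
    # drop one instance of the record's own value
    self <- which(others == df$value[i])[1]
    others <- others[-self]
    if (length(others) == 0) return(NA_real_)
    df$value[i] - mean(utils::head(sort(others, decreasing = TRUE), top_n))
  }
  ds <- vapply(seq_len(nrow(df)), delta, numeric(1), key = "site_id")
  dc <- vapply(seq_len(nrow(df)), delta, numeric(1), key = "compound_id")
  pmin(ds, dc)
}

# pocket oracle: exhaustive pairwise distances
oracle_pocket <- function(thiols, spheres, cutoff, convention) {
  flags <- logical(nrow(thiols))
  for (i in seq_len(nrow(thiols))) {
    dmin <- Inf
    for (j in seq_len(nrow(spheres))) {
      d <- sqrt((thiols$x[i] - spheres$x[j])^2 +
                  (thiols$y[i] - spheres$y[j])^2 +
                  (thiols$z[i] - spheres$z[j])^2)
      if (convention == "surface") d <- d - spheres$radius[j]
      dmin <- min(dmin, d)
    }
    flags[i] <- dmin <= cutoff
  }
  flags
}

# ---- structure-file fixture writers --------------------------------------

pdb_atom_line <- function(serial, name, resn, chain, resno, x, y, z, elem) {
  sprintf(
    "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    serial, name, resn, chain, resno, x, y, z, 1, 0, elem
  )
}

write_toy_pdb <- function(path, residues) {
  # residues: data.frame(resno, resn, x, y, z) -> one CA (+SG for CYS) each
  lines <- character(0)
  serial <- 0
  for (i in seq_len(nrow(residues))) {
    r <- residues[i, ]
    serial <- serial + 1
    lines <- c(lines, pdb_atom_line(
      serial, "CA", r$resn, "A", r$resno, r$x + 1, r$y, r$z, "C"
    ))
    if (r$resn == "CYS" && !isTRUE(r$no_sg)) {
      serial <- serial + 1
      lines <- c(lines, pdb_atom_line(
        serial, "SG", r$resn, "A", r$resno, r$x, r$y, r$z, "S"
      ))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

write_toy_cif <- function(path, residues) {
  hdr <- c(
    "data_toy", "#", "loop_",
    paste0("_atom_site.", c(
      "group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
      "label_comp_id", "label_asym_id", "label_entity_id", "label_seq_id",
      "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
      "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
      "auth_comp_id", "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num"
    ))
  )
  rows <- character(0)
  serial <- 0
  cif_row <- function(serial, elem, name, resn, resno, x, y, z) {
    sprintf(
      "ATOM %d %s %s . %s A 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s A %s 1",
      serial, elem, name, resn, resno, x, y, z, resno, resn, name
    )
  }
  for (i in seq_len(nrow(residues))) {
    r <- residues[i, ]
    serial <- serial + 1
    rows <- c(rows, cif_row(serial, "C", "CA", r$resn, r$resno,
                            r$x + 1, r$y, r$z))
    if (r$resn == "CYS" && !isTRUE(r$no_sg)) {
      serial <- serial + 1
      rows <- c(rows, cif_row(serial, "S", "SG", r$resn, r$resno,
                              r$x, r$y, r$z))
    }
  }
  writeLines(c(hdr, rows, "#"), path)
  path
}

pqr_sphere_line <- function(serial, pocket, x, y, z, radius) {
  sprintf("ATOM  %5d    C STP %5d    %8.3f%8.3f%8.3f %7.2f %7.2f",
          serial, pocket, x, y, z, 0, radius)
}

write_toy_pqr <- function(path, spheres, header = TRUE) {
  lines <- if (header) "HEADER  alpha spheres of pockets" else character(0)
  for (i in seq_len(nrow(spheres))) {
    s <- spheres[i, ]
    lines <- c(lines, pqr_sphere_line(i, s$pocket_id, s$x, s$y, s$z, s$radius))
  }
  writeLines(c(lines, "TER", "END"), path)
  path
}

# random thiol/sphere sets for the geometry oracle
random_geometry <- function(n_thiols, n_spheres, seed) {
  set.seed(seed)
  list(
    thiols = tibble::tibble(
      chain = "A", residue_index = seq_len(n_thiols),
      x = runif(n_thiols, -20, 20), y = runif(n_thiols, -20, 20),
      z = runif(n_thiols, -20, 20), source_model = "synthetic"
    ),
    spheres = tibble::tibble(
      pocket_id = sample(1:5, n_spheres, replace = TRUE),
      x = runif(n_spheres, -20, 20), y = runif(n_spheres, -20, 20),
      z = runif(n_spheres, -20, 20), radius = runif(n_spheres, 3, 5)
    )
  )
}

random_protein <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}
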