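#' Read and validate a sample metadata table
#'
#' The sample table declares the screen design: which runs are DMSO controls
#' and which are compound-treated, at what concentration, and in which
#' experiment. One row per MS run.
#'
#' @param path Tab-separated file with a header row.
#' @param dialect Named list mapping logical column names (`sample_id`,
#'   `role`, `compound_id`, `concentration_um`, `replicate_index`, `context`,
#'   `experiment_id`) to the column names used in the file. Defaults to the
#'   identity mapping of `default_config()$dialect`. `context` and
#'   `experiment_id` are optional in the file and default to `"default"`.
#' @return Tibble with the logical column names, `role` in
#'   `{"control","treated"}`; control rows carry `NA` compound and
#'   concentration.
#' @export
read_sample_table <- function(path, dialect = NULL) {
  dialect <- dialect %||% default_config()$dialect
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("sample_id", "role", "compound_id", "concentration_um",
                "replicate_index")
  for (col in required) {
    file_col <- dialect[[col]] %||% col
    if (!file_col %in% names(raw)) {
      stop_format(sprintf("sample table is missing column '%s'", file_col))
    }
  }
  optional <- c("context", "experiment_id")
  meta <- tibble(
    sample_id = as.character(raw[[dialect$sample_id]]),
    role = as.character(raw[[dialect$role]]),
    compound_id = as.character(raw[[dialect$compound_id]]),
    concentration_um = suppressWarnings(
      as.numeric(raw[[dialect$concentration_um]])
    ),
    replicate_index = as.integer(raw[[dialect$replicate_index]])
  )
  for (col in optional) {
    file_col <- dialect[[col]] %||% col
    meta[[col]] <- if (file_col %in% names(raw)) {
      as.character(raw[[file_col]])
    } else {
      "default"
    }
  }
  validate_sample_meta(meta)
}

#' Validate a sample metadata tibble
#'
#' Enforces the design invariants: unique sample ids; control rows carry no
#' compound or concentration; treated rows carry both.
#'
#' @param meta Tibble as returned by [read_sample_table()].
#' @return `meta`, invisibly validated (returned for piping).
#' @export
validate_sample_meta <- function(meta) {
  dup <- meta$sample_id[duplicated(meta$sample_id)]
  if (length(dup) > 0) {
    stop_validation(sprintf(
      "duplicated sample_id(s): %s", paste(unique(dup), collapse = ", ")
    ))
  }
  bad_role <- setdiff(unique(meta$role), c("control", "treated"))
  if (length(bad_role) > 0) {
    stop_validation(sprintf(
      "role must be 'control' or 'treated'; found: %s",
      paste(bad_role, collapse = ", ")
    ))
  }
  ctrl <- meta$role == "control"
  bad <- ctrl & (!is.na(meta$compound_id) | !is.na(meta$concentration_um))
  if (any(bad)) {
    stop_validation(sprintf(
      "control sample(s) with compound/concentration set: %s",
      paste(meta$sample_id[bad], collapse = ", ")
    ))
  }
  bad <- !ctrl & (is.na(meta$compound_id) | is.na(meta$concentration_um))
  if (any(bad)) {
    stop_validation(sprintf(
      "treated sample(s) missing compound or concentration: %s",
      paste(meta$sample_id[bad], collapse = ", ")
    ))
  }
  if (any(!is.na(meta$concentration_um) & meta$concentration_um <= 0)) {
    stop_validation("concentrations must be positive")
  }
  meta
}

#' Parse inline-bracketed modified peptide sequences
#'
#' The report's modified-sequence grammar is a plain residue string with
#' bracketed tags attached to the preceding residue, e.g.
#' `"AC[DTB]DM[Oxidation]K"`; a leading bracket (before any residue) is an
#' N-terminal modification. Tags are classified through `tokens`
#' (tag -> class); unrecognised tags are kept verbatim as distinct variable
#' modifications rather than rejected.
#'
#' @param mods Character vector of modified sequences.
#' @param tokens Named list/vector mapping tag -> class among
#'   `dtb`, `oxidation`, `carbamidomethyl`, `acetyl`.
#' @return Tibble with one row per input element: `modified_sequence`,
#'   `stripped_sequence`, `dtb_count`, `metox_count`, `dtb_positions`
#'   (comma-joined 1-based positions within the stripped peptide),
#'   `other_mod_key` (canonical string of all non-DTB, non-oxidation mods,
#'   used as part of the peptide identity during aggregation).
#' @export
parse_modified_sequences <- function(mods, tokens = NULL) {
  tokens <- tokens %||% default_config()$mod_tokens
  uniq <- unique(mods)
  parsed <- lapply(uniq, parse_one_modseq, tokens = tokens)
  out <- dplyr::bind_rows(parsed)
  out$modified_sequence <- uniq
  out[match(mods, uniq), , drop = FALSE]
}

parse_one_modseq <- function(ms, tokens) {
  chars <- strsplit(ms, "", fixed = TRUE)[[1]]
  stripped <- character(0)
  tags <- character(0)
  tag_pos <- integer(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      close <- NA_integer_
      j <- i + 1L
      while (j <= length(chars)) {
        if (chars[j] == "]") {
          close <- j
          break
        }
        j <- j + 1L
      }
      if (is.na(close)) {
        stop_format(sprintf("unterminated modification bracket in '%s'", ms))
      }
      tags <- c(tags, paste(chars[(i + 1L):(close - 1L)], collapse = ""))
      tag_pos <- c(tag_pos, max(length(stripped), 1L))
      i <- close + 1L
    } else if (ch %in% LETTERS) {
      stripped <- c(stripped, ch)
      i <- i + 1L
    } else {
      stop_format(sprintf(
        "unparseable character '%s' in modified sequence '%s'", ch, ms
      ))
    }
  }
  seq <- paste(stripped, collapse = "")
  classes <- vapply(
    tags, function(t) as.character(tokens[[t]] %||% t), character(1)
  )
  dtb_idx <- tag_pos[classes == "dtb"]
  if (any(classes == "dtb") && any(stripped[dtb_idx] != "C")) {
    stop_format(sprintf(
      "DTB modification on a non-cysteine residue in '%s'", ms
    ))
  }
  other <- which(classes != "dtb" & classes != "oxidation")
  other_key <- if (length(other) == 0) {
    ""
  } else {
    paste(sort(paste0(tag_pos[other], ":", classes[other])), collapse = ";")
  }
  tibble(
    stripped_sequence = seq,
    dtb_count = length(dtb_idx),
    metox_count = sum(classes == "oxidation"),
    dtb_positions = paste(sort(dtb_idx), collapse = ","),
    other_mod_key = other_key
  )
}

#' Read a precursor-level quantification report
#'
#' Consumes the long-format (one row per sample x precursor) peptide export
#' of a DIA search engine. Missing values are representational: a peptide not
#' detected in a sample simply has no row. Rows with non-positive or
#' non-numeric intensity are dropped and counted (attribute `n_dropped`).
#'
#' @param path Tab-separated file with header.
#' @param dialect Column-name mapping, see `default_config()$report_dialect`.
#' @param mod_tokens Modification tag table, see [parse_modified_sequences()].
#' @param meta Optional sample table; if supplied, report rows referencing an
#'   unknown `sample_id` raise an error.
#' @return Tibble of precursor records: `sample_id`, `protein_accession`,
#'   `stripped_sequence`, `modified_sequence`, `charge`, `dtb_count`,
#'   `metox_count`, `dtb_positions`, `other_mod_key`, `intensity`; attribute
#'   `n_dropped` holds the number of discarded non-positive-intensity rows.
#' @export
read_precursor_report <- function(path, dialect = NULL, mod_tokens = NULL,
                                  meta = NULL) {
  dialect <- dialect %||% default_config()$report_dialect
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("sample_id", "protein_accession", "modified_sequence",
                "charge", "intensity")) {
    file_col <- dialect[[col]] %||% col
    if (!file_col %in% names(raw)) {
      stop_format(sprintf("precursor report is missing column '%s'", file_col))
    }
  }
  rec <- tibble(
    sample_id = as.character(raw[[dialect$sample_id]]),
    protein_accession = as.character(raw[[dialect$protein_accession]]),
    modified_sequence = as.character(raw[[dialect$modified_sequence]]),
    charge = as.integer(raw[[dialect$charge]]),
    intensity = suppressWarnings(as.numeric(raw[[dialect$intensity]]))
  )
  if (!is.null(meta)) {
    unknown <- setdiff(unique(rec$sample_id), meta$sample_id)
    if (length(unknown) > 0) {
      stop_validation(sprintf(
        "report references sample_id(s) absent from metadata: %s",
        paste(unknown, collapse = ", ")
      ))
    }
  }
  keep <- !is.na(rec$intensity) & rec$intensity > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(sprintf(
      "read_precursor_report: dropped %d row(s) with non-positive intensity",
      n_dropped
    ))
  }
  rec <- rec[keep, , drop = FALSE]
  parsed <- parse_modified_sequences(rec$modified_sequence, mod_tokens)
  rec <- dplyr::bind_cols(
    rec[, c("sample_id", "protein_accession", "modified_sequence", "charge")],
    parsed[, c("stripped_sequence", "dtb_count", "metox_count",
               "dtb_positions", "other_mod_key")],
    rec[, "intensity"]
  )
  if (any(rec$charge < 1, na.rm = TRUE)) {
    stop_format("charge must be a positive integer")
  }
  attr(rec, "n_dropped") <- n_dropped
  rec
}

#' Read a protein FASTA file
#'
#' @param path FASTA file; the accession is the first whitespace-delimited
#'   token of each defline.
#' @return Named character vector of uppercase protein sequences.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aa))
  names(seqs) <- vapply(
    strsplit(names(aa), "\\s+"), `[[`, character(1), 1
  )
  seqs
}

#' Write a result table as TSV
#'
#' Deterministic column order (as given); reals are written with full
#' precision so that `read_result_table(write_table(x))` round-trips string
#' and integer columns exactly and reals to at least 12 significant digits.
#'
#' @param records Data frame / tibble (may be empty: a header-only file is
#'   written).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  readr::write_tsv(as_tibble(records), path, progress = FALSE)
  invisible(path)
}

#' Read a result table written by [write_table()]
#'
#' @param path TSV path.
#' @return Tibble with column types guessed from the full file.
#' @export
read_result_table <- function(path) {
  # na = "NA" only: empty strings (e.g. a clean filter_flags field) are
  # data, not missing values; pin the free-text columns to character so an
  # all-empty flag column is not mis-guessed as logical
  hdr <- names(readr::read_tsv(path, n_max = 0, show_col_types = FALSE))
  char_cols <- intersect(hdr, c(
    "sample_id", "role", "compound_id", "context", "experiment_id",
    "protein_accession", "stripped_sequence", "modified_sequence",
    "dtb_positions", "other_mod_key", "filter_flags", "at_bound", "reason",
    "chain", "source_model", "convention", "host_sequence", "peptide"
  ))
  ct <- do.call(readr::cols, c(
    setNames(
      rep(list(readr::col_character()), length(char_cols)), char_cols
    ),
    .default = readr::col_guess()
  ))
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  guess_max = Inf, na = "NA", col_types = ct)
}
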