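# extended IUPAC amino-acid alphabet accepted in input sequences
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWYUOBZJX", "")[[1]]

#' In-silico tryptic digestion
#'
#' Cleaves after lysine or arginine unless the next residue is proline, and
#' enumerates peptides with up to `missed_cleavages` internal skipped sites.
#' The protein C-terminal peptide is always emitted (no cleavage condition
#' applies past the last residue). A peptide is classified `detectable`
#' when it is fully cleaved (`missed_cleavages == 0`) and its length lies in
#' `length_range` (default 7-40 residues, the MS-detectability convention);
#' for emulating a search space use e.g. `length_range = c(7, 52)` with
#' `missed_cleavages = 2`.
#'
#' @param sequence Uppercase amino-acid string.
#' @param missed_cleavages Maximum skipped cleavage sites (default 0).
#' @param length_range Detectable length window, inclusive (default 7-40).
#' @return Tibble: `start`, `end` (1-based inclusive), `sequence`, `length`,
#'   `missed_cleavages`, `detectable`.
#' @export
tryptic_digest <- function(sequence, missed_cleavages = 0L,
                           length_range = c(7L, 40L)) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (length(chars) == 0) stop_validation("sequence must be non-empty")
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad) > 0) {
    stop_format(sprintf(
      "invalid amino-acid character '%s' at position %d",
      chars[bad[1]], bad[1]
    ))
  }
  n <- length(chars)
  # cut points: cleave AFTER position i when chars[i] is K/R and chars[i+1]
  # is not P; the sequence end is always a boundary
  cut_after <- which(
    chars %in% c("K", "R") & c(chars[-1], "") != "P" & seq_len(n) < n
  )
  bounds <- c(0L, cut_after, n)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  out <- list()
  n_frag <- length(starts)
  for (mc in 0:missed_cleavages) {
    if (mc + 1 > n_frag) break
    i <- seq_len(n_frag - mc)
    s <- starts[i]
    e <- ends[i + mc]
    out[[mc + 1]] <- tibble(
      start = s, end = e,
      sequence = substring(sequence, s, e),
      length = e - s + 1L,
      missed_cleavages = mc
    )
  }
  res <- bind_rows(out)
  res$detectable <- res$missed_cleavages == 0L &
    res$length >= length_range[1] & res$length <= length_range[2]
  arrange(res, .data$start, .data$missed_cleavages)
}

#' Proteome-wide cysteine site table with detectability
#'
#' Enumerates every cysteine residue of every protein and classifies it as
#' lying within an MS-detectable fully-cleaved tryptic peptide (7-40
#' residues by default).
#'
#' @param proteome Named character vector, accession -> sequence.
#' @param length_range Detectable peptide length window (default 7-40).
#' @return Tibble, one row per cysteine: `protein_accession`,
#'   `residue_index`, `in_detectable_peptide`, `host_start`, `host_end`,
#'   `host_length`, `host_sequence`.
#' @export
cysteine_site_table <- function(proteome, length_range = c(7L, 40L)) {
  res <- lapply(names(proteome), function(acc) {
    seq <- proteome[[acc]]
    cys <- as.integer(gregexpr("C", seq, fixed = TRUE)[[1]])
    if (length(cys) == 0 || cys[1] == -1L) {
      return(NULL)
    }
    pep <- tryptic_digest(seq, missed_cleavages = 0L,
                          length_range = length_range)
    host <- findInterval(cys, pep$start)
    tibble(
      protein_accession = acc,
      residue_index = cys,
      in_detectable_peptide = pep$detectable[host],
      host_start = pep$start[host],
      host_end = pep$end[host],
      host_length = pep$length[host],
      host_sequence = pep$sequence[host]
    )
  })
  out <- bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble(
      protein_accession = character(), residue_index = integer(),
      in_detectable_peptide = logical(), host_start = integer(),
      host_end = integer(), host_length = integer(),
      host_sequence = character()
    ))
  }
  out
}

#' Join annotation tables onto a cysteine site table
#'
#' Left-joins user-supplied annotation tables (PTM/disulfide flags, pPSE
#' solvent exposure, IDG family / target development level, protein
#' abundance, pocket flags) onto a site table. Protein-level tables are
#' keyed by `protein_accession`; residue-level tables additionally by
#' `residue_index`. Unmatched sites keep `NA` in the annotation columns
#' (absent, not false); duplicate keys within an annotation table are an
#' error. Join statistics (matched row counts) are reported via `message()`.
#'
#' @param sites Tibble from [cysteine_site_table()] (or any table with the
#'   key columns).
#' @param tables Named list of annotation tibbles; each must carry
#'   `protein_accession` and optionally `residue_index` plus its payload
#'   columns.
#' @return `sites` with all annotation payload columns appended.
#' @export
annotate_sites <- function(sites, tables = list()) {
  for (nm in names(tables)) {
    tab <- as_tibble(tables[[nm]])
    if (!"protein_accession" %in% names(tab)) {
      stop_format(sprintf(
        "annotation table '%s' lacks a protein_accession column", nm
      ))
    }
    keys <- intersect(c("protein_accession", "residue_index"), names(tab))
    dup <- tab[duplicated(tab[keys]), keys, drop = FALSE]
    if (nrow(dup) > 0) {
      stop_validation(sprintf(
        "annotation table '%s' has duplicate key(s): %s", nm,
        paste(head(apply(dup, 1, paste, collapse = ":"), 5), collapse = ", ")
      ))
    }
    before <- names(sites)
    sites <- left_join(sites, tab, by = keys)
    payload <- setdiff(names(sites), before)
    n_matched <- sum(stats::complete.cases(
      sites[, payload[1], drop = FALSE]
    ))
    message(sprintf(
      "annotate_sites: '%s' matched %d / %d sites", nm, n_matched,
      nrow(sites)
    ))
  }
  sites
}
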