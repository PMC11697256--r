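#' Collapse precursors to peptide-level intensities
#'
#' Precursor rows that differ only in charge state or methionine-oxidation
#' state are equivalent observations of one modified peptide; their
#' intensities are summed per sample to a single peptide-level intensity.
#' Peptides differing in stripped sequence, in the set of DTB-modified
#' residues, or in any other variable modification (e.g. acetylation) are
#' never merged. Peptides carrying no DTB modification (carbamidomethylated
#' only) are not part of the enriched cysteinome readout and are dropped
#' here, with a count in attribute `n_non_dtb_dropped`.
#'
#' @param records Precursor tibble from [read_precursor_report()].
#' @return Long site-quantity tibble: one row per (peptide, sample) with
#'   `protein_accession`, `stripped_sequence`, `dtb_positions`, `dtb_count`,
#'   `other_mod_key`, `sample_id`, `intensity`. A peptide is detected in a
#'   sample iff at least one contributing precursor was.
#' @export
collapse_precursors <- function(records) {
  n_non_dtb <- 0L
  if (nrow(records) > 0) {
    keep <- records$dtb_count > 0
    n_non_dtb <- sum(!keep)
    records <- records[keep, , drop = FALSE]
  }
  out <- records %>%
    group_by(
      .data$protein_accession, .data$stripped_sequence, .data$dtb_positions,
      .data$dtb_count, .data$other_mod_key, .data$sample_id
    ) %>%
    summarise(intensity = sum(.data$intensity), .groups = "drop") %>%
    arrange(
      .data$protein_accession, .data$stripped_sequence,
      .data$dtb_positions, .data$other_mod_key, .data$sample_id
    )
  attr(out, "n_non_dtb_dropped") <- n_non_dtb
  out
}

#' Map DTB-modified peptides to protein cysteine residue indices
#'
#' Locates each peptide's stripped sequence in its protein and converts the
#' within-peptide position of the (first) DTB-modified cysteine to a 1-based
#' residue index in the protein — the site key under which liganding events
#' are reported. A peptide occurring more than once in its protein is mapped
#' to the leftmost occurrence and flagged `ambiguous`; a peptide not found
#' (or whose accession is absent from the proteome) is flagged `unmapped`
#' (`residue_index` `NA`) and excluded from site-level outputs downstream.
#'
#' @param quants Peptide-level tibble from [collapse_precursors()].
#' @param proteome Named character vector, accession -> protein sequence
#'   (see [read_fasta()]).
#' @return `quants` with columns `residue_index`, `peptide_start`,
#'   `ambiguous`, `unmapped` added.
#' @export
map_sites <- function(quants, proteome) {
  key <- quants %>%
    distinct(
      .data$protein_accession, .data$stripped_sequence, .data$dtb_positions
    )
  map_one <- function(acc, pep, dtbpos) {
    seqs <- proteome[acc]
    if (is.na(seqs)) {
      return(c(NA_integer_, NA_integer_, 0L))
    }
    hits <- gregexpr(pep, seqs, fixed = TRUE)[[1]]
    if (hits[1] == -1L) {
      return(c(NA_integer_, NA_integer_, 0L))
    }
    start <- hits[1]
    first_dtb <- as.integer(strsplit(dtbpos, ",", fixed = TRUE)[[1]][1])
    c(start + first_dtb - 1L, start, as.integer(length(hits) > 1))
  }
  m <- mapply(
    map_one, key$protein_accession, key$stripped_sequence, key$dtb_positions
  )
  key$residue_index <- as.integer(m[1, ])
  key$peptide_start <- as.integer(m[2, ])
  key$ambiguous <- m[3, ] == 1
  key$unmapped <- is.na(key$residue_index)
  n_unmapped <- sum(key$unmapped)
  if (n_unmapped > 0) {
    message(sprintf(
      "map_sites: %d peptide(s) could not be located in the proteome",
      n_unmapped
    ))
  }
  left_join(
    quants, key,
    by = c("protein_accession", "stripped_sequence", "dtb_positions")
  )
}

#' Resolve redundant cleavage forms per cysteine site
#'
#' Missed-cleavage variants (and other distinct peptide forms) covering the
#' same cysteine site are redundant quantifications; only the most abundant
#' form per site is retained for hit calling. "Most abundant" defaults to
#' the highest mean intensity over the samples in which the form was
#' detected; `"most_abundant_total"` uses the summed intensity instead.
#' Exact ties break deterministically: shorter peptide first, then
#' lexicographic sequence, then modification key.
#'
#' @param quants Site-mapped tibble from [map_sites()]. Unmapped peptides are
#'   set aside into the audit table.
#' @param rule `"most_abundant_mean_all_samples"` (default) or
#'   `"most_abundant_total"`.
#' @return List with `quants` (one peptide form per site, long over samples)
#'   and `audit` (tibble of discarded forms and unmapped peptides with a
#'   `reason` column).
#' @export
dedupe_cleavage_forms <- function(quants,
                                  rule = c("most_abundant_mean_all_samples",
                                           "most_abundant_total")) {
  rule <- match.arg(rule)
  unmapped <- filter(quants, .data$unmapped)
  mapped <- filter(quants, !.data$unmapped)
  stat_fun <- if (rule == "most_abundant_total") sum else mean
  form_stats <- mapped %>%
    group_by(
      .data$protein_accession, .data$residue_index,
      .data$stripped_sequence, .data$dtb_positions, .data$other_mod_key
    ) %>%
    summarise(abundance = stat_fun(.data$intensity), .groups = "drop") %>%
    group_by(.data$protein_accession, .data$residue_index) %>%
    arrange(
      dplyr::desc(.data$abundance), nchar(.data$stripped_sequence),
      .data$stripped_sequence, .data$other_mod_key,
      .by_group = TRUE
    ) %>%
    mutate(selected = row_number() == 1L) %>%
    ungroup()
  keep_key <- form_stats %>%
    filter(.data$selected) %>%
    select(
      "protein_accession", "residue_index",
      "stripped_sequence", "dtb_positions", "other_mod_key"
    )
  drop_key <- form_stats %>%
    filter(!.data$selected) %>%
    select(
      "protein_accession", "residue_index",
      "stripped_sequence", "dtb_positions", "other_mod_key", "abundance"
    )
  by_cols <- c("protein_accession", "residue_index", "stripped_sequence",
               "dtb_positions", "other_mod_key")
  kept <- semi_join(mapped, keep_key, by = by_cols)
  audit <- bind_rows(
    drop_key %>%
      distinct(
        .data$protein_accession, .data$residue_index,
        .data$stripped_sequence, .data$dtb_positions, .data$other_mod_key,
        .data$abundance
      ) %>%
      mutate(reason = "redundant_cleavage_form"),
    unmapped %>%
      distinct(
        .data$protein_accession, .data$stripped_sequence, .data$dtb_positions,
        .data$other_mod_key
      ) %>%
      mutate(
        residue_index = NA_integer_, abundance = NA_real_,
        reason = "unmapped"
      )
  )
  list(quants = kept, audit = audit)
}
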