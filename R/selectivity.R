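#' Selectivity scores for compound-site interactions
#'
#' Scores how specific each interaction is relative to the strongest
#' competing interactions: for each record, `delta_site` is its value minus
#' the mean of the (up to) five strongest OTHER compounds at the same
#' cysteine site, `delta_compound` its value minus the mean of the five
#' strongest OTHER sites of the same compound, and
#' `score = min(delta_site, delta_compound)`. The record itself is always
#' excluded from both top-5 sets, so a unique interaction is maximally
#' selective rather than self-penalised. When a site (or compound) has no
#' other interaction at all, the corresponding delta is not computable and
#' the record is flagged `unsupported` (delta `NA`).
#'
#' @param records Competition records (typically [call_hits()] output,
#'   optionally pre-filtered to hits) carrying the value column.
#' @param value_col Column scored; default `"mean_log2_cr"` (log2 scale
#'   keeps deltas interpretable as fold-change ratios). Use a raw-CR column
#'   for the raw-scale variant.
#' @param top_n Size of the "strongest others" set (default 5).
#' @return Tibble: compound/site identities, the value, `delta_site`,
#'   `delta_compound`, `score`, `n_used_site`, `n_used_compound`,
#'   `unsupported`.
#' @export
selectivity_scores <- function(records, value_col = "mean_log2_cr",
                               top_n = 5L) {
  if (nrow(records) == 0) {
    return(tibble(
      compound_id = character(), protein_accession = character(),
      residue_index = integer(), value = numeric(),
      delta_site = numeric(), delta_compound = numeric(), score = numeric(),
      n_used_site = integer(), n_used_compound = integer(),
      unsupported = logical()
    ))
  }
  rec <- records %>%
    mutate(value = .data[[value_col]]) %>%
    filter(!is.na(.data$value)) %>%
    mutate(site_id = paste0(.data$protein_accession, ":",
                            .data$residue_index))
  rec$delta_site <- NA_real_
  rec$n_used_site <- 0L
  rec$delta_compound <- NA_real_
  rec$n_used_compound <- 0L
  fill_deltas <- function(rec, group_col, delta_col, n_col, top_n) {
    for (g in unique(rec[[group_col]])) {
      idx <- which(rec[[group_col]] == g)
      v <- rec$value[idx]
      for (k in seq_along(idx)) {
        others <- v[-k]
        if (length(others) == 0) next
        top <- head(sort(others, decreasing = TRUE), top_n)
        rec[[delta_col]][idx[k]] <- v[k] - mean(top)
        rec[[n_col]][idx[k]] <- length(top)
      }
    }
    rec
  }
  rec <- fill_deltas(rec, "site_id", "delta_site", "n_used_site", top_n)
  rec <- fill_deltas(rec, "compound_id", "delta_compound", "n_used_compound",
                     top_n)
  rec %>%
    mutate(
      score = pmin(.data$delta_site, .data$delta_compound),
      unsupported = is.na(.data$delta_site) | is.na(.data$delta_compound)
    ) %>%
    select(
      "compound_id", "protein_accession", "residue_index", "value",
      "delta_site", "delta_compound", "score",
      "n_used_site", "n_used_compound", "unsupported"
    ) %>%
    arrange(dplyr::desc(.data$score))
}

#' Intersect selectivity across two experiments
#'
#' Joins two record sets (e.g. two cell-line lysates) by (compound, site)
#' and keeps only interactions scored in both, with the more conservative
#' (minimum) score.
#'
#' @param scores1,scores2 Outputs of [selectivity_scores()].
#' @return Tibble of shared interactions with `score = pmin(score1, score2)`.
#' @export
intersect_selectivity <- function(scores1, scores2) {
  inner_join(
    scores1, scores2,
    by = c("compound_id", "protein_accession", "residue_index"),
    suffix = c("_1", "_2")
  ) %>%
    mutate(score = pmin(.data$score_1, .data$score_2)) %>%
    select(
      "compound_id", "protein_accession", "residue_index",
      "score", "score_1", "score_2"
    ) %>%
    arrange(dplyr::desc(.data$score))
}
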