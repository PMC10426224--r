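# Full-length toxin homology screen and the structured screen verdict.

#' Full-length toxin homology screen
#'
#' Aligns the query against every subject in a toxin reference set with
#' [smith_waterman()], keeps the single best alignment per subject, gates
#' candidates at `E <= rule$evalue_max_protein` and calls significance by
#' the 35%-identity-over-80-columns rule (both thresholds configurable via
#' [screen_rule()]). There is no published numeric significance criterion
#' specific to toxins; the same identity/segment rule used for allergens is
#' applied, reflecting structural-homology arguments for 35% identity and
#' ~80-residue protein domains.
#'
#' Database headers may carry table metadata in the
#' `id|organism|description` convention; absent fields become empty
#' strings. The `comment` column is a free-text field reserved for manual
#' inspection notes and is never auto-filled.
#'
#' @inheritParams sliding_window_screen
#' @return `data.frame` with one row per reported subject, sorted by
#'   E-value ascending: `subject_id`, `organism`, `description`,
#'   `subject_length`, `evalue`, `percent_identity`, `alignment_length`,
#'   `score`, `significant`, `comment`. The underlying `local_alignment`
#'   objects are attached as `attr(, "alignments")`, keyed by record id.
#' @export
toxin_screen <- function(query, db, scheme = scoring_scheme("BLOSUM62"),
                         rule = screen_rule(), ctx = NULL) {
  .full_length_screen(query, db, scheme, rule, ctx)
}

#' Structured verdict over the outputs of one query's screens
#'
#' Aggregates full-length hits, epitope matches and window hits into a
#' structured rule-outcome summary. This is deliberately *not* a risk
#' score: it enumerates which screening rules fired and what a human
#' assessor should look at, in the spirit of weight-of-evidence review.
#'
#' @param hits `data.frame` from [toxin_screen()] /
#'   [full_length_allergen_screen()] (may be empty).
#' @param epitopes `data.frame` from [kmer_epitope_scan()] (may be empty).
#' @param windows `data.frame` from [sliding_window_screen()] (may be
#'   empty).
#' @return List with `any_significant_alignment`, `any_flagged_window`,
#'   `epitope_count` (distinct k-mer/subject pairs) and
#'   `items_for_manual_review` (character vector).
#' @export
verdict <- function(hits, epitopes, windows) {
  any_sig <- nrow(hits) > 0L && any(hits$significant)
  any_flag <- nrow(windows) > 0L && any(windows$flagged)
  n_epi <- nrow(epitopes)
  review <- character(0)
  if (any_sig) {
    sig <- hits[hits$significant, , drop = FALSE]
    review <- c(review, sprintf("significant alignment to %s (%.1f%% over %d aa)",
                                sig$subject_id, sig$percent_identity,
                                sig$alignment_length))
  }
  if (any_flag) {
    fl <- windows[windows$flagged, , drop = FALSE]
    review <- c(review, sprintf("flagged window at %d vs %s (%.1f%% over %d aa)",
                                fl$window_start, fl$subject_id,
                                fl$percent_identity, fl$columns))
  }
  if (n_epi > 0L) review <- c(review, unique(epitopes$kmer))
  list(any_significant_alignment = any_sig,
       any_flagged_window = any_flag,
       epitope_count = n_epi,
       items_for_manual_review = review)
}
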