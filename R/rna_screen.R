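# Guide-RNA versus microRNA screen: local nucleotide alignment on both
# strands with an E < 0.01 significance gate.

.normalize_to_dna <- function(record) {
  if (record$alphabet == "dna") return(record)
  res <- gsub("U", "T", record$residues, fixed = TRUE)
  seq_record(record$id, res, "dna", record$description)
}

.revcomp_record <- function(record) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(record$residues)))
  seq_record(record$id, rc, "dna", record$description)
}

#' Screen a guide RNA against a microRNA reference set
#'
#' Both sequences are normalized to DNA letters (U -> T). Each microRNA is
#' aligned to the query with [smith_waterman()] under the nucleotide scheme
#' on the given strand and on its reverse complement, and the better of the
#' two alignments is reported (mature microRNAs are single-stranded, but
#' searching both strands matches the default behaviour of nucleotide
#' search engines and is the conservative choice). A hit is significant
#' when its E-value is strictly below `rule$evalue_max_rna` (default 0.01).
#'
#' @param grna Nucleotide [seq_record()] (RNA or DNA letters).
#' @param mirna_db List of nucleotide [seq_record()] (the microRNA set).
#' @param rule A [screen_rule()].
#' @param ctx An [evalue_context()]; defaults to query length x database
#'   residue total.
#' @param scheme Nucleotide [scoring_scheme()]; default match +5 /
#'   mismatch -4, gap 10/6.
#' @return `data.frame` sorted by E-value: `mirna_id`, `species`,
#'   `strand` (`"+"`/`"-"`), `score`, `columns`, `identities`,
#'   `percent_identity`, `evalue`, `significant`.
#' @export
rna_screen <- function(grna, mirna_db, rule = screen_rule(), ctx = NULL,
                       scheme = scoring_scheme("NUC")) {
  stopifnot(inherits(grna, "seq_record"),
            grna$alphabet %in% c("dna", "rna"),
            inherits(rule, "screen_rule"))
  empty <- data.frame(mirna_id = character(0), species = character(0),
                      strand = character(0), score = integer(0),
                      columns = integer(0), identities = integer(0),
                      percent_identity = numeric(0), evalue = numeric(0),
                      significant = logical(0))
  if (length(mirna_db) == 0L) return(empty)
  q <- .normalize_to_dna(grna)
  params <- ka_params(scheme)
  if (is.null(ctx)) ctx <- .ctx_from_db(q, mirna_db)
  rows <- vector("list", length(mirna_db))
  n <- 0L
  for (mir in mirna_db) {
    stopifnot(inherits(mir, "seq_record"))
    s_fwd <- .normalize_to_dna(mir)
    a_fwd <- smith_waterman(q, s_fwd, scheme)
    a_rev <- smith_waterman(q, .revcomp_record(s_fwd), scheme)
    strand <- if (a_fwd$score >= a_rev$score) "+" else "-"
    aln <- if (strand == "+") a_fwd else a_rev
    if (aln$score == 0L) next
    e <- evalue(aln$score, params, ctx)
    meta <- .parse_subject_meta(mir)
    n <- n + 1L
    rows[[n]] <- data.frame(
      mirna_id = meta$id, species = meta$organism, strand = strand,
      score = aln$score, columns = aln$columns, identities = aln$identities,
      percent_identity = percent_identity(aln), evalue = e,
      significant = (e < rule$evalue_max_rna))
  }
  if (n == 0L) return(empty)
  out <- do.call(rbind, rows[seq_len(n)])
  out <- out[order(out$evalue, out$mirna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract the spacer of a guide RNA
#'
#' The first `spacer_length` nucleotides of a single-guide RNA are the
#' genome-targeting spacer; the remainder is the invariant scaffold. Some
#' screening protocols search the spacer on its own in addition to the
#' full-length guide.
#'
#' @param grna Nucleotide [seq_record()].
#' @param spacer_length Spacer length in nucleotides (default 20).
#' @return [seq_record()] holding the spacer.
#' @export
grna_spacer <- function(grna, spacer_length = 20L) {
  stopifnot(inherits(grna, "seq_record"), grna$alphabet %in% c("dna", "rna"),
            spacer_length >= 1L, seq_length(grna) >= spacer_length)
  seq_record(paste0(grna$id, "_spacer"),
             substr(grna$residues, 1L, spacer_length),
             grna$alphabet, grna$description)
}
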