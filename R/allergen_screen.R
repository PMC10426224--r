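# The three-tier allergenicity screen: full-length 35%/80aa rule,
# sliding 80-residue window search, exact contiguous k-mer epitope scan.

#' Screening significance thresholds
#'
#' Default values reproduce the regulatory screening settings: the Codex
#' Alimentarius cross-reactivity rule (>= 35% identity over an alignment
#' segment of >= 80 residues), 80-residue sliding windows, exact 8-mer
#' epitope scanning (a 6-mer alternative is exposed but discouraged as
#' false-positive-prone), an E <= 10 candidate gate for protein searches
#' and E < 0.01 significance for RNA searches.
#'
#' @param identity_threshold Percent identity threshold in (0, 100].
#' @param min_segment Minimum alignment columns for significance.
#' @param window Sliding window length (residues).
#' @param kmer Epitope k-mer length.
#' @param evalue_max_protein E-value ceiling for reported protein hits.
#' @param evalue_max_rna E-value significance ceiling for RNA hits
#'   (significant means strictly below this value).
#' @return Object of class `screen_rule`.
#' @export
screen_rule <- function(identity_threshold = 35, min_segment = 80L,
                        window = 80L, kmer = 8L,
                        evalue_max_protein = 10, evalue_max_rna = 0.01) {
  stopifnot(identity_threshold > 0, identity_threshold <= 100,
            min_segment >= 1L, window >= 1L, kmer >= 1L,
            evalue_max_protein > 0, evalue_max_rna > 0)
  structure(list(identity_threshold = identity_threshold,
                 min_segment = as.integer(min_segment),
                 window = as.integer(window), kmer = as.integer(kmer),
                 evalue_max_protein = evalue_max_protein,
                 evalue_max_rna = evalue_max_rna),
            class = "screen_rule")
}

#' Number of sliding k-mer windows in a sequence
#'
#' The count of stride-1 windows of length k: `max(length - k + 1, 0)`,
#' duplicate substrings included. A sequence shorter than k yields 0 with a
#' warning.
#'
#' @param seq A [seq_record()].
#' @param k Window length (>= 1).
#' @return Integer window count.
#' @examples
#' count_kmer_windows(seq_record("x", "EHIANLAG", "protein"), 8)
#' @export
count_kmer_windows <- function(seq, k) {
  stopifnot(inherits(seq, "seq_record"), k >= 1)
  L <- seq_length(seq)
  if (L < k) {
    warning("sequence '", seq$id, "' (", L,
            " residues) is shorter than k = ", k, "; 0 windows",
            call. = FALSE)
    return(0L)
  }
  L - as.integer(k) + 1L
}

.kmer_table <- function(residues, k) {
  L <- nchar(residues)
  if (L < k) return(data.frame(kmer = character(0), pos = integer(0)))
  starts <- seq_len(L - k + 1L)
  data.frame(kmer = substring(residues, starts, starts + k - 1L),
             pos = starts - 1L)  # 0-based
}

#' Exact k-mer epitope scan of a query against a database
#'
#' Every length-k substring of the query is matched exactly (sequences are
#' already uppercased on input) against every database sequence. K-mers
#' containing the ambiguity character X never match. One row is returned per
#' distinct (k-mer, subject) pair, carrying all 0-based occurrence positions
#' in query and subject, ordered by subject then k-mer.
#'
#' @param query Protein [seq_record()].
#' @param db List of protein [seq_record()] (the allergen set).
#' @param k K-mer length (default 8).
#' @return `data.frame` with columns `kmer`, `subject_id`,
#'   `query_positions`, `subject_positions` (the position columns are list
#'   columns of 0-based integer vectors).
#' @examples
#' q <- read_fasta(fixture_path("hcas9"), "protein")[[1]]
#' s <- read_fasta(fixture_path("hevb9"), "protein")[[1]]
#' kmer_epitope_scan(q, list(s), 8)$kmer
#' @export
kmer_epitope_scan <- function(query, db, k = 8L) {
  stopifnot(inherits(query, "seq_record"), query$alphabet == "protein",
            k >= 1)
  k <- as.integer(k)
  empty <- data.frame(kmer = character(0), subject_id = character(0))
  empty$query_positions <- list(); empty$subject_positions <- list()
  if (length(db) == 0L) {
    warning("empty database: no k-mers to scan", call. = FALSE)
    return(empty)
  }
  qtab <- .kmer_table(query$residues, k)
  qtab <- qtab[!grepl("X", qtab$kmer, fixed = TRUE), , drop = FALSE]
  if (nrow(qtab) == 0L) return(empty)
  qpos <- split(qtab$pos, qtab$kmer)
  out <- list()
  for (subject in db) {
    stopifnot(inherits(subject, "seq_record"))
    stab <- .kmer_table(subject$residues, k)
    stab <- stab[!grepl("X", stab$kmer, fixed = TRUE), , drop = FALSE]
    shared <- sort(intersect(names(qpos), unique(stab$kmer)))
    if (length(shared) == 0L) next
    spos <- split(stab$pos, stab$kmer)
    rows <- data.frame(kmer = shared, subject_id = subject$id)
    rows$query_positions <- unname(qpos[shared])
    rows$subject_positions <- unname(spos[shared])
    out[[length(out) + 1L]] <- rows
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' Sliding-window local alignment screen
#'
#' Every stride-1 window of length `rule$window` of the query (a query
#' shorter than the window yields one full-length window) is aligned to
#' each database subject with [smith_waterman()]. A window hit is *flagged*
#' when its percent identity reaches `rule$identity_threshold` and its
#' alignment spans at least `min(rule$min_segment, window_length)` columns.
#' All window/subject pairs whose E-value is at or below
#' `rule$evalue_max_protein` are returned.
#'
#' @param query Protein [seq_record()].
#' @param db List of protein [seq_record()].
#' @param scheme A [scoring_scheme()]; default BLOSUM62 11/2.
#' @param rule A [screen_rule()].
#' @param ctx An [evalue_context()]; defaults to window length x database
#'   residue total.
#' @return `data.frame` with one row per reported window/subject pair:
#'   `window_start` (0-based), `window_length`, `subject_id`, `score`,
#'   `columns`, `identities`, `percent_identity`, `evalue`, `flagged`.
#' @export
sliding_window_screen <- function(query, db, scheme = scoring_scheme("BLOSUM62"),
                                  rule = screen_rule(), ctx = NULL) {
  stopifnot(inherits(query, "seq_record"), query$alphabet == "protein",
            inherits(rule, "screen_rule"))
  empty <- data.frame(window_start = integer(0), window_length = integer(0),
                      subject_id = character(0), score = integer(0),
                      columns = integer(0), identities = integer(0),
                      percent_identity = numeric(0), evalue = numeric(0),
                      flagged = logical(0))
  if (length(db) == 0L) return(empty)
  L <- seq_length(query)
  w <- min(rule$window, L)
  starts <- seq_len(max(L - w + 1L, 1L)) - 1L
  params <- ka_params(scheme)
  if (is.null(ctx)) {
    ctx <- evalue_context(w, sum(vapply(db, seq_length, numeric(1))),
                          length(db))
  }
  min_cols <- min(rule$min_segment, w)
  out <- vector("list", length(starts) * length(db))
  n_out <- 0L
  for (st in starts) {
    win <- seq_record(paste0(query$id, "_w", st),
                      substr(query$residues, st + 1L, st + w),
                      query$alphabet)
    for (subject in db) {
      aln <- smith_waterman(win, subject, scheme)
      if (aln$score == 0L) next
      e <- evalue(aln$score, params, ctx)
      if (e > rule$evalue_max_protein) next
      pid <- percent_identity(aln)
      n_out <- n_out + 1L
      out[[n_out]] <- data.frame(
        window_start = st, window_length = w, subject_id = subject$id,
        score = aln$score, columns = aln$columns,
        identities = aln$identities, percent_identity = pid, evalue = e,
        flagged = (pid >= rule$identity_threshold && aln$columns >= min_cols))
    }
  }
  if (n_out == 0L) return(empty)
  do.call(rbind, out[seq_len(n_out)])
}

#' Full-length allergen homology screen
#'
#' One best local alignment per database subject; hits with E-value at or
#' below `rule$evalue_max_protein` are returned sorted by E ascending.
#' Each hit carries `significant = (percent_identity >=
#' rule$identity_threshold AND columns >= rule$min_segment)` — the Codex
#' 35%/80aa cross-reactivity criterion at the defaults.
#'
#' @inheritParams sliding_window_screen
#' @return `data.frame` of screen hits (see [toxin_screen()] for the
#'   column schema; allergen and toxin full-length screens share it).
#' @export
full_length_allergen_screen <- function(query, db,
                                        scheme = scoring_scheme("BLOSUM62"),
                                        rule = screen_rule(), ctx = NULL) {
  .full_length_screen(query, db, scheme, rule, ctx)
}

# Shared engine for the full-length allergen and toxin screens.
.full_length_screen <- function(query, db, scheme, rule, ctx) {
  stopifnot(inherits(query, "seq_record"), query$alphabet == "protein",
            inherits(rule, "screen_rule"), inherits(scheme, "scoring_scheme"))
  empty <- data.frame(subject_id = character(0), organism = character(0),
                      description = character(0), subject_length = integer(0),
                      evalue = numeric(0), percent_identity = numeric(0),
                      alignment_length = integer(0), score = integer(0),
                      significant = logical(0), comment = character(0))
  if (length(db) == 0L) {
    warning("empty database: nothing to screen", call. = FALSE)
    return(empty)
  }
  params <- ka_params(scheme)
  if (is.null(ctx)) ctx <- .ctx_from_db(query, db)
  rows <- list()
  alns <- list()
  for (subject in db) {
    aln <- smith_waterman(query, subject, scheme)
    if (aln$score == 0L) next
    e <- evalue(aln$score, params, ctx)
    if (e > rule$evalue_max_protein) next
    pid <- percent_identity(aln)
    meta <- .parse_subject_meta(subject)
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = meta$id, organism = meta$organism,
      description = meta$description, subject_length = seq_length(subject),
      evalue = e, percent_identity = pid, alignment_length = aln$columns,
      score = aln$score,
      significant = (pid >= rule$identity_threshold &&
                       aln$columns >= rule$min_segment),
      comment = "")
    alns[[subject$id]] <- aln
  }
  if (length(rows) == 0L) return(empty)
  hits <- do.call(rbind, rows)
  hits <- hits[order(hits$evalue, hits$subject_id), , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "alignments") <- alns
  hits
}

# Database headers may carry metadata in the "id|organism|description"
# convention; absent fields become empty strings.
.parse_subject_meta <- function(subject) {
  header <- if (nzchar(subject$description)) {
    paste(subject$id, subject$description)
  } else {
    subject$id
  }
  if (grepl("|", header, fixed = TRUE)) {
    parts <- strsplit(header, "|", fixed = TRUE)[[1]]
    list(id = trimws(parts[1]),
         organism = if (length(parts) >= 2L) trimws(parts[2]) else "",
         description = if (length(parts) >= 3L) {
           trimws(paste(parts[-(1:2)], collapse = "|"))
         } else {
           ""
         })
  } else {
    list(id = subject$id, organism = "", description = subject$description)
  }
}
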