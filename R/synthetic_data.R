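# Seeded decoy-database generation: i.i.d. background sequences with
# planted homologous segments, planted exact k-mer epitopes, and
# composition-preserving RNA shuffles.

# Robinson & Robinson (1991) amino-acid background frequencies, the
# standard composition model behind the BLOSUM search statistics.
.AA_BACKGROUND <- c(
  A = 0.07805, C = 0.01925, D = 0.05364, E = 0.06295, F = 0.03856,
  G = 0.07377, H = 0.02199, I = 0.05142, K = 0.05744, L = 0.09019,
  M = 0.02243, N = 0.04487, P = 0.05203, Q = 0.04264, R = 0.05129,
  S = 0.07120, T = 0.05841, V = 0.06441, W = 0.01330, Y = 0.03216)

.default_freqs <- function(alphabet) {
  switch(alphabet,
    protein = .AA_BACKGROUND / sum(.AA_BACKGROUND),
    dna = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
    rna = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25))
}

# Evaluate `code` under a deterministic RNG state without disturbing the
# caller's random stream. All public generators take an explicit seed.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

.random_residues <- function(n, freqs) {
  paste(sample(names(freqs), n, replace = TRUE, prob = freqs), collapse = "")
}

#' Recipe for a synthetic decoy reference database
#'
#' A `decoy_spec` fully determines a decoy database: record count, a
#' uniform length range, residue composition (defaulting to the standard
#' amino-acid background frequencies behind the BLOSUM statistics, or
#' uniform bases for nucleotides), planted homologous segments derived
#' from donor sequences at an exact target identity, planted verbatim
#' k-mer epitopes, and a seed. The same spec and seed always produce
#' byte-identical output.
#'
#' @param n_records Number of decoy records.
#' @param length_range Integer vector `c(min, max)`: record lengths are
#'   drawn uniformly from this range. The protein default spans the length
#'   range typical of database hits (80-600 residues).
#' @param alphabet `"protein"`, `"dna"` or `"rna"`.
#' @param residue_freqs Optional named frequency vector overriding the
#'   composition model.
#' @param planted_homologs List of `list(donor = seq_record,
#'   target_identity = fraction in (0,1], segment_length = int)` entries;
#'   each plants one mutated donor segment inside a random record.
#' @param planted_epitopes List of `list(kmer = string, record = optional
#'   1-based host record index)` entries; each plants one verbatim k-mer.
#' @param seed Integer seed.
#' @return Object of class `decoy_spec`.
#' @export
decoy_spec <- function(n_records, length_range = c(80L, 600L),
                       alphabet = c("protein", "dna", "rna"),
                       residue_freqs = NULL,
                       planted_homologs = list(),
                       planted_epitopes = list(), seed = 1L) {
  alphabet <- match.arg(alphabet)
  stopifnot(n_records >= 1, length(length_range) == 2L,
            length_range[1] >= 1, length_range[2] >= length_range[1])
  if (is.null(residue_freqs)) residue_freqs <- .default_freqs(alphabet)
  stopifnot(!is.null(names(residue_freqs)), all(residue_freqs > 0))
  residue_freqs <- residue_freqs / sum(residue_freqs)
  for (h in planted_homologs) {
    stopifnot(inherits(h$donor, "seq_record"),
              h$target_identity > 0, h$target_identity <= 1,
              h$segment_length >= 1,
              h$segment_length <= seq_length(h$donor),
              h$segment_length <= length_range[2])
  }
  for (e in planted_epitopes) {
    stopifnot(is.character(e$kmer), nchar(e$kmer) >= 1)
  }
  structure(list(n_records = as.integer(n_records),
                 length_range = as.integer(length_range),
                 alphabet = alphabet, residue_freqs = residue_freqs,
                 planted_homologs = planted_homologs,
                 planted_epitopes = planted_epitopes,
                 seed = as.integer(seed)),
            class = "decoy_spec")
}

# Substitute exactly n_sub positions, each to a different residue drawn
# from the composition model. Uses the current RNG stream.
.mutate_core <- function(segment, target_identity, freqs) {
  chars <- strsplit(segment, "")[[1]]
  L <- length(chars)
  # realized identity must be round(t*L)/L exactly, so the substitution
  # count is the complement of the rounded identity count
  n_sub <- L - round(target_identity * L)
  if (n_sub == 0L) return(segment)
  pos <- sample.int(L, n_sub)
  letters_all <- names(freqs)
  for (p in pos) {
    choices <- setdiff(letters_all, chars[p])
    w <- freqs[choices]
    chars[p] <- sample(choices, 1L, prob = w / sum(w))
  }
  paste(chars, collapse = "")
}

#' Mutate a donor segment to an exact target identity
#'
#' Substitutes exactly `round((1 - target_identity) * L)` positions, chosen
#' without replacement, each to a residue different from the original drawn
#' from the composition model. The realized ungapped identity to the donor
#' is exactly `round(target_identity * L) / L` — no sampling tolerance.
#'
#' @param donor_segment Residue string (length >= 1).
#' @param target_identity Fraction in (0, 1].
#' @param seed Integer seed.
#' @param alphabet Alphabet of the segment (selects the default
#'   composition model).
#' @param residue_freqs Optional named frequency vector.
#' @return Mutated residue string of the same length.
#' @examples
#' mutate_to_identity("EHIANLAGEHIANLAG", 0.75, seed = 1)
#' @export
mutate_to_identity <- function(donor_segment, target_identity, seed,
                               alphabet = c("protein", "dna", "rna"),
                               residue_freqs = NULL) {
  alphabet <- match.arg(alphabet)
  stopifnot(is.character(donor_segment), length(donor_segment) == 1L,
            target_identity > 0, target_identity <= 1)
  if (!nzchar(donor_segment)) {
    stop("cannot mutate an empty segment", call. = FALSE)
  }
  if (is.null(residue_freqs)) residue_freqs <- .default_freqs(alphabet)
  residue_freqs <- residue_freqs / sum(residue_freqs)
  .with_seed(seed, .mutate_core(donor_segment, target_identity, residue_freqs))
}

#' Generate a decoy database from a spec
#'
#' Draws `n_records` i.i.d. sequences from the composition model, embeds
#' each planted homolog (donor segment taken at a seeded random donor
#' offset, mutated to the exact target identity, overwriting a random
#' in-bounds stretch of a random sufficiently long record) and each
#' planted epitope (verbatim overwrite), and returns the records together
#' with a manifest recording every planted item.
#'
#' @param spec A [decoy_spec()].
#' @return List with `records` (list of [seq_record()], ids
#'   `decoy_0001`...) and `manifest` (`data.frame` with `record_id`,
#'   `kind` = `"homolog"`/`"epitope"`, `offset` (0-based), `length`,
#'   `target_identity`, `donor`).
#' @examples
#' db <- make_decoy_db(decoy_spec(3, c(100, 200), seed = 42))
#' vapply(db$records, seq_length, numeric(1))
#' @export
make_decoy_db <- function(spec) {
  stopifnot(inherits(spec, "decoy_spec"))
  .with_seed(spec$seed, {
    lens <- spec$length_range[1] - 1L +
      sample.int(spec$length_range[2] - spec$length_range[1] + 1L,
                 spec$n_records, replace = TRUE)
    seqs <- vapply(lens, .random_residues, character(1),
                   freqs = spec$residue_freqs)
    ids <- sprintf("decoy_%04d", seq_len(spec$n_records))
    manifest <- list()
    for (h in spec$planted_homologs) {
      seg_len <- as.integer(h$segment_length)
      don_off <- sample.int(seq_length(h$donor) - seg_len + 1L, 1L) - 1L
      donor_seg <- substr(h$donor$residues, don_off + 1L, don_off + seg_len)
      mutated <- .mutate_core(donor_seg, h$target_identity,
                              spec$residue_freqs)
      hosts <- which(lens >= seg_len)
      if (length(hosts) == 0L) {
        stop("no decoy record long enough to host a planted ", seg_len,
             "-residue homolog", call. = FALSE)
      }
      rec <- hosts[sample.int(length(hosts), 1L)]
      off <- sample.int(lens[rec] - seg_len + 1L, 1L) - 1L
      substr(seqs[rec], off + 1L, off + seg_len) <- mutated
      manifest[[length(manifest) + 1L]] <- data.frame(
        record_id = ids[rec], kind = "homolog", offset = off,
        length = seg_len, target_identity = h$target_identity,
        donor = h$donor$id)
    }
    for (e in spec$planted_epitopes) {
      k <- nchar(e$kmer)
      rec <- if (!is.null(e$record)) {
        as.integer(e$record)
      } else {
        hosts <- which(lens >= k)
        hosts[sample.int(length(hosts), 1L)]
      }
      if (rec < 1L || rec > spec$n_records) {
        stop("epitope host record index out of range: ", rec, call. = FALSE)
      }
      if (lens[rec] < k) {
        stop("planted epitope '", e$kmer, "' is longer than host record ",
             ids[rec], " (", lens[rec], " residues)", call. = FALSE)
      }
      off <- sample.int(lens[rec] - k + 1L, 1L) - 1L
      substr(seqs[rec], off + 1L, off + k) <- toupper(e$kmer)
      manifest[[length(manifest) + 1L]] <- data.frame(
        record_id = ids[rec], kind = "epitope", offset = off,
        length = k, target_identity = 1, donor = toupper(e$kmer))
    }
    records <- mapply(function(id, s) seq_record(id, s, spec$alphabet),
                      ids, seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
    manifest <- if (length(manifest) > 0L) {
      do.call(rbind, manifest)
    } else {
      data.frame(record_id = character(0), kind = character(0),
                 offset = integer(0), length = integer(0),
                 target_identity = numeric(0), donor = character(0))
    }
    list(records = records, manifest = manifest)
  })
}

#' Composition-preserving shuffle of a nucleotide sequence
#'
#' `"mononucleotide"` mode permutes the bases (base counts preserved
#' exactly). `"dinucleotide"` mode performs an Eulerian-path shuffle
#' (Altschul-Erickson): the shuffled sequence has exactly the original
#' dinucleotide count table, the standard null model for local-alignment
#' significance of nucleotide sequences.
#'
#' @param record Nucleotide [seq_record()].
#' @param mode `"mononucleotide"` or `"dinucleotide"`.
#' @param seed Integer seed.
#' @return Shuffled [seq_record()] (same id with a `_shuf` suffix).
#' @export
shuffle_rna <- function(record, mode = c("mononucleotide", "dinucleotide"),
                        seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(record, "seq_record"),
            record$alphabet %in% c("dna", "rna"))
  chars <- strsplit(record$residues, "")[[1]]
  if (mode == "dinucleotide" && length(chars) < 2L) {
    stop("dinucleotide shuffle needs at least 2 residues", call. = FALSE)
  }
  shuffled <- .with_seed(seed, {
    if (mode == "mononucleotide") {
      sample(chars)
    } else {
      .dinuc_shuffle(chars)
    }
  })
  seq_record(paste0(record$id, "_shuf"), paste(shuffled, collapse = ""),
             record$alphabet, record$description)
}

# Altschul-Erickson Eulerian-path shuffle. Dinucleotide edges form a
# multigraph; a random in-tree toward the terminal vertex guarantees the
# permuted edge lists are traversable as a single Eulerian walk.
.dinuc_shuffle <- function(chars) {
  L <- length(chars)
  verts <- unique(chars)
  if (length(verts) == 1L) return(chars)
  last <- chars[L]
  edges <- split(chars[-1L], factor(chars[-L], levels = verts))
  inner <- setdiff(verts, last)
  repeat {
    pick <- lapply(edges[inner], function(succ) {
      succ[sample.int(length(succ), 1L)]
    })
    reaches_last <- vapply(inner, function(v) {
      seen <- character(0)
      while (v != last) {
        if (v %in% seen || is.null(pick[[v]])) return(FALSE)
        seen <- c(seen, v)
        v <- pick[[v]]
      }
      TRUE
    }, logical(1))
    if (all(reaches_last)) break
  }
  out_edges <- lapply(verts, function(v) {
    succ <- edges[[v]]
    if (v %in% inner) {
      succ <- succ[-match(pick[[v]], succ)]
      c(succ[sample.int(length(succ))], pick[[v]])
    } else {
      succ[sample.int(length(succ))]
    }
  })
  names(out_edges) <- verts
  res <- character(L)
  res[1L] <- chars[1L]
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  v <- chars[1L]
  for (i in 2:L) {
    nxt <- out_edges[[v]][ptr[[v]]]
    ptr[[v]] <- ptr[[v]] + 1L
    res[i] <- nxt
    v <- nxt
  }
  res
}
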