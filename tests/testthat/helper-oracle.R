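# Independent reference implementation of affine-gap local alignment:
# plain quadratic-space dynamic programming with full score matrices,
# written against the documented contract (gap of length L costs
# open + L*extend; best cell = max score, then smallest subject end, then
# smallest query end; traceback prefers diagonal over gap-in-subject over
# gap-in-query). Shares no code with the package's C++ engine.
oracle_sw <- function(q, s, sub, gap_open, gap_extend) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  m <- length(qc)
  n <- length(sc)
  NEG <- -1e9
  go <- gap_open + gap_extend
  ge <- gap_extend
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  subsc <- function(a, b) {
    if (a %in% rownames(sub) && b %in% colnames(sub)) sub[a, b] else -1
  }
  best <- 0; bi <- 0; bj <- 0
  if (m >= 1 && n >= 1) {
    for (i in 2:(m + 1)) {
      for (j in 2:(n + 1)) {
        E[i, j] <- max(H[i, j - 1] - go, E[i, j - 1] - ge)
        F[i, j] <- max(H[i - 1, j] - go, F[i - 1, j] - ge)
        d <- H[i - 1, j - 1] + subsc(qc[i - 1], sc[j - 1])
        H[i, j] <- max(0, d, E[i, j], F[i, j])
        if (H[i, j] > best ||
            (H[i, j] == best && H[i, j] > 0 &&
             (j < bj || (j == bj && i < bi)))) {
          best <- H[i, j]; bi <- i; bj <- j
        }
      }
    }
  }
  columns <- 0L; identities <- 0L
  if (best > 0) {
    i <- bi; j <- bj; state <- "H"
    repeat {
      if (state == "H") {
        if (H[i, j] == 0) break
        d <- H[i - 1, j - 1] + subsc(qc[i - 1], sc[j - 1])
        if (d > 0 && d == H[i, j]) {
          columns <- columns + 1L
          if (qc[i - 1] == sc[j - 1]) identities <- identities + 1L
          i <- i - 1; j <- j - 1
        } else if (F[i, j] == H[i, j]) {
          state <- "F"
        } else {
          state <- "E"
        }
      } else if (state == "F") {
        columns <- columns + 1L
        from_open <- (H[i - 1, j] - go) >= (F[i - 1, j] - ge)
        i <- i - 1
        if (from_open) state <- "H"
      } else {
        columns <- columns + 1L
        from_open <- (H[i, j - 1] - go) >= (E[i, j - 1] - ge)
        j <- j - 1
        if (from_open) state <- "H"
      }
    }
  }
  list(score = as.integer(best), columns = columns, identities = identities)
}

# Naive double-loop exact substring matcher: the oracle for the k-mer scan.
oracle_kmer_matches <- function(query, subject, k) {
  out <- list()
  for (qs in seq_len(nchar(query) - k + 1)) {
    km <- substr(query, qs, qs + k - 1)
    if (grepl("X", km, fixed = TRUE)) next
    for (ss in seq_len(nchar(subject) - k + 1)) {
      if (km == substr(subject, ss, ss + k - 1)) {
        out[[length(out) + 1L]] <- data.frame(kmer = km, qpos = qs - 1L,
                                              spos = ss - 1L)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(kmer = character(0), qpos = integer(0),
                      spos = integer(0)))
  }
  do.call(rbind, out)
}
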