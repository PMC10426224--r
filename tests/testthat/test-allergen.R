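b62 <- scoring_scheme("BLOSUM62")

test_that("window counting is max(L - k + 1, 0)", {
  expect_identical(count_kmer_windows(fx_record("hcas9"), 8), 1416L)
  expect_identical(count_kmer_windows(seq_record("x", "EHIANLAG", "protein"), 8),
                   1L)
  expect_warning(n <- count_kmer_windows(seq_record("x", "EHIANLA", "protein"), 8),
                 "shorter than k")
  expect_identical(n, 0L)
})

test_that("the epitope scan finds the single shared 8-mer in the fixtures", {
  epi <- kmer_epitope_scan(fx_record("hcas9"), list(fx_record("hevb9")), 8)
  expect_identical(nrow(epi), 1L)
  expect_identical(epi$kmer, "EHIANLAG")
  # positions are 0-based starts of the shared epitope in both proteins
  qp <- epi$query_positions[[1]]
  sp <- epi$subject_positions[[1]]
  expect_identical(substr(fx_record("hcas9")$residues, qp + 1, qp + 8),
                   "EHIANLAG")
  expect_identical(substr(fx_record("hevb9")$residues, sp + 1, sp + 8),
                   "EHIANLAG")
})

test_that("self-scan matches every window at its own position", {
  r <- seq_record("self", "MKVLAAGRSTWE", "protein")
  epi <- kmer_epitope_scan(r, list(r), 8)
  expect_identical(sum(lengths(epi$query_positions)),
                   as.integer(count_kmer_windows(r, 8)))
  for (i in seq_len(nrow(epi))) {
    expect_identical(epi$query_positions[[i]], epi$subject_positions[[i]])
  }
})

test_that("the scan agrees with the naive substring oracle", {
  set.seed(31)
  for (i in 1:15) {
    q <- random_protein(sample(20:60, 1), "q")
    s <- random_protein(sample(20:60, 1), "s")
    # implant a shared 6-mer in half the cases so matches actually occur
    if (i %% 2 == 0) {
      substr(q$residues, 5, 10) <- "WWHHWW"
      substr(s$residues, 11, 16) <- "WWHHWW"
    }
    got <- kmer_epitope_scan(q, list(s), 6)
    ref <- oracle_kmer_matches(q$residues, s$residues, 6)
    expect_identical(sort(unique(got$kmer)), sort(unique(ref$kmer)))
    for (r in seq_len(nrow(got))) {
      km <- got$kmer[r]
      expect_identical(got$query_positions[[r]],
                       sort(unique(ref$qpos[ref$kmer == km])))
      expect_identical(got$subject_positions[[r]],
                       sort(unique(ref$spos[ref$kmer == km])))
    }
  }
})

test_that("scan symmetry: shared k-mer sets agree in both directions", {
  set.seed(37)
  a <- random_protein(80, "a")
  b <- random_protein(80, "b")
  substr(a$residues, 10, 17) <- "EHIANLAG"
  substr(b$residues, 40, 47) <- "EHIANLAG"
  ab <- kmer_epitope_scan(a, list(b), 8)
  ba <- kmer_epitope_scan(b, list(a), 8)
  expect_identical(sort(unique(ab$kmer)), sort(unique(ba$kmer)))
})

test_that("k-mers containing X never match; empty database warns", {
  q <- seq_record("q", "AAAXAAAA", "protein")
  expect_identical(nrow(kmer_epitope_scan(q, list(q), 8)), 0L)
  expect_warning(out <- kmer_epitope_scan(q, list(), 8), "empty database")
  expect_identical(nrow(out), 0L)
})

test_that("a query aligned against itself flags every window", {
  q <- random_protein(150, "self")
  set.seed(41)
  wins <- sliding_window_screen(q, list(q), b62)
  expect_identical(nrow(wins), 71L)  # 150 - 80 + 1 windows, one subject
  expect_true(all(wins$flagged))
  expect_true(all(wins$percent_identity == 100))
})

test_that("queries shorter than the window fall back to full length", {
  set.seed(43)
  q <- random_protein(50, "short")
  wins <- sliding_window_screen(q, list(q), b62)
  expect_identical(nrow(wins), 1L)
  expect_identical(wins$window_length, 50L)
  # segment requirement becomes min(80, query length): self-hit still flags
  expect_true(wins$flagged)
})

test_that("raising the identity threshold never grows the flagged set", {
  set.seed(47)
  hc <- fx_record("hcas9")
  donor_seg <- substr(hc$residues, 101, 220)
  db <- make_decoy_db(decoy_spec(
    4, c(150, 300), seed = 9,
    planted_homologs = list(list(donor = hc, target_identity = 0.6,
                                 segment_length = 120))))
  q <- seq_record("q", substr(hc$residues, 1, 300), "protein")
  flagged_at <- function(th) {
    wins <- sliding_window_screen(q, db$records, b62,
                                  screen_rule(identity_threshold = th))
    wins[wins$flagged, c("window_start", "subject_id")]
  }
  f35 <- flagged_at(35); f50 <- flagged_at(50); f90 <- flagged_at(90)
  key <- function(df) paste(df$window_start, df$subject_id)
  expect_true(all(key(f50) %in% key(f35)))
  expect_true(all(key(f90) %in% key(f50)))
})

test_that("full-length screen: self-hit is significant, fixtures are not", {
  hc <- fx_record("hcas9")
  hv <- fx_record("hevb9")
  self_hits <- full_length_allergen_screen(hv, list(hv), b62)
  expect_identical(nrow(self_hits), 1L)
  expect_true(self_hits$significant)
  expect_identical(self_hits$percent_identity, 100)
  expect_identical(self_hits$alignment_length, 445L)
  cross <- full_length_allergen_screen(hc, list(hv), b62)
  expect_false(any(cross$significant))
})

test_that("k = window = query length collapses the window screen to the full-length screen", {
  set.seed(53)
  q <- random_protein(90, "q")
  db <- list(q, random_protein(120, "other"))
  rule_full <- screen_rule(min_segment = 80)
  rule_win <- screen_rule(window = 90, min_segment = 80)
  full <- full_length_allergen_screen(q, db, b62, rule_full)
  wins <- sliding_window_screen(q, db, b62, rule_win)
  # one window only, and flag decisions agree per subject
  expect_true(all(wins$window_start == 0))
  for (sid in wins$subject_id) {
    expect_identical(wins$flagged[wins$subject_id == sid],
                     full$significant[full$subject_id == sid])
  }
})
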