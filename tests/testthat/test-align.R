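b62 <- scoring_scheme("BLOSUM62")
nuc <- scoring_scheme("NUC")

test_that("bundled schemes carry the documented penalties and tables", {
  expect_identical(c(b62$gap_open, b62$gap_extend), c(11L, 2L))
  b50 <- scoring_scheme("BLOSUM50")
  expect_identical(c(b50$gap_open, b50$gap_extend), c(10L, 2L))
  expect_identical(c(nuc$gap_open, nuc$gap_extend), c(10L, 6L))
  expect_identical(unname(nuc$substitution["A", c("A", "C")]), c(5L, -4L))
  # matrices are symmetric and carry sensible diagonal entries
  expect_identical(b62$substitution, t(b62$substitution))
  expect_identical(unname(b62$substitution["W", "W"]), 11L)
  expect_error(scoring_scheme("BLOSUM62", gap_open = 2, gap_extend = 5))
})

test_that("identical sequences self-align over their full length", {
  a <- seq_record("a", "EHIANLAG", "protein")
  aln <- smith_waterman(a, a, b62)
  expect_identical(aln$columns, 8L)
  expect_identical(aln$identities, 8L)
  expect_identical(percent_identity(aln), 100)
  expect_identical(aln$query_interval, c(0L, 8L))
  # property: self-alignment of any sequence spans all residues
  set.seed(5)
  for (i in 1:25) {
    r <- random_protein(sample(1:60, 1))
    s <- smith_waterman(r, r, b62)
    expect_identical(s$identities, seq_length(r))
    expect_identical(s$columns, seq_length(r))
  }
})

test_that("no positive-scoring pair yields the empty alignment", {
  # G vs P scores -2 under BLOSUM62
  g <- seq_record("g", "GGGG", "protein")
  p <- seq_record("p", "PPPP", "protein")
  aln <- smith_waterman(g, p, b62)
  expect_identical(aln$score, 0L)
  expect_identical(aln$columns, 0L)
  expect_error(percent_identity(aln), "empty")
})

test_that("alphabet/scheme mismatches are rejected", {
  prot <- seq_record("p", "ACDEF", "protein")
  dna <- seq_record("d", "ACGT", "dna")
  expect_error(smith_waterman(prot, dna, b62), "incompatible")
  expect_error(smith_waterman(dna, dna, b62), "incompatible")
  expect_error(smith_waterman(prot, prot, nuc), "incompatible")
})

test_that("engine matches the reference DP on random pairs, both alphabets", {
  set.seed(101)
  for (i in 1:120) {
    if (i %% 2 == 0) {
      q <- random_protein(sample(1:30, 1))
      s <- random_protein(sample(1:30, 1))
      sch <- b62
    } else {
      q <- random_dna(sample(1:30, 1))
      s <- random_dna(sample(1:30, 1))
      sch <- nuc
    }
    got <- smith_waterman(q, s, sch)
    ref <- oracle_sw(q$residues, s$residues, sch$substitution,
                     sch$gap_open, sch$gap_extend)
    expect_identical(got$score, ref$score)
    expect_identical(got$columns, ref$columns)
    expect_identical(got$identities, ref$identities)
  }
})

test_that("score is symmetric and monotone under extension", {
  set.seed(202)
  for (i in 1:20) {
    q <- random_protein(sample(5:40, 1))
    s <- random_protein(sample(5:40, 1))
    expect_identical(smith_waterman(q, s, b62)$score,
                     smith_waterman(s, q, b62)$score)
    base <- smith_waterman(q, s, b62)$score
    longer <- seq_record(q$id, paste0(q$residues, "W"), "protein")
    expect_gte(smith_waterman(longer, s, b62)$score, base)
  }
})

test_that("X never counts as an identity and scores via the matrix", {
  q <- seq_record("q", "EHIXNLAG", "protein")
  s <- seq_record("s", "EHIXNLAG", "protein")
  aln <- smith_waterman(q, s, b62)
  expect_identical(aln$identities, 7L)
  # U is outside BLOSUM62: scores -1, never an identity
  qu <- seq_record("qu", "EHIANLAGU", "protein")
  aln2 <- smith_waterman(qu, qu, b62)
  expect_identical(aln2$identities, 8L)
})

test_that("percent identity follows the alignment-length convention", {
  fake <- structure(list(columns = 100L, identities = 40L),
                    class = "local_alignment")
  expect_identical(percent_identity(fake), 40)
  fake$identities <- 33L
  expect_identical(percent_identity(fake), 33)
  fake$columns <- 99L
  expect_identical(percent_identity(fake), 33.3)
})

test_that("E-values follow the Karlin-Altschul closed form", {
  sch <- b62
  params <- ka_params(sch, lambda = 0.267, K = 0.041)
  ctx1 <- evalue_context(100, 100)
  # direct closed-form evaluation, frozen: 0.041 * 1e4 * exp(-10.68)
  expect_equal(evalue(40, params, ctx1), 0.041 * 1e4 * exp(-0.267 * 40),
               tolerance = 1e-12)
  expect_equal(evalue(40, params, ctx1), 9.430154e-03, tolerance = 1e-6)
  # linear in database size
  ctx2 <- evalue_context(100, 200)
  expect_equal(evalue(40, params, ctx2), 2 * evalue(40, params, ctx1))
  # strictly decreasing in S
  es <- evalue(seq(0, 100, by = 5), params, ctx1)
  expect_true(all(diff(es) < 0))
})

test_that("unparameterized schemes fail loudly in the lambda/K lookup", {
  odd <- scoring_scheme("BLOSUM62", gap_open = 20, gap_extend = 1)
  expect_error(ka_params(odd), "supply lambda and K")
  expect_silent(ka_params(odd, lambda = 0.25, K = 0.05))
  expect_error(ka_params(odd, lambda = 0.25), "both lambda and K")
})

test_that("alignments render as query/match/subject text blocks", {
  a <- seq_record("a", "EHIANLAG", "protein")
  lines <- format_alignment(smith_waterman(a, a, b62))
  expect_identical(lines[1], "Q EHIANLAG")
  expect_identical(lines[2], "  ********")
  expect_identical(lines[3], "S EHIANLAG")
})
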