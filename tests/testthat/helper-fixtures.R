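# Fixture loaders and random-sequence generators shared across tests.

fx_record <- local({
  cache <- new.env(parent = emptyenv())
  function(name) {
    if (is.null(cache[[name]])) {
      alphabet <- if (name == "t1_grna") "rna" else "protein"
      cache[[name]] <- read_fasta(fixture_path(name), alphabet)[[1]]
    }
    cache[[name]]
  }
})

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(n, id = "rp") {
  seq_record(id, paste(sample(AA20, n, replace = TRUE), collapse = ""),
             "protein")
}

random_dna <- function(n, id = "rd") {
  seq_record(id, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                       collapse = ""), "dna")
}

# Decoy microRNA database: random-composition 22-mers, each passed through
# the seeded dinucleotide shuffle (composition-preserving randomization).
shuffled_mirna_db <- function(n, seed) {
  base <- make_decoy_db(decoy_spec(n, c(22L, 22L), alphabet = "dna",
                                   seed = seed))$records
  lapply(seq_along(base), function(k) {
    r <- shuffle_rna(base[[k]], "dinucleotide", seed = seed * 1000L + k)
    seq_record(sprintf("mir_%04d", k), r$residues, "dna")
  })
}

dinuc_counts <- function(residues) {
  chars <- strsplit(residues, "")[[1]]
  table(paste0(chars[-length(chars)], chars[-1]))
}
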