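# safescreen

Tiered allergenicity and toxicity sequence screening for
transgene-expressed products, as used in the bioinformatic tier of
environmental risk assessment (ERA) of genetically modified organisms —
for example gene-drive mosquitoes expressing a Cas9 endonuclease, a guide
RNA and a fluorescent marker protein.

Regulatory screening of a novel protein asks a narrow, well-defined
question: does the protein's primary sequence resemble any known allergen
or toxin closely enough to warrant wet-lab follow-up? `safescreen`
implements the standard answer as a reusable, fully deterministic
pipeline:

* **Full-length homology screen** — exact Smith–Waterman/Gotoh local
  alignment with affine gaps (`gap(L) = open + L·extend`) under BLOSUM62
  (11/2) or BLOSUM50 (10/2). A hit is *significant* under the Codex
  Alimentarius cross-reactivity rule: percent identity ≥ 35% over an
  alignment segment of ≥ 80 residues, where
  `pid = 100 · identities / columns` with gap columns in the denominator.
* **Sliding 80-mer window screen** — every stride-1 window of 80 residues
  of the query is aligned to each database entry, to expose local
  structural motifs a full-length alignment can dilute.
* **Exact 8-mer epitope scan** — every contiguous 8-mer of the query is
  matched exactly against the database, approximating shared linear
  IgE-binding epitopes (a 6-mer alternative is exposed but
  false-positive-prone).
* **E-value gating** — candidate hits are gated by the Karlin–Altschul
  expectation `E = K·m·n·e^(−λS)` with published gapped (λ, K) for the
  bundled schemes; protein screens gate at E ≤ 10, the guide-RNA versus
  microRNA screen calls significance at E < 0.01.
* **Decoy databases** — a seeded generator produces synthetic reference
  sets with planted homologous segments at an exact target identity,
  planted verbatim epitopes, and dinucleotide-shuffled RNA decoys
  (Eulerian-path shuffle), so sensitivity and specificity of every stage
  are testable without downloading any external database.

The shipped fixtures are the four sequences at the centre of the screen:
hCas9 (1423 aa), DsRed (226 aa), the latex allergen Hev b 9 (445 aa,
enolase isoform 1, accession CAC00532) and the 96-nt T1 guide RNA.

## Worked example

Screen hCas9 against the latex allergen Hev b 9:

```r
library(safescreen)
hcas9 <- read_fasta(fixture_path("hcas9"), "protein")[[1]]
hevb9 <- read_fasta(fixture_path("hevb9"), "protein")[[1]]

count_kmer_windows(hcas9, 8)
#> [1] 1416

kmer_epitope_scan(hcas9, list(hevb9), 8)[, c("kmer", "subject_id")]
#>       kmer subject_id
#> 1 EHIANLAG      HevB9

full <- full_length_allergen_screen(hcas9, list(hevb9))
full[, c("subject_id", "evalue", "percent_identity",
         "alignment_length", "significant")]
#>   subject_id      evalue percent_identity alignment_length significant
#> 1      HevB9 0.005625535             57.1               21       FALSE

attr(full, "alignments")$HevB9
#> <local_alignment> hCas9[748,769) x HevB9[125,146) score 54, 12/21 identities (0 gaps)
#> Q KAQVSGQGDSLHEHIANLAGS
#>   **     *  * ********
#> S KAGAHVKGIPLYEHIANLAGN
```

Reading: hCas9 contains 1416 sliding 8-mers, exactly one of which —
`EHIANLAG` — also occurs in Hev b 9. The best full-length local alignment
between the two proteins is only 21 columns long (it is essentially the
shared epitope plus flanking residues), so it fails the 35%/80aa
cross-reactivity rule decisively: a shared linear 8-mer without extended
homology. The sliding 80-mer screen flags nothing either
(`sliding_window_screen(hcas9, list(hevb9))` — 1344 windows, 0 flagged).

From the command line:

```sh
Rscript inst/cli/safescreen.R allergen \
  --query inst/extdata/fixtures/hcas9.faa \
  --db inst/extdata/fixtures/hevb9.faa \
  --out-prefix hc
# writes hc_full.tsv, hc_windows.tsv, hc_epitopes.tsv, hc_verdict.json
```

Subcommands: `allergen`, `toxin`, `rna`, `decoys`. Every output starts
with a `#` header recording the package version, the fully resolved
configuration and input checksums.

## Scope

The package screens sequences; it does not make safety claims. Verdicts
enumerate which screening rules fired and what needs manual review.
IgE-binding prediction, 3-D epitope modelling, serum cross-reactivity
testing and database download tooling are out of scope. See
`vignettes/tiered-screening.Rmd` for the model, parameter rationale and
known limitations.
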