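---
title: "Tiered sequence screening for allergenicity and toxicity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tiered sequence screening for allergenicity and toxicity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(safescreen)
```

## The screening problem

Before a transgene-expressed product can be released into the
environment, risk assessment asks whether its primary sequence resembles
any known allergen or toxin closely enough to warrant wet-lab follow-up
(serum IgE testing, pepsin-digestion assays, and so on). The accepted
bioinformatic tier of that assessment is a set of sequence-comparison
rules, each tuned to a different failure mode of the others:

1. a **full-length local alignment** against each database entry, judged
   by the Codex Alimentarius cross-reactivity criterion — at least 35%
   identity over an alignment segment of at least 80 amino acids;
2. a **sliding-window search** with 80-residue windows, which can expose
   a locally conserved domain that a full-length alignment against a
   much longer protein would dilute below threshold;
3. an **exact short-mer scan** (8-mers by default), approximating shared
   linear IgE-binding epitopes that carry no extended homology at all;
4. for expressed RNAs, a **nucleotide local-alignment screen** against
   known microRNAs, significance-gated at E < 0.01, probing potential
   interference with host gene regulation.

The thresholds are not arbitrary. 35% identity is the level at which
protein pairs are generally expected to share three-dimensional
structure, and has been proposed independently for functional grouping
of toxins; 80 amino acids is a conservative estimate of the size of an
autonomous protein domain (optimal domain sizes cluster near 100
residues). The package treats both as defaults of a `screen_rule`, not
constants, but the defaults are the regulatory settings.

`safescreen` implements all four screens over a small set of explicit
types — sequence records, scoring schemes, alignment results, screen
rules, decoy specifications — and ships the four query/subject sequences
of a well-studied gene-drive construct as fixtures: the hCas9
endonuclease (1423 aa), the DsRed marker (226 aa), the latex allergen
Hev b 9 (445 aa) and the 96-nt T1 guide RNA.

## The aligner

Database search engines (BLASTP, TBLASTN, FASTA, COMPASS) are heuristic:
word seeding, banded extension, compositional score adjustment,
effective-length corrections. Their scores depend on engine version and
database composition, which makes them poor foundations for a
reproducible screen. `safescreen` instead computes the **exact**
optimal local alignment by the Smith–Waterman/Gotoh dynamic programme
(affine gaps, `gap(L) = open + L·extend`, the NCBI existence/extension
convention), in C++ for speed, with **no** compositional adjustment and
**no** effective-length correction.

Consequences worth understanding:

* Scores and alignments are deterministic and independently checkable —
  the test suite verifies the engine cell-for-cell against a plain
  quadratic-space reference DP written separately in R, on hundreds of
  random pairs per run.
* E-values differ from what a heuristic engine with compositional
  adjustment would print for the same pair. The screen's *decisions*
  (identity/length rules) are far less sensitive to this than the
  E-values themselves; E here gates candidate reporting, while
  significance rests on identity and alignment length.
* Only the single best local alignment per pair is reported, no
  suboptimal-HSP enumeration — screening reports carry one row per
  database subject.

Determinism requires explicit tie-breaking: among equal-scoring maxima
the cell with the smallest subject end, then smallest query end, wins;
traceback prefers diagonal over gap-in-subject over gap-in-query. These
choices are part of the documented contract and are mirrored by the
reference implementation in the tests.

**Ambiguity handling.** `X` (protein) and any non-ACGT nucleotide score
through the matrix where a row exists, otherwise −1, and never count as
identities — conservative for identity-threshold rules. Stop characters
(`*`) are stripped on input with a warning.

## Scoring schemes and E-values

Three schemes ship as plain-text NCBI-format matrix files:

| scheme   | gap open | gap extend | λ     | K      | used for |
|----------|---------|------------|-------|--------|----------|
| BLOSUM62 | 11      | 2          | 0.297 | 0.082  | full-length and window protein screens |
| BLOSUM50 | 10      | 2          | 0.181 | 0.025  | FASTA-style allergen searches |
| NUC (+5/−4) | 10   | 6          | 0.163 | 0.068  | guide-RNA vs microRNA screen |

E-values use the Karlin–Altschul form `E = K·m·n·e^(−λS)` with `m` the
query length and `n` the total database residue count, no length
adjustment. λ and K are the published gapped values from the NCBI BLAST
statistics tables, with one documented approximation: **BLOSUM50 at gap
10/2** — the historical FASTA/COMPASS setting — is not parameterized in
any published table (NCBI BLAST rejects the combination outright), so
the package ships the nearest published extend-2 parameterization
(gap 12/2: λ = 0.181, K = 0.025). Since λ decreases as gaps get
cheaper, true E-values at 10/2 would be slightly larger than reported;
the candidate gate at E ≤ 10 is therefore marginally narrower than
ideal for that scheme only. Any other (matrix, gap) combination fails
loudly unless the user supplies λ and K explicitly.

## Screen semantics

* **Full-length screen** (`full_length_allergen_screen`, `toxin_screen`):
  one row per subject with E ≤ 10 (default), sorted by E;
  `significant = pid ≥ 35 AND columns ≥ 80`. Identity percentages use
  alignment columns *including gap columns* as the denominator — the
  BLAST "alignment length" convention — so the significance rule and the
  printed percentage share one denominator. The toxin screen applies the
  same rule; there is no separate published numeric criterion for
  toxins, and the structural-homology rationale above is the stated
  basis.
* **Window screen** (`sliding_window_screen`): stride-1 windows of 80
  residues; queries shorter than the window are screened full-length,
  and the segment requirement becomes `min(80, query length)` — the
  regulatory intent for short proteins is full-length comparison. The
  stride is a design choice: "searched by 80 amino acid segments" is
  ambiguous between overlapping and disjoint segments, and stride 1 is
  the conservative reading (it cannot miss a window a coarser stride
  would catch). A window hit is *flagged* when it meets the identity
  rule; all window/subject pairs passing the E gate are reported.
* **Epitope scan** (`kmer_epitope_scan`): exact matching of every
  query k-mer, X-containing k-mers excluded, one row per distinct
  (k-mer, subject) pair carrying every occurrence position. Counting is
  over distinct shared k-mer strings, so "one match" means one shared
  8-mer even if it occurs at several positions. K-mer matches are
  reported unconditionally — no E gate — because a shared epitope is
  reportable precisely when no significant alignment exists. The
  default k = 8; k = 6 is exposed but known to drown in false
  positives.
* **RNA screen** (`rna_screen`): U normalized to T on both sides, both
  strands searched (the reverse complement via Biostrings), best strand
  reported, significance at E < 0.01. Seed-region (positions 2–8)
  complementarity analysis is deliberately not implemented — the screen
  models whole-sequence similarity only.
* **Verdict** (`verdict`): a structured enumeration —
  `{any_significant_alignment, any_flagged_window, epitope_count,
  items_for_manual_review}` — never a safety claim or a risk score.
  Weight-of-evidence assessment is a human activity; the package's job
  is to make the rule outcomes explicit.

## The decoy generator

Real allergen/toxin/microRNA databases are living snapshots; screening
results against them are not reproducible offline, and their contents
cannot validate a screen's *sensitivity* (nothing is known to be
planted). The `decoy_spec`/`make_decoy_db` generator replaces them for
testing:

* background records are i.i.d. draws from a composition model — the
  Robinson–Robinson amino-acid frequencies (the background behind the
  BLOSUM search statistics) or uniform bases; default protein lengths
  Uniform(80, 600), spanning the length range typical of database hits;
* **planted homologs**: a donor segment is taken at a seeded random
  offset, mutated to an exact target identity
  (`mutate_to_identity` substitutes exactly `L − round(t·L)` positions,
  each to a different residue, so realized ungapped identity is
  `round(t·L)/L` with no sampling tolerance), and embedded at a random
  offset in a random record; the manifest records where;
* **planted epitopes**: verbatim k-mer overwrites, manifest-recorded;
* **RNA decoys**: `shuffle_rna` preserves base counts (mononucleotide
  mode) or the exact dinucleotide count table (Eulerian-path /
  Altschul–Erickson shuffle) — the standard null model for nucleotide
  local alignment.

Every generator takes an explicit seed, never touches the caller's
random stream, and the same spec yields byte-identical FASTA.

**What a green decoy test establishes, and what it does not.** Planted
identity is enforced ungapped and exact, but the screens flag *gapped*
alignments, so tests assert flag outcomes (a 45%/100-residue plant is
flagged; a 25%/100 plant is not), not exact recovered percentages. The
decoys model composition, not biology: no database redundancy, no
taxonomic structure, no real header dialects, no homologous families.
A screen that is clean on decoys is calibrated against chance
similarity — it says nothing about content absent from the decoy world.

One decoy design choice deserves its own paragraph. Decoy microRNA sets
are random-composition 22-mers passed through the dinucleotide shuffle
— they are **not** derived from the guide RNA itself. An Eulerian
shuffle of a query's own window shares every dinucleotide with the
query and, a fraction of the time, reassembles long near-exact runs;
such decoys emulate a database compositionally entangled with the
query, which is not the question the screen answers (a public microRNA
database is unrelated to a synthetic guide). The sensitivity direction
is tested separately by planting a true self-substring, which the
screen must and does find.

## Numerical and degenerate-input choices

* Empty alignments (no positive-scoring residue pair) have score 0 and
  are excluded from reports; percent identity of an empty alignment is
  an error, not NaN.
* A query shorter than k yields 0 windows with a warning; an empty
  database yields an empty result (with a warning where the emptiness
  is likely a user error). Emptiness of a *report* is a finding and
  exits 0 from the CLI.
* Reports print E to two significant digits and identities to one
  decimal; underlying values are full precision, and `significant`
  flags are recomputable from the row's own printed columns.
* FASTA identifiers must be unique; lowercase residues are uppercased
  silently (masking has no meaning under exact-identity rules); RNA
  records accept both U and T since guides are routinely published in
  DNA letters; requesting DNA for an RNA-letter input normalizes U→T
  and flags the record.

## Known limitations

* E-values are not comparable to composition-adjusted engine output;
  printed E-values from historical database searches will not be
  reproduced exactly, and the BLOSUM50 10/2 λ/K pair is a documented
  nearest-published approximation.
* The VapC-style toxin fixture shipped with the package is a labelled
  synthetic stand-in (built by mutating a 117-aa window of hCas9
  spanning the HNH/RuvC-III boundary to 43% ungapped identity), because
  the real database record cannot be fetched in an offline build; the
  regression test pins the package's own output for it, not a published
  alignment.
* Database-wide hit counts from live repositories (entry counts below
  an E cutoff, and similar) depend on database snapshots and are out of
  scope; decoy-based properties stand in for them.
* The screens address linear sequence similarity only: no 3-D epitope
  modelling, no IgE-binding prediction, no digestion stability, no
  exposure assessment. A clean screen is one tier of evidence, not a
  safety conclusion.
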