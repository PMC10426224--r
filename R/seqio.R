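# FASTA input/output and sequence-record validation.

.PROTEIN_CHARS <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "B", "Z", "U", "X", "*")
.DNA_CHARS <- strsplit("ACGTRYSWKMBDHVN", "")[[1]]
# RNA accepts both U and T: guide RNA and microRNA sequences are routinely
# published in DNA letters.
.RNA_CHARS <- strsplit("ACGUTRYSWKMBDHVN", "")[[1]]

.alphabet_chars <- function(alphabet) {
  switch(alphabet,
    protein = .PROTEIN_CHARS,
    dna = .DNA_CHARS,
    rna = .RNA_CHARS,
    stop("unknown alphabet: ", alphabet, call. = FALSE)
  )
}

#' Construct a sequence record
#'
#' A `seq_record` holds one FASTA entry: an identifier, a free-text
#' description, an alphabet tag and the residues. Residues are uppercased on
#' construction and validated against the declared alphabet (protein: the 20
#' standard amino acids plus B, Z, U, X and `*`; nucleotide: ACGT/ACGU plus
#' the IUPAC ambiguity codes and N). Stop characters (`*`) are tolerated on
#' input but stripped with a warning, since the identity-based screening
#' rules have no use for them.
#'
#' @param id Short unique identifier (no whitespace).
#' @param residues Residue string; lowercase is uppercased silently.
#' @param alphabet One of `"protein"`, `"dna"`, `"rna"`.
#' @param description Free-text description (may be empty).
#' @return An object of class `seq_record` with fields `id`, `description`,
#'   `alphabet`, `residues`.
#' @examples
#' rec <- seq_record("epi", "EHIANLAG", "protein")
#' seq_length(rec)
#' @export
seq_record <- function(id, residues, alphabet = c("protein", "dna", "rna"),
                       description = "") {
  alphabet <- match.arg(alphabet)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(residues), length(residues) == 1L)
  if (grepl("\\s", id)) stop("record id must not contain whitespace: ", id,
                             call. = FALSE)
  residues <- toupper(gsub("[ \t\r\n]", "", residues))
  if (alphabet == "protein" && grepl("\\*", residues, fixed = FALSE)) {
    warning("record '", id, "': stop characters '*' stripped from sequence",
            call. = FALSE)
    residues <- gsub("*", "", residues, fixed = TRUE)
  }
  if (!nzchar(residues)) {
    stop("record '", id, "' has no residues", call. = FALSE)
  }
  allowed <- .alphabet_chars(alphabet)
  chars <- strsplit(residues, "")[[1]]
  bad <- which(!(chars %in% allowed))
  if (length(bad) > 0L) {
    stop("record '", id, "': illegal character '", chars[bad[1]],
         "' for alphabet '", alphabet, "' at position ", bad[1], call. = FALSE)
  }
  structure(list(id = id, description = description, alphabet = alphabet,
                 residues = residues),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s [%s, %d residues] %s\n", x$id, x$alphabet,
              seq_length(x), x$description))
  invisible(x)
}

#' Sequence length of a record
#'
#' @param record A [seq_record()].
#' @return Number of residues (integer).
#' @export
seq_length <- function(record) {
  stopifnot(inherits(record, "seq_record"))
  nchar(record$residues)
}

#' Read a FASTA file into sequence records
#'
#' Records are returned in file order, uppercased and validated against the
#' requested alphabet. Requesting `alphabet = "dna"` on an RNA-letter input
#' normalizes U to T; the records then carry `attr(, "u_normalized") = TRUE`.
#' Duplicate identifiers and empty sequences are rejected.
#'
#' @param path Path to a FASTA file (plain text or gzip).
#' @param alphabet One of `"protein"`, `"dna"`, `"rna"`.
#' @return List of [seq_record()] objects.
#' @examples
#' faa <- system.file("extdata", "fixtures", "hevb9.faa", package = "safescreen")
#' recs <- read_fasta(faa, "protein")
#' seq_length(recs[[1]])
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna", "rna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("failed to parse FASTA '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  if (length(set) == 0L) stop("no records in FASTA file: ", path, call. = FALSE)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    stop("duplicate record id in '", path, "': ",
         ids[duplicated(ids)][1], call. = FALSE)
  }
  records <- vector("list", length(set))
  for (k in seq_along(set)) {
    res <- toupper(as.character(set[[k]]))
    if (!nzchar(res)) stop("record '", ids[k], "' has no residues",
                           call. = FALSE)
    normalized <- FALSE
    if (alphabet == "dna" && grepl("U", res, fixed = TRUE)) {
      res <- gsub("U", "T", res, fixed = TRUE)
      normalized <- TRUE
    }
    rec <- seq_record(ids[k], res, alphabet, descs[k])
    if (normalized) attr(rec, "u_normalized") <- TRUE
    records[[k]] <- rec
  }
  records
}

#' Write sequence records to a FASTA file
#'
#' Round-trip stable with [read_fasta()]: writing a record list and reading
#' it back yields identical ids, descriptions and residues.
#'
#' @param records Non-empty list of [seq_record()] objects.
#' @param path Output path.
#' @param line_width Positive integer wrap width for sequence lines.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, line_width = 60L) {
  if (length(records) == 0L) {
    stop("refusing to write an empty FASTA file", call. = FALSE)
  }
  stopifnot(all(vapply(records, inherits, logical(1), "seq_record")),
            line_width >= 1L)
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) {
    header <- if (nzchar(rec$description)) {
      paste(rec$id, rec$description)
    } else {
      rec$id
    }
    writeLines(paste0(">", header), con)
    res <- rec$residues
    starts <- seq(1L, nchar(res), by = line_width)
    writeLines(substring(res, starts, pmin(starts + line_width - 1L, nchar(res))), con)
  }
  invisible(path)
}

#' Paths to the bundled query/subject fixtures
#'
#' The four sequences at the centre of the screen — the hCas9 endonuclease
#' (1423 aa), the DsRed marker protein (226 aa), the latex allergen Hev b 9
#' (445 aa, enolase isoform 1, accession CAC00532) and the 96-nt T1 guide
#' RNA — transcribed once into FASTA and shipped with the package.
#'
#' @param name One of `"hcas9"`, `"dsred"`, `"hevb9"`, `"t1_grna"`,
#'   `"vapc_synthetic"`.
#' @return Path to the fixture FASTA file.
#' @export
fixture_path <- function(name = c("hcas9", "dsred", "hevb9", "t1_grna",
                                  "vapc_synthetic")) {
  name <- match.arg(name)
  fn <- switch(name,
    hcas9 = "hcas9.faa", dsred = "dsred.faa", hevb9 = "hevb9.faa",
    t1_grna = "t1_grna.fna", vapc_synthetic = "vapc_synthetic.faa")
  p <- system.file("extdata", "fixtures", fn, package = "safescreen")
  if (!nzchar(p)) stop("fixture not found: ", name, call. = FALSE)
  p
}
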