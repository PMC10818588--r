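#' Coerce input to a validated peptide tibble
#'
#' Peptide sets travel through the package as tibbles with columns `id` and
#' `peptide`. This coercer accepts a character vector of sequences (names, if
#' any, become ids), a data frame with a `peptide` column, or an existing
#' peptide tibble. Sequences are upper-cased and validated against the
#' 20-letter standard alphabet; any other character (X, B, Z, U, gaps, digits)
#' is an error naming the peptide and the offending character, because the
#' matrices define no value for it.
#'
#' @param x Character vector of sequences or a data frame with a `peptide`
#'   column (and optionally `id`).
#' @return A tibble with character columns `id` and `peptide`.
#' @export
#' @examples
#' as_peptide_tbl(c("PQPELPYPQ", "QPQQPFPQQ"))
as_peptide_tbl <- function(x) {
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids) || any(ids == "")) ids <- paste0("pep", seq_along(x))
    out <- tibble(id = as.character(ids), peptide = unname(x))
  } else if (is.data.frame(x)) {
    if (!"peptide" %in% names(x)) {
      abort("expected a `peptide` column in the peptide data frame")
    }
    out <- tibble(
      id = if ("id" %in% names(x)) as.character(x$id)
           else paste0("pep", seq_len(nrow(x))),
      peptide = as.character(x$peptide)
    )
  } else {
    abort("peptides must be a character vector or a data frame")
  }
  if (nrow(out) == 0) abort("peptide set is empty")
  out$peptide <- toupper(out$peptide)
  bad <- !grepl(paste0("^[", paste(AA_ONE, collapse = ""), "]+$"), out$peptide)
  if (any(bad)) {
    i <- which(bad)[1]
    ch <- setdiff(strsplit(out$peptide[i], "")[[1]], AA_ONE)[1]
    abort(sprintf(
      "peptide '%s' (%s) contains non-standard residue '%s'; only the 20 standard one-letter codes are allowed",
      out$id[i], out$peptide[i], ch))
  }
  out
}

#' Read a peptide set from FASTA or line-per-peptide text
#'
#' Both formats yield the same tibble. FASTA records may wrap across lines
#' (concatenated before validation) and headers are kept as ids. The `lines`
#' format is one peptide per line; blank lines and lines starting with `#`
#' are ignored and ids are generated as `pep1`, `pep2`, ...
#'
#' @param path Path to the input file.
#' @param format `"auto"` (default; FASTA if the first non-blank character is
#'   `>`), `"fasta"`, or `"lines"`.
#' @return A validated peptide tibble (see [as_peptide_tbl()]).
#' @export
read_peptides <- function(path, format = c("auto", "fasta", "lines")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readLines(path, warn = FALSE)
  if (format == "auto") {
    first <- raw[nzchar(trimws(raw))][1]
    format <- if (!is.na(first) && startsWith(trimws(first), ">")) "fasta" else "lines"
  }
  if (format == "fasta") {
    ss <- tryCatch(
      Biostrings::readAAStringSet(path),
      error = function(e) abort(sprintf("malformed FASTA in %s: %s",
                                        path, conditionMessage(e))))
    if (length(ss) == 0) abort(sprintf("no FASTA records in %s", path))
    w <- Biostrings::width(ss)
    if (any(w == 0)) {
      abort(sprintf("malformed FASTA in %s: record '%s' has no sequence",
                    path, names(ss)[which(w == 0)[1]]))
    }
    as_peptide_tbl(setNames(as.character(ss), names(ss)))
  } else {
    keep <- nzchar(trimws(raw)) & !grepl("^\\s*#", raw)
    seqs <- trimws(raw[keep])
    if (length(seqs) == 0) abort(sprintf("no peptides in %s", path))
    as_peptide_tbl(seqs)
  }
}

#' Write a peptide set to FASTA or line-per-peptide text
#'
#' @param peps Peptide tibble or character vector (see [as_peptide_tbl()]).
#' @param path Output path.
#' @param format `"fasta"` or `"lines"`.
#' @return `path`, invisibly. Reading the file back reproduces the sequences
#'   exactly (and, for FASTA, the ids).
#' @export
write_peptides <- function(peps, path, format = c("fasta", "lines")) {
  format <- match.arg(format)
  peps <- as_peptide_tbl(peps)
  if (format == "fasta") {
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(setNames(peps$peptide, peps$id)), path)
  } else {
    writeLines(peps$peptide, path)
  }
  invisible(path)
}

#' Generate synthetic peptides from a positional frequency table
#'
#' Draws each position independently from the given per-position residue
#' distribution — the generative model behind a sequence logo. Used as a
#' seeded stand-in for experimentally determined binding-core training sets;
#' it reproduces positional composition but, by construction, none of the
#' between-position correlation real binding cores may carry.
#'
#' @param freqs Numeric matrix, 20 rows (residues, one- or three-letter
#'   rownames in any order) by L position columns; every column must sum to 1
#'   within 1e-9 and contain no negative entries.
#' @param n Number of peptides to draw (>= 1).
#' @param seed Integer seed; identical `(freqs, n, seed)` give identical
#'   output.
#' @return A peptide tibble with ids `syn1`, ..., `syn<n>`.
#' @export
#' @examples
#' f <- matrix(0, 20, 3, dimnames = list(amino_acids()$one, NULL))
#' f["P", ] <- 1
#' generate_fixture_peptides(f, n = 2, seed = 7)
generate_fixture_peptides <- function(freqs, n, seed) {
  if (!is.matrix(freqs) || nrow(freqs) != 20 || is.null(rownames(freqs))) {
    abort("freqs must be a 20-row matrix with residue rownames")
  }
  if (n < 1) abort("n must be >= 1")
  rn <- aa_to_one(rownames(freqs))
  if (anyDuplicated(rn)) abort("duplicate residue rows in freqs")
  freqs <- freqs[match(AA_ONE, rn), , drop = FALSE]
  if (any(freqs < 0)) abort("freqs must be non-negative")
  cs <- colSums(freqs)
  if (any(abs(cs - 1) > 1e-9)) {
    abort(sprintf("freqs columns must sum to 1 (column %d sums to %.12g)",
                  which(abs(cs - 1) > 1e-9)[1], cs[which(abs(cs - 1) > 1e-9)[1]]))
  }
  L <- ncol(freqs)
  seqs <- withr::with_seed(as.integer(seed), {
    cols <- lapply(seq_len(L), function(p) {
      sample(AA_ONE, n, replace = TRUE, prob = freqs[, p])
    })
    do.call(paste0, cols)
  })
  tibble(id = paste0("syn", seq_len(n)), peptide = seqs)
}

# Require all peptides equal length; returns that length.
peptide_length1 <- function(peps) {
  len <- unique(nchar(peps$peptide))
  if (length(len) != 1) {
    abort(sprintf("peptides must all have equal length; found lengths %s",
                  paste(sort(len), collapse = ", ")))
  }
  len
}
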