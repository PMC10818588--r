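# -- constructors -----------------------------------------------------------

new_counts <- function(m, n_peptides) {
  storage.mode(m) <- "integer"
  structure(m, n_peptides = as.integer(n_peptides),
            class = c("peplogo_counts", class(m)))
}

new_qm <- function(values, n_peptides, label = NA_character_,
                   allele = NA_character_, params = NULL) {
  structure(values,
            n_peptides = as.integer(n_peptides),
            label = label, allele = allele, params = params,
            class = c("peplogo_qm", class(values)))
}

# strip class/attrs down to a plain numeric matrix
as_plain_matrix <- function(x) {
  matrix(as.numeric(x), nrow(x), ncol(x), dimnames = dimnames(x))
}

# round half away from zero, the convention used for the printed tables
round_away <- function(x, digits = 3) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# -- counting ---------------------------------------------------------------

#' Count residues at each binding-core position
#'
#' Tallies how often each of the 20 residues occurs at each position across
#' an equal-length peptide set. Duplicate peptides count with multiplicity:
#' the frequencies feeding the logo model are occurrence frequencies, not
#' unique-sequence frequencies.
#'
#' @param peps Peptide tibble or character vector; all sequences must have
#'   the same length.
#' @return A 20 x L integer matrix of class `peplogo_counts` (rows Ala..Val,
#'   columns p1..pL) with attribute `n_peptides`; every column sums to the
#'   number of peptides.
#' @export
#' @examples
#' count_positions(c("PQPELPYPQ", "PQPELPYPA"))
count_positions <- function(peps) {
  peps <- as_peptide_tbl(peps)
  L <- peptide_length1(peps)
  n <- nrow(peps)
  idx <- matrix(match(unlist(strsplit(peps$peptide, "", fixed = TRUE)), AA_ONE),
                nrow = n, ncol = L, byrow = TRUE)
  m <- vapply(seq_len(L), function(p) tabulate(idx[, p], nbins = 20),
              integer(20))
  dimnames(m) <- list(AA_THREE, paste0("p", seq_len(L)))
  new_counts(m, n)
}

# -- normalization ----------------------------------------------------------

#' Normalize a count matrix into a quantitative matrix (logo model)
#'
#' Converts positional counts to frequencies X = count/N and centers each
#' cell on its column mean (1/20 when columns sum to 1), scaled by the range
#' of frequencies:
#' \deqn{X^{norm}_{i,p} = (X_{i,p} - \bar{X}_p) / (X_{max} - X_{min})}
#' where the maximum and minimum are taken over all 20 x L frequency cells
#' of the matrix (the global convention; see the methods vignette for why
#' the per-position alternative is not used). Entries fall in \[-1, 1\] and
#' every column sums to 0.
#'
#' @param cm A `peplogo_counts` matrix from [count_positions()].
#' @param label Optional `"binder"`/`"non-binder"` tag carried as metadata.
#' @param allele Optional allele name carried as metadata.
#' @return A 20 x L numeric matrix of class `peplogo_qm` with attributes
#'   `n_peptides`, `label`, `allele` and `params` (the column means and the
#'   global max/min frequencies used).
#' @export
normalize_counts <- function(cm, label = NA_character_, allele = NA_character_) {
  if (!inherits(cm, "peplogo_counts")) abort("cm must come from count_positions()")
  n <- attr(cm, "n_peptides")
  if (n < 1) abort("count matrix has no peptides")
  f <- as_plain_matrix(cm) / n
  fmax <- max(f)
  fmin <- min(f)
  if (fmax - fmin <= 0) {
    abort("degenerate input: all frequencies are equal, the logo model is undefined")
  }
  col_means <- colMeans(f)
  values <- sweep(f, 2, col_means) / (fmax - fmin)
  new_qm(values, n, label = label, allele = allele,
         params = list(col_means = col_means, global_max = fmax,
                       global_min = fmin))
}

#' Build a logo model from a peptide set
#'
#' Composition of [count_positions()] and [normalize_counts()]: the one-call
#' route from an equal-length peptide set to its quantitative matrix.
#'
#' @inheritParams count_positions
#' @param label `"binder"` or `"non-binder"`.
#' @param allele Free-text allele name (e.g. `"HLA-DQ2.5"`).
#' @return A `peplogo_qm` matrix.
#' @export
#' @examples
#' qm <- build_logo_model(c("PQPELPYPQ", "PQPELPYPQ", "PQPELPYPQ"), "binder")
#' range(qm)
build_logo_model <- function(peps, label = c("binder", "non-binder"),
                             allele = NA_character_) {
  label <- match.arg(label)
  normalize_counts(count_positions(peps), label = label, allele = allele)
}

# -- decoding printed matrices back to counts -------------------------------

#' Recover integer counts from a printed quantitative matrix
#'
#' Inverts the normalization for matrices whose global minimum count is 0
#' (true whenever at least one residue was never seen at some position, as
#' in all packaged reference matrices). Under that assumption
#' `value = (count - N/20) / R` with `R` the global maximum count, so the
#' decoder searches the integer scale `R` in a window around
#' `r0 = round((N/20) / (-min value))`, keeping candidates for which the
#' rounded counts are non-negative and every column sums to `N`, and returns
#' the candidate with the smallest rounding residual.
#'
#' @param qm A `peplogo_qm` or plain 20 x L numeric matrix (typically printed
#'   at 3 decimals).
#' @param n_peptides The number of peptides `N` the matrix was built from.
#' @param window Half-width of the integer search window around `r0`.
#' @return A `peplogo_counts` matrix with attribute `scale_R` (the chosen
#'   global maximum count).
#' @export
decode_counts <- function(qm, n_peptides, window = 3) {
  v <- as_plain_matrix(qm)
  n <- as.integer(n_peptides)
  if (min(v) >= 0) abort("matrix has no negative entries; cannot locate the zero-count level")
  r0 <- round((n / 20) / (-min(v)))
  candidates <- seq(max(1, r0 - window), r0 + window)
  best <- NULL
  best_resid <- Inf
  for (R in candidates) {
    raw <- v * R + n / 20
    cnt <- round(raw)
    if (any(cnt < 0)) next
    if (any(colSums(cnt) != n)) next
    resid <- max(abs(raw - cnt))
    if (resid < best_resid) {
      best <- cnt
      best_resid <- resid
      attr(best, "scale_R") <- R
    }
  }
  if (is.null(best)) {
    abort(sprintf(
      "decode failure: no integer scale R in [%d, %d] yields non-negative counts with all column sums %d; the matrix is inconsistent with the encoding",
      min(candidates), max(candidates), n))
  }
  R <- attr(best, "scale_R")
  dimnames(best) <- dimnames(v) %||% list(AA_THREE, paste0("p", seq_len(ncol(v))))
  out <- new_counts(best, n)
  attr(out, "scale_R") <- R
  out
}

# -- TSV interfaces ---------------------------------------------------------

#' Read and write quantitative-matrix TSV files
#'
#' The on-disk layout mirrors the published tables: a header row
#' `AA p1 ... p9`, 20 rows keyed by three-letter residue code, and metadata
#' (`allele`, `label`, `n_peptides`) in `#`-prefixed comment lines.
#'
#' @param path File path.
#' @return `read_qm()` returns a `peplogo_qm`; `write_qm()` returns `path`
#'   invisibly.
#' @export
read_qm <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readLines(path)
  meta_lines <- grep("^#", raw, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ml), ":\\s*")[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  body <- raw[!grepl("^#", raw) & nzchar(trimws(raw))]
  parts <- strsplit(body, "\t", fixed = TRUE)
  header <- parts[[1]]
  if (header[1] != "AA") abort(sprintf("malformed matrix file %s: expected 'AA' header", path))
  rows <- parts[-1]
  if (length(rows) != 20) {
    abort(sprintf("malformed matrix file %s: expected 20 residue rows, found %d",
                  path, length(rows)))
  }
  res <- vapply(rows, `[`, "", 1)
  vals <- t(vapply(rows, function(p) as.numeric(p[-1]), numeric(length(header) - 1)))
  rownames(vals) <- aa_to_three(res)
  colnames(vals) <- header[-1]
  vals <- vals[AA_THREE, , drop = FALSE]
  new_qm(vals,
         n_peptides = as.integer(meta$n_peptides %||% NA),
         label = meta$label %||% NA_character_,
         allele = meta$allele %||% NA_character_)
}

#' @rdname read_qm
#' @param qm A `peplogo_qm` matrix.
#' @param digits Decimals to print; the default 3 matches the published
#'   layout, `NA` writes full precision.
#' @export
write_qm <- function(qm, path, digits = 3) {
  v <- as_plain_matrix(qm)
  fmt <- if (is.na(digits)) function(x) sprintf("%.15g", x)
         else function(x) sprintf(paste0("%.", digits, "f"), round_away(x, digits))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# allele: %s", attr(qm, "allele") %||% NA),
    sprintf("# label: %s", attr(qm, "label") %||% NA),
    sprintf("# n_peptides: %s", attr(qm, "n_peptides") %||% NA),
    paste(c("AA", colnames(v)), collapse = "\t")), con)
  writeLines(paste(rownames(v),
                   apply(v, 1, function(r) paste(fmt(r), collapse = "\t")),
                   sep = "\t"), con)
  invisible(path)
}

#' Export positional frequencies for logo rendering
#'
#' Writes the frequency table (counts / N) as TSV with residues as rows and
#' positions as columns — the input format logo-drawing tools consume. The
#' package quantifies logos rather than drawing them.
#'
#' @param cm A `peplogo_counts` matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_frequencies <- function(cm, path) {
  if (!inherits(cm, "peplogo_counts")) abort("cm must come from count_positions()")
  f <- as_plain_matrix(cm) / attr(cm, "n_peptides")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("AA", colnames(f)), collapse = "\t"), con)
  writeLines(paste(rownames(f),
                   apply(f, 1, function(r) paste(sprintf("%.15g", r), collapse = "\t")),
                   sep = "\t"), con)
  invisible(path)
}

# -- methods ----------------------------------------------------------------

#' @export
print.peplogo_qm <- function(x, ...) {
  cat(sprintf("<peplogo_qm> %s %s model (N = %s), %d residues x %d positions\n",
              attr(x, "allele") %||% "?", attr(x, "label") %||% "?",
              attr(x, "n_peptides") %||% "?", nrow(x), ncol(x)))
  print(round(as_plain_matrix(x), 3))
  invisible(x)
}

#' @export
print.peplogo_counts <- function(x, ...) {
  cat(sprintf("<peplogo_counts> N = %d peptides, %d residues x %d positions\n",
              attr(x, "n_peptides"), nrow(x), ncol(x)))
  print(as_plain_matrix(x))
  invisible(x)
}

#' Tidy a quantitative or count matrix into long format
#'
#' @param x A `peplogo_qm` or `peplogo_counts`.
#' @param ... Unused.
#' @return A tibble with columns `residue` (three-letter), `position`
#'   (integer, 1-based) and `value` (or `count`).
#' @export
tidy.peplogo_qm <- function(x, ...) {
  m <- as_plain_matrix(x)
  tibble(residue = rep(rownames(m), ncol(m)),
         position = rep(seq_len(ncol(m)), each = nrow(m)),
         value = as.numeric(m))
}

#' @rdname tidy.peplogo_qm
#' @export
tidy.peplogo_counts <- function(x, ...) {
  m <- as_plain_matrix(x)
  tibble(residue = rep(rownames(m), ncol(m)),
         position = rep(seq_len(ncol(m)), each = nrow(m)),
         count = as.integer(m))
}

#' One-row summary of a quantitative matrix
#'
#' @param x A `peplogo_qm`.
#' @param ... Unused.
#' @return A tibble with allele, label, N, dimensions and value range.
#' @export
glance.peplogo_qm <- function(x, ...) {
  tibble(allele = attr(x, "allele"), label = attr(x, "label"),
         n_peptides = attr(x, "n_peptides"),
         n_positions = ncol(x),
         min_value = min(x), max_value = max(x),
         max_abs_colsum = max(abs(colSums(as_plain_matrix(x)))))
}
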