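# -- non-preferred motif ----------------------------------------------------

#' Define a combinatorial non-binder pool by per-position residue sets
#'
#' A non-preferred motif is one set of experimentally disfavored residues per
#' binding-core position. Its Cartesian product defines a pool of sequences
#' that carry a non-preferred residue at *every* position and are therefore
#' taken as non-binders — the construction used to assemble negative training
#' and test sets when no experimentally validated non-binders exist.
#'
#' @param position_sets List of L character vectors of residue codes (one- or
#'   three-letter), one per position; every set must be non-empty.
#' @param allele Free-text allele tag.
#' @return An object of class `peplogo_motif`: a named list of one-letter
#'   residue sets `p1` ... `pL` with an `allele` attribute.
#' @export
#' @examples
#' m <- np_motif(list(c("A", "V"), c("A", "V"), c("A", "V")))
#' pool_size(m)
np_motif <- function(position_sets, allele = NA_character_) {
  if (!is.list(position_sets) || length(position_sets) == 0) {
    abort("position_sets must be a non-empty list of residue vectors")
  }
  sets <- lapply(position_sets, function(s) {
    if (length(s) == 0) abort("every position set must be non-empty")
    s1 <- aa_to_one(s)
    if (anyDuplicated(s1)) abort("duplicate residues within a position set")
    s1
  })
  names(sets) <- paste0("p", seq_along(sets))
  structure(sets, allele = allele, class = "peplogo_motif")
}

#' @export
print.peplogo_motif <- function(x, ...) {
  cat(sprintf("<peplogo_motif> %s, %d positions, pool size %s\n",
              attr(x, "allele") %||% "?", length(x),
              format(pool_size(x), big.mark = ",", scientific = FALSE)))
  for (p in names(x)) cat(sprintf("  %s: %s\n", p, paste(x[[p]], collapse = " ")))
  invisible(x)
}

#' Read and write a non-preferred motif file
#'
#' Plain text, one line per position: `p<i><TAB>comma-separated residue
#' codes`, with optional `# allele: <name>` comment lines.
#'
#' @param path File path.
#' @return `read_motif()` returns a `peplogo_motif`; `write_motif()` returns
#'   `path` invisibly.
#' @export
read_motif <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readLines(path)
  allele <- NA_character_
  al <- grep("^#\\s*allele:", raw, value = TRUE)
  if (length(al)) allele <- trimws(sub("^#\\s*allele:", "", al[1]))
  body <- raw[!grepl("^#", raw) & nzchar(trimws(raw))]
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(vapply(parts, length, 1L) != 2)) {
    abort(sprintf("malformed motif file %s: expected 'p<i><TAB>residues' lines", path))
  }
  pos <- as.integer(sub("^p", "", vapply(parts, `[`, "", 1)))
  if (anyNA(pos) || !identical(sort(pos), seq_along(pos))) {
    abort(sprintf("malformed motif file %s: positions must be p1..p%d", path, length(pos)))
  }
  sets <- lapply(parts[order(pos)], function(p) strsplit(p[2], ",", fixed = TRUE)[[1]])
  np_motif(sets, allele = allele)
}

#' @rdname read_motif
#' @param motif A `peplogo_motif`.
#' @export
write_motif <- function(motif, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# allele: %s", attr(motif, "allele") %||% NA), con)
  writeLines(sprintf("%s\t%s", names(motif),
                     vapply(motif, paste, "", collapse = ",")), con)
  invisible(path)
}

# -- pool arithmetic --------------------------------------------------------

#' Size of the combinatorial pool
#'
#' Exact product of the per-position set cardinalities (exact in double
#' precision for any realistic motif; the packaged pools are ~1e7, far below
#' 2^53).
#'
#' @param motif A `peplogo_motif`.
#' @return The pool size as a (whole) number.
#' @export
pool_size <- function(motif) {
  stopifnot(inherits(motif, "peplogo_motif"))
  prod(lengths(motif))
}

#' Test membership of peptides in the pool
#'
#' A peptide belongs to the pool iff its residue at every position is in that
#' position's non-preferred set.
#'
#' @param motif A `peplogo_motif` with L positions.
#' @param peps Peptide tibble or character vector of length-L sequences.
#' @return Logical vector, one element per peptide.
#' @export
pool_contains <- function(motif, peps) {
  stopifnot(inherits(motif, "peplogo_motif"))
  peps <- as_peptide_tbl(peps)
  L <- length(motif)
  if (any(nchar(peps$peptide) != L)) {
    abort(sprintf("peptide length must equal motif length (%d positions)", L))
  }
  chars <- matrix(unlist(strsplit(peps$peptide, "", fixed = TRUE)),
                 nrow = nrow(peps), ncol = L, byrow = TRUE)
  ok <- rep(TRUE, nrow(peps))
  for (p in seq_len(L)) ok <- ok & chars[, p] %in% motif[[p]]
  ok
}

#' Enumerate every member of a small pool
#'
#' Materializes the full Cartesian product; refused above `max_size` members
#' to avoid accidental ~1e7-sequence allocations.
#'
#' @param motif A `peplogo_motif`.
#' @param max_size Guard limit (default 1e5).
#' @return Character vector of all pool members.
#' @export
enumerate_pool <- function(motif, max_size = 1e5) {
  ps <- pool_size(motif)
  if (ps > max_size) {
    abort(sprintf("pool has %.0f members, above the enumeration limit %.0f", ps, max_size))
  }
  grid <- expand.grid(rev(unclass(motif)), stringsAsFactors = FALSE)
  do.call(paste0, rev(grid))
}

# -- sampling ---------------------------------------------------------------

#' Sample distinct peptides uniformly from the pool
#'
#' Draws each position independently and uniformly from its set, rejecting
#' duplicates and excluded sequences — exact uniform sampling without
#' replacement over the remaining pool, without materializing the ~1e7
#' member sequences. Rejection is cheap because requested sample sizes are
#' far below the pool size in every intended use.
#'
#' @param motif A `peplogo_motif`.
#' @param n Number of distinct peptides to draw.
#' @param seed Integer seed; required, so every draw is reproducible.
#' @param exclude Optional peptides (tibble or character vector) that must
#'   not appear in the sample, matched by exact sequence.
#' @return A peptide tibble with ids `nb1` ... `nb<n>`.
#' @export
#' @examples
#' m <- np_motif(list(c("A", "V"), c("A", "V"), c("A", "V")))
#' sample_pool(m, n = 4, seed = 42)
sample_pool <- function(motif, n, seed, exclude = NULL) {
  stopifnot(inherits(motif, "peplogo_motif"))
  n <- as.integer(n)
  if (n < 1) abort("n must be >= 1")
  ps <- pool_size(motif)
  excl <- character(0)
  if (!is.null(exclude)) {
    excl <- unique(as_peptide_tbl(exclude)$peptide)
    excl <- excl[nchar(excl) == length(motif)]
    excl <- excl[pool_contains(motif, excl)]
  }
  if (n + length(excl) > ps) {
    abort(sprintf(
      "capacity error: requested %d peptides but only %.0f remain in the pool after %d exclusions",
      n, ps - length(excl), length(excl)))
  }
  seqs <- withr::with_seed(as.integer(seed), draw_rejecting(motif, n, excl))
  tibble(id = paste0("nb", seq_len(n)), peptide = seqs)
}

# rejection loop, runs inside an established RNG context
draw_rejecting <- function(motif, n, excl) {
  taken <- character(0)
  forbidden <- excl
  while (length(taken) < n) {
    need <- n - length(taken)
    batch <- ceiling(need * 1.2) + 8
    cols <- lapply(motif, function(s) sample(s, batch, replace = TRUE))
    cand <- do.call(paste0, cols)
    cand <- cand[!duplicated(cand) & !(cand %in% forbidden)]
    keep <- head(cand, need)
    taken <- c(taken, keep)
    forbidden <- c(forbidden, keep)
  }
  taken
}

#' Draw disjoint negative training and test sets
#'
#' Samples `n_train` peptides for model training, then `n_test` peptides
#' from the remaining pool (the test draw excludes the training draw), all
#' from a single seeded RNG stream.
#'
#' @inheritParams sample_pool
#' @param n_train,n_test Sizes of the two disjoint samples.
#' @return A list with peptide tibbles `train` and `test`.
#' @export
split_train_test_negatives <- function(motif, n_train, n_test, seed) {
  ps <- pool_size(motif)
  if (n_train + n_test > ps) {
    abort(sprintf("capacity error: %d + %d draws exceed the pool size %.0f",
                  n_train, n_test, ps))
  }
  res <- withr::with_seed(as.integer(seed), {
    train <- draw_rejecting(motif, as.integer(n_train), character(0))
    test <- draw_rejecting(motif, as.integer(n_test), train)
    list(train = train, test = test)
  })
  list(train = tibble(id = paste0("nb", seq_len(n_train)), peptide = res$train),
       test = tibble(id = paste0("nb", n_train + seq_len(n_test)), peptide = res$test))
}
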