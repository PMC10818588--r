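# Independent oracles: deliberately naive re-implementations (explicit loops,
# no shared code with the package internals) used to cross-check the fast
# paths.

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# normalization oracle: direct evaluation of
# (f - colmean) / (global fmax - global fmin), cell by cell
oracle_normalize <- function(counts, n) {
  f <- counts / n
  fmax <- max(f); fmin <- min(f)
  out <- matrix(NA_real_, nrow(f), ncol(f), dimnames = dimnames(f))
  for (p in seq_len(ncol(f))) {
    cm <- mean(f[, p])
    for (a in seq_len(nrow(f))) out[a, p] <- (f[a, p] - cm) / (fmax - fmin)
  }
  out
}

# per-position accumulation scoring oracle
oracle_score <- function(qm, seq) {
  chars <- strsplit(seq, "")[[1]]
  total <- 0
  for (p in seq_along(chars)) {
    row <- aa_to_three(chars[p])
    total <- total + qm[row, p]
  }
  total
}

# counting oracle over explicit loops
oracle_counts <- function(seqs) {
  L <- nchar(seqs[1])
  m <- matrix(0L, 20, L, dimnames = list(AA1, paste0("p", seq_len(L))))
  for (s in seqs) {
    chars <- strsplit(s, "")[[1]]
    for (p in seq_len(L)) m[chars[p], p] <- m[chars[p], p] + 1L
  }
  m
}

# random count matrix with column sums n (multinomial columns)
random_counts <- function(n, L, seed) {
  withr::with_seed(seed, {
    m <- vapply(seq_len(L),
                function(p) as.integer(stats::rmultinom(1, n, prob = stats::runif(20))),
                integer(20))
    dimnames(m) <- list(aa_to_three(AA1), paste0("p", seq_len(L)))
    m
  })
}

# wrap a plain count matrix as package counts via a peptide reconstruction:
# expand the counts column-by-column into n peptides (order is irrelevant
# for counting)
counts_as_peptides <- function(m, n) {
  L <- ncol(m)
  cols <- lapply(seq_len(L), function(p) rep(aa_to_one(rownames(m)), m[, p]))
  stopifnot(all(lengths(cols) == n))
  do.call(paste0, cols)
}

# exhaustive enumeration of a small Cartesian pool
oracle_enumerate <- function(sets) {
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  sort(do.call(paste0, rev(grid)))
}

tiny_motif <- function() np_motif(list(c("A", "V"), c("A", "V"), c("A", "V")))
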