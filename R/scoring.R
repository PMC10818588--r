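# -- model pair -------------------------------------------------------------

#' Pair a binder and a non-binder quantitative matrix
#'
#' Classification needs both models: a peptide's binding score (BS) is summed
#' over the binder matrix, its non-binding score (NBS) over the non-binder
#' matrix, and the larger one wins (ties go to non-binder).
#'
#' @param binder,nonbinder `peplogo_qm` matrices of identical dimensions.
#' @param allele Allele tag; defaults to the binder matrix's allele.
#' @return An object of class `peplogo_pair`.
#' @export
model_pair <- function(binder, nonbinder, allele = NULL) {
  if (!inherits(binder, "peplogo_qm") || !inherits(nonbinder, "peplogo_qm")) {
    abort("binder and nonbinder must be peplogo_qm matrices")
  }
  if (!identical(dim(binder), dim(nonbinder))) {
    abort("binder and nonbinder matrices must share dimensions")
  }
  allele <- allele %||% attr(binder, "allele")
  a2 <- attr(nonbinder, "allele")
  if (!is.null(allele) && !is.na(allele) && !is.na(a2) && allele != a2) {
    abort(sprintf("allele mismatch between matrices: '%s' vs '%s'", allele, a2))
  }
  structure(list(binder = binder, nonbinder = nonbinder, allele = allele),
            class = "peplogo_pair")
}

#' @export
print.peplogo_pair <- function(x, ...) {
  cat(sprintf("<peplogo_pair> %s: binder QM (N = %s) / non-binder QM (N = %s), %d x %d\n",
              x$allele %||% "?",
              attr(x$binder, "n_peptides") %||% "?",
              attr(x$nonbinder, "n_peptides") %||% "?",
              nrow(x$binder), ncol(x$binder)))
  invisible(x)
}

core_length <- function(pair) ncol(pair$binder)

# residue-index matrix (n x L) for equal-length sequences
index_matrix <- function(seqs, L) {
  matrix(match(unlist(strsplit(seqs, "", fixed = TRUE)), AA_ONE),
         nrow = length(seqs), ncol = L, byrow = TRUE)
}

# sum of matrix cells along each row of an index matrix
sum_scores <- function(qm, idx) {
  L <- ncol(idx)
  m <- as_plain_matrix(qm)
  acc <- numeric(nrow(idx))
  for (p in seq_len(L)) acc <- acc + m[cbind(idx[, p], p)]
  acc
}

# -- scoring ----------------------------------------------------------------

#' Score a single binding core
#'
#' BS and NBS are the sums of the binder- and non-binder-matrix cells for the
#' core's residue at each position. The core is a binder iff BS > NBS;
#' a tie is a non-binder.
#'
#' @param pair A `peplogo_pair`.
#' @param core A single sequence whose length equals the matrix width
#'   (9 for the packaged models).
#' @return One-row tibble: `id`, `peptide`, `offset` (0-based, always 0
#'   here), `core`, `bs`, `nbs`, `predicted`.
#' @export
#' @examples
#' dq25 <- load_packaged_allele("HLA-DQ2.5")
#' score_core(dq25$pair, "PQPELPYPQ")
score_core <- function(pair, core) {
  stopifnot(inherits(pair, "peplogo_pair"))
  peps <- as_peptide_tbl(core)
  if (nrow(peps) != 1) abort("score_core() takes a single core; use score_peptides() for sets")
  L <- core_length(pair)
  if (nchar(peps$peptide) != L) {
    abort(sprintf("core length must be %d, got %d", L, nchar(peps$peptide)))
  }
  idx <- index_matrix(peps$peptide, L)
  bs <- sum_scores(pair$binder, idx)
  nbs <- sum_scores(pair$nonbinder, idx)
  tibble(id = peps$id, peptide = peps$peptide, offset = 0L,
         core = peps$peptide, bs = bs, nbs = nbs,
         predicted = ifelse(bs > nbs, "binder", "non-binder"))
}

#' Score peptides, scanning 9-mer windows for longer sequences
#'
#' Each peptide of length >= L is scored at every L-mer window; the reported
#' window is the one maximizing BS − NBS (ties broken toward the smallest
#' offset), the standard core-scanning convention for class II 9-mer cores:
#' the peptide is a binder if any register of it would be. Peptides shorter
#' than L are an error.
#'
#' @param peps Peptide tibble or character vector (lengths may vary, all
#'   >= L).
#' @param pair A `peplogo_pair`.
#' @param label Optional true class of the whole set (`"binder"`,
#'   `"non-binder"`) or `"unknown"`; passed to [add_confidence()]. Use `NULL`
#'   to skip the confidence columns.
#' @return A tibble with one row per peptide: `id`, `peptide`, `offset`
#'   (0-based), `core` (the best window), `bs`, `nbs`, `predicted`, and, if
#'   `label` is given, `ratio` and `bin`.
#' @export
#' @examples
#' dq25 <- load_packaged_allele("HLA-DQ2.5")
#' score_peptides(c("PQPELPYPQ", "APQPELPYPQ"), dq25$pair)
score_peptides <- function(peps, pair, label = NULL) {
  stopifnot(inherits(pair, "peplogo_pair"))
  peps <- as_peptide_tbl(peps)
  L <- core_length(pair)
  len <- nchar(peps$peptide)
  if (any(len < L)) {
    abort(sprintf("peptide '%s' is shorter than the %d-residue core",
                  peps$id[which(len < L)[1]], L))
  }
  # score by window offset group: all peptides contribute their k-th window
  n <- nrow(peps)
  best_bs <- rep(-Inf, n); best_nbs <- rep(-Inf, n)
  best_off <- rep(NA_integer_, n); best_delta <- rep(-Inf, n)
  for (off in 0:(max(len) - L)) {
    active <- which(len >= L + off)
    if (!length(active)) break
    cores <- substr(peps$peptide[active], off + 1, off + L)
    idx <- index_matrix(cores, L)
    bs <- sum_scores(pair$binder, idx)
    nbs <- sum_scores(pair$nonbinder, idx)
    delta <- bs - nbs
    better <- delta > best_delta[active]          # strict: ties keep earliest
    upd <- active[better]
    best_bs[upd] <- bs[better]; best_nbs[upd] <- nbs[better]
    best_off[upd] <- off; best_delta[upd] <- delta[better]
  }
  out <- tibble(
    id = peps$id, peptide = peps$peptide, offset = best_off,
    core = substr(peps$peptide, best_off + 1, best_off + L),
    bs = best_bs, nbs = best_nbs,
    predicted = ifelse(best_bs > best_nbs, "binder", "non-binder"))
  if (!is.null(label)) out <- add_confidence(out, label)
  out
}

#' Attach confidence ratios and bins to a score table
#'
#' The prediction-confidence ratio is BS/NBS for peptides whose true class is
#' binder and NBS/BS for true non-binders; when the class is unknown, the
#' winning score is divided by the losing one according to the predicted
#' class. Predictions with a ratio strictly between −1 and +1 are flagged
#' `uncertain` — in validation those are where misclassifications
#' concentrate; ratios below −1 or above +1 mark confident calls. A ratio
#' whose denominator is within 1e-12 of zero is `undefined` (not ±Inf, which
#' would have an arbitrary sign).
#'
#' @param scores A score tibble from [score_peptides()] or [score_core()].
#' @param label `"binder"`, `"non-binder"` or `"unknown"`; either a single
#'   value for the whole table or one value per row.
#' @return `scores` with columns `ratio` (numeric, `NA` when undefined) and
#'   `bin` (factor: `below_minus1`, `uncertain`, `above_plus1`, `undefined`).
#' @export
add_confidence <- function(scores, label = "unknown") {
  stopifnot(all(c("bs", "nbs", "predicted") %in% names(scores)))
  label <- rep_len(as.character(label), nrow(scores))
  bad <- setdiff(unique(label), c("binder", "non-binder", "unknown"))
  if (length(bad)) abort(sprintf("unknown label '%s'", bad[1]))
  eff <- ifelse(label == "unknown", scores$predicted, label)
  num <- ifelse(eff == "binder", scores$bs, scores$nbs)
  den <- ifelse(eff == "binder", scores$nbs, scores$bs)
  ratio <- ifelse(abs(den) < 1e-12, NA_real_, num / den)
  bin <- dplyr::case_when(
    is.na(ratio) ~ "undefined",
    ratio < -1 ~ "below_minus1",
    ratio > 1 ~ "above_plus1",
    .default = "uncertain")
  scores$ratio <- ratio
  scores$bin <- factor(bin, levels = c("below_minus1", "uncertain",
                                       "above_plus1", "undefined"))
  scores
}

#' Write a score report TSV
#'
#' @param scores Score tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  df <- as.data.frame(scores)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
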