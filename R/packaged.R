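PACKAGED_ALLELES <- list(
  "HLA-DQ2.5" = list(binder = "qm_dq2.5_binder.tsv",
                     nonbinder = "qm_dq2.5_nonbinder.tsv",
                     motif = "motif_dq2.5.tsv",
                     n_train_binders = 125L, n_train_negatives = 125L,
                     R_binder = 48L, R_nonbinder = 66L),
  "HLA-DQ8.1" = list(binder = "qm_dq8.1_binder.tsv",
                     nonbinder = "qm_dq8.1_nonbinder.tsv",
                     motif = "motif_dq8.1.tsv",
                     n_train_binders = 463L, n_train_negatives = 463L,
                     R_binder = 190L, R_nonbinder = 165L)
)

extdata <- function(file) {
  path <- system.file("extdata", file, package = "peplogo")
  if (path == "") abort(sprintf("packaged data file missing: %s", file))
  path
}

#' Load a packaged reference model
#'
#' Two alleles ship with the package, `"HLA-DQ2.5"` and `"HLA-DQ8.1"` — the
#' class II proteins whose gluten-peptide presentation underlies celiac
#' disease. Each bundles the published binder and non-binder quantitative
#' matrices (built from 125 resp. 463 training nonamers) and the
#' non-preferred residue motif defining its combinatorial non-binder pool.
#'
#' @param allele `"HLA-DQ2.5"` or `"HLA-DQ8.1"` (case-insensitive).
#' @param verify Run the decode-roundtrip integrity check on load (default
#'   TRUE); an inconsistent matrix raises an error naming the first
#'   mismatched cell.
#' @return An object of class `peplogo_allele`: list with `allele`, `pair`
#'   (a `peplogo_pair`), `motif` (a `peplogo_motif`), `n_train_binders`,
#'   `n_train_negatives`.
#' @export
#' @examples
#' dq8 <- load_packaged_allele("HLA-DQ8.1")
#' pool_size(dq8$motif)
load_packaged_allele <- function(allele, verify = TRUE) {
  hit <- match(toupper(allele), toupper(names(PACKAGED_ALLELES)))
  if (is.na(hit)) {
    abort(sprintf("unknown allele '%s'; packaged alleles are: %s",
                  allele, paste(names(PACKAGED_ALLELES), collapse = ", ")))
  }
  name <- names(PACKAGED_ALLELES)[hit]
  info <- PACKAGED_ALLELES[[name]]
  binder <- read_qm(extdata(info$binder))
  nonbinder <- read_qm(extdata(info$nonbinder))
  motif <- read_motif(extdata(info$motif))
  pa <- structure(list(allele = name,
                       pair = model_pair(binder, nonbinder, allele = name),
                       motif = motif,
                       n_train_binders = info$n_train_binders,
                       n_train_negatives = info$n_train_negatives),
                  class = "peplogo_allele")
  if (verify) {
    rep <- verify_packaged(pa)
    # motif_consistency is a documented property of the published data, not a
    # transcription fault (see ?verify_packaged); only corruption checks are fatal
    fatal <- rep[!rep$ok & rep$check != "motif_consistency", ]
    if (nrow(fatal) > 0) {
      bad <- fatal[1, ]
      abort(sprintf("packaged model integrity failure for %s/%s (%s): %s",
                    name, bad$matrix, bad$check, bad$detail))
    }
  }
  pa
}

#' @export
print.peplogo_allele <- function(x, ...) {
  cat(sprintf("<peplogo_allele> %s: %d binder / %d non-binder training nonamers, pool size %s\n",
              x$allele, x$n_train_binders, x$n_train_negatives,
              format(pool_size(x$motif), big.mark = ",", scientific = FALSE)))
  invisible(x)
}

# roundtrip one matrix; returns list(ok, detail, R)
check_roundtrip <- function(qm, n) {
  res <- tryCatch(decode_counts(qm, n), error = function(e) e)
  if (inherits(res, "error")) {
    return(list(ok = FALSE, detail = conditionMessage(res), R = NA_integer_))
  }
  rebuilt <- normalize_counts(res)
  printed <- round_away(as_plain_matrix(qm), 3)
  recomp <- round_away(as_plain_matrix(rebuilt), 3)
  diff <- abs(recomp - printed)
  if (any(diff > 0.001 + 1e-12)) {
    w <- which(diff == max(diff), arr.ind = TRUE)[1, ]
    return(list(ok = FALSE, R = attr(res, "scale_R"),
                detail = sprintf("roundtrip mismatch at %s/p%d: printed %.3f, recomputed %.3f",
                                 rownames(qm)[w[1]], w[2], printed[w[1], w[2]],
                                 recomp[w[1], w[2]])))
  }
  list(ok = TRUE, detail = "", R = attr(res, "scale_R"))
}

#' Verify the integrity of a packaged model
#'
#' Runs, per matrix: the value-range check (all entries in \[-1, 1\]), the
#' rounded column-sum check (|sum| <= 0.011, the worst case for 20 cells
#' printed at 3 decimals), the decode-to-counts roundtrip (recovered integer
#' counts re-normalize to the printed values at 3 decimals, with the expected
#' global maximum count R), the motif-consistency check on the non-binder
#' matrix (every residue outside a position's non-preferred set decodes to
#' count 0), and an md5 checksum of the packaged files against the shipped
#' manifest.
#'
#' For HLA-DQ2.5 the motif-consistency check is expected to report a single
#' violation: Arg at p7 decodes to 18 occurrences although Arg is absent from
#' the published p7 non-preferred list. This is a property of the published
#' data, not a transcription error — an 11-residue p7 set is also the only
#' reading that reconciles the published pool size 24,710,400 with the
#' product of the published set sizes (22,464,000 x 11/10). The packaged
#' motif keeps the published 10-residue list verbatim; see the methods
#' vignette.
#'
#' @param pa A `peplogo_allele` (or allele name).
#' @return A tibble with one row per check: `matrix`, `check`, `ok`,
#'   `detail`.
#' @export
verify_packaged <- function(pa) {
  if (is.character(pa)) pa <- load_packaged_allele(pa, verify = FALSE)
  stopifnot(inherits(pa, "peplogo_allele"))
  info <- PACKAGED_ALLELES[[pa$allele]]
  rows <- list()
  add <- function(matrix, check, ok, detail = "") {
    rows[[length(rows) + 1]] <<- tibble(matrix = matrix, check = check,
                                        ok = ok, detail = detail)
  }
  for (side in c("binder", "nonbinder")) {
    qm <- pa$pair[[side]]
    n <- attr(qm, "n_peptides")
    rng_ok <- min(qm) >= -1 && max(qm) <= 1
    add(side, "range", rng_ok,
        if (!rng_ok) sprintf("entries outside [-1, 1]: range %.3f..%.3f",
                             min(qm), max(qm)) else "")
    cs <- colSums(as_plain_matrix(qm))
    cs_ok <- all(abs(cs) <= 0.011)
    add(side, "column_sums", cs_ok,
        if (!cs_ok) sprintf("column %d sums to %.4f", which.max(abs(cs)),
                            cs[which.max(abs(cs))]) else "")
    rt <- check_roundtrip(qm, n)
    expected_R <- info[[paste0("R_", side)]]
    r_ok <- rt$ok && identical(as.integer(rt$R), expected_R)
    add(side, "decode_roundtrip", r_ok,
        if (!rt$ok) rt$detail
        else if (!r_ok) sprintf("decoded R = %s, expected %d", rt$R, expected_R)
        else sprintf("R = %d", rt$R))
  }
  # non-binder matrix consistent with the motif: zero counts outside the sets
  cnt <- tryCatch(decode_counts(pa$pair$nonbinder,
                                attr(pa$pair$nonbinder, "n_peptides")),
                  error = function(e) NULL)
  if (!is.null(cnt)) {
    viol <- character(0)
    for (p in seq_along(pa$motif)) {
      outside <- setdiff(AA_ONE, pa$motif[[p]])
      out3 <- aa_to_three(outside)
      bad <- out3[cnt[out3, p] > 0]
      if (length(bad)) viol <- c(viol, sprintf("p%d:%s", p, paste(bad, collapse = "/")))
    }
    add("nonbinder", "motif_consistency", length(viol) == 0,
        paste(viol, collapse = "; "))
  } else {
    add("nonbinder", "motif_consistency", FALSE, "decode failed")
  }
  # checksum manifest
  manifest <- utils::read.table(extdata("checksums.tsv"), sep = "\t",
                                col.names = c("file", "md5"),
                                stringsAsFactors = FALSE)
  for (f in c(info$binder, info$nonbinder, info$motif)) {
    expected <- manifest$md5[manifest$file == f]
    actual <- unname(tools::md5sum(extdata(f)))
    add(f, "checksum", length(expected) == 1 && identical(actual, expected),
        if (!identical(actual, expected))
          sprintf("md5 %s != manifest %s", actual,
                  if (length(expected)) expected else "<absent>") else "")
  }
  dplyr::bind_rows(rows)
}
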