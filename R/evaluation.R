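#' Evaluate a model pair on labeled positive and negative peptide sets
#'
#' Scores every peptide (window-scanning the positives if they vary in
#' length), tallies the confusion matrix against the true labels and computes
#' sensitivity TP/(TP+FN), specificity TN/(TN+FP) and accuracy
#' (TP+TN)/total. Confidence ratios follow the validation convention:
#' BS/NBS for true binders, NBS/BS for true non-binders.
#'
#' @param pair A `peplogo_pair`.
#' @param positives,negatives Peptide tibbles or character vectors; both
#'   non-empty.
#' @return An object of class `peplogo_eval` with elements `scores` (the
#'   per-peptide tibble with `truth` and `outcome` in TP/FN/TN/FP),
#'   `confusion` (named integer vector), and `metrics` (named numeric
#'   vector). Metrics with a zero denominator are `NaN`, with a warning.
#' @export
#' @examples
#' dq25 <- load_packaged_allele("HLA-DQ2.5")
#' neg <- sample_pool(dq25$motif, 50, seed = 1)
#' ev <- evaluate_model(dq25$pair, positives = c("PQPELPYPQ"), negatives = neg)
#' glance(ev)
evaluate_model <- function(pair, positives, negatives) {
  pos <- score_peptides(positives, pair, label = "binder")
  neg <- score_peptides(negatives, pair, label = "non-binder")
  pos$truth <- "binder"
  neg$truth <- "non-binder"
  scores <- dplyr::bind_rows(pos, neg)
  scores$outcome <- dplyr::case_when(
    scores$truth == "binder" & scores$predicted == "binder" ~ "TP",
    scores$truth == "binder" ~ "FN",
    scores$truth == "non-binder" & scores$predicted == "non-binder" ~ "TN",
    .default = "FP")
  conf <- c(TP = sum(scores$outcome == "TP"), FP = sum(scores$outcome == "FP"),
            TN = sum(scores$outcome == "TN"), FN = sum(scores$outcome == "FN"))
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warn(sprintf("%s undefined: zero denominator", what))
      return(NaN)
    }
    num / den
  }
  metrics <- c(
    sensitivity = safe_div(conf[["TP"]], conf[["TP"]] + conf[["FN"]], "sensitivity"),
    specificity = safe_div(conf[["TN"]], conf[["TN"]] + conf[["FP"]], "specificity"),
    accuracy = safe_div(conf[["TP"]] + conf[["TN"]], sum(conf), "accuracy"))
  structure(list(scores = scores, confusion = conf, metrics = metrics,
                 allele = pair$allele),
            class = "peplogo_eval")
}

#' @export
print.peplogo_eval <- function(x, ...) {
  cat(sprintf("<peplogo_eval> %s: %d peptides\n", x$allele %||% "?",
              sum(x$confusion)))
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$confusion[["TP"]],
              x$confusion[["FP"]], x$confusion[["TN"]], x$confusion[["FN"]]))
  cat(sprintf("  sensitivity %.3f  specificity %.3f  accuracy %.3f\n",
              x$metrics[["sensitivity"]], x$metrics[["specificity"]],
              x$metrics[["accuracy"]]))
  invisible(x)
}

#' Confidence-bin breakdown of classified peptides
#'
#' For each confusion-matrix cell present in the input, the count and
#' percentage of its peptides falling in each confidence-ratio bin.
#' Percentages within a cell sum to 100 (to rounding).
#'
#' @param scores A score tibble carrying `outcome` and `bin` columns (e.g.
#'   `evaluate_model(...)$scores`).
#' @return A tibble with columns `outcome`, `bin`, `n`, `pct` (percent,
#'   1 decimal).
#' @export
ratio_bin_table <- function(scores) {
  if (!is.data.frame(scores) || nrow(scores) == 0) {
    abort("empty score table: nothing to bin")
  }
  if (!all(c("outcome", "bin") %in% names(scores))) {
    abort("scores must carry 'outcome' and 'bin' columns (see evaluate_model())")
  }
  scores |>
    dplyr::count(.data$outcome, .data$bin, .drop = FALSE, name = "n") |>
    dplyr::group_by(.data$outcome) |>
    dplyr::filter(sum(.data$n) > 0) |>
    dplyr::mutate(pct = round(100 * .data$n / sum(.data$n), 1)) |>
    dplyr::ungroup()
}

#' Tidy an evaluation: confidence-bin breakdown per confusion cell
#'
#' @param x A `peplogo_eval`.
#' @param ... Unused.
#' @return The [ratio_bin_table()] tibble of the evaluation.
#' @export
tidy.peplogo_eval <- function(x, ...) {
  ratio_bin_table(x$scores)
}

#' One-row evaluation summary
#'
#' @param x A `peplogo_eval`.
#' @param ... Unused.
#' @return A tibble with the confusion counts and the three metrics.
#' @export
glance.peplogo_eval <- function(x, ...) {
  tibble(allele = x$allele %||% NA_character_,
         n = sum(x$confusion),
         tp = x$confusion[["TP"]], fp = x$confusion[["FP"]],
         tn = x$confusion[["TN"]], fn = x$confusion[["FN"]],
         sensitivity = x$metrics[["sensitivity"]],
         specificity = x$metrics[["specificity"]],
         accuracy = x$metrics[["accuracy"]])
}

#' Write an evaluation report (counts, metrics, bin breakdown) as text
#'
#' @param ev A `peplogo_eval`.
#' @param path Output path.
#' @param scores_path Optional path for the per-peptide score TSV.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(ev, path, scores_path = NULL) {
  g <- glance(ev)
  lines <- c(
    sprintf("allele\t%s", g$allele),
    sprintf("n\t%d", g$n),
    sprintf("TP\t%d", g$tp), sprintf("FP\t%d", g$fp),
    sprintf("TN\t%d", g$tn), sprintf("FN\t%d", g$fn),
    sprintf("sensitivity\t%.4f", g$sensitivity),
    sprintf("specificity\t%.4f", g$specificity),
    sprintf("accuracy\t%.4f", g$accuracy),
    "", "outcome\tbin\tn\tpct")
  bb <- ratio_bin_table(ev$scores)
  lines <- c(lines, sprintf("%s\t%s\t%d\t%.1f", bb$outcome, bb$bin, bb$n, bb$pct))
  writeLines(lines, path)
  if (!is.null(scores_path)) write_scores(ev$scores, scores_path)
  invisible(path)
}
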