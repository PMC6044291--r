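# Turning score vectors into decisions.
#
# The plain rule takes the argmax of the six softmax outputs. The
# thresholded rule rebalances precision and recall: let x be the argmax
# of the five positive outputs, o_x its score and o_0 the NONE score;
# one of three statistics — a = o_x, b = o_x - o_0, c = o_x / o_0 — is
# compared against a threshold fitted (jointly with the formula choice)
# to maximize micro-F on development data.

#' Argmax decision
#'
#' @param scores Numeric matrix (n x 6) of class scores, or a single
#'   6-vector; column order NONE, CPR:3..CPR:9.
#' @return Integer labels in 0..5; ties go to the lowest index.
#' @export
argmax_decision <- function(scores) {
  if (is.null(dim(scores))) scores <- matrix(scores, 1L)
  max.col(scores, ties.method = "first") - 1L
}

#' Threshold statistic of a score vector
#'
#' With `o_0` the NONE score and `o_x` the best positive score:
#' formula `"A"` returns `o_x`, `"B"` returns `o_x - o_0`, `"C"` returns
#' `o_x / o_0` (`+Inf` when `o_0` is zero).
#'
#' @param scores Matrix (n x 6) or 6-vector.
#' @param formula `"A"`, `"B"` or `"C"`.
#' @return Numeric vector of statistics, one per row.
#' @export
threshold_value <- function(scores, formula = c("A", "B", "C")) {
  formula <- match.arg(formula)
  if (is.null(dim(scores))) scores <- matrix(scores, 1L)
  pos <- scores[, -1L, drop = FALSE]
  o0 <- scores[, 1L]
  ox <- pos[cbind(seq_len(nrow(pos)), max.col(pos, ties.method = "first"))]
  switch(formula,
         A = ox,
         B = ox - o0,
         C = ifelse(o0 == 0, Inf, ox / o0))
}

#' Best positive class of each score vector
#'
#' @param scores Matrix (n x 6) or 6-vector.
#' @return Integer labels in 1..5 (argmax over the five positive columns,
#'   ties to the lowest).
#' @export
best_positive <- function(scores) {
  if (is.null(dim(scores))) scores <- matrix(scores, 1L)
  max.col(scores[, -1L, drop = FALSE], ties.method = "first")
}

#' A fitted threshold rule
#'
#' @param formula `"A"`, `"B"` or `"C"`.
#' @param threshold Real threshold; the candidate positive is accepted
#'   when the statistic is strictly above it.
#' @return A list of class `threshold_rule`.
#' @export
threshold_rule <- function(formula, threshold) {
  structure(list(formula = match.arg(formula, c("A", "B", "C")),
                 threshold = threshold),
            class = "threshold_rule")
}

#' @export
print.threshold_rule <- function(x, ...) {
  cat("<threshold_rule> formula ", x$formula, ", threshold ",
      format(x$threshold), "\n", sep = "")
  invisible(x)
}

#' Thresholded decision
#'
#' Accepts the best positive class when the rule's statistic is strictly
#' above the threshold, otherwise returns NONE (0).
#'
#' @param scores Matrix (n x 6) or 6-vector.
#' @param rule A [threshold_rule()].
#' @return Integer labels in 0..5.
#' @export
thresholded_decision <- function(scores, rule) {
  stopifnot(inherits(rule, "threshold_rule"))
  stat <- threshold_value(scores, rule$formula)
  x <- best_positive(scores)
  ifelse(stat > rule$threshold, x, 0L)
}

# candidate-level micro P/R/F (unrounded) from label vectors
.micro_f_labels <- function(pred, gold) {
  tp <- sum(pred == gold & pred > 0L)
  np <- sum(pred > 0L)
  ng <- sum(gold > 0L)
  p <- if (np == 0L) 0 else 100 * tp / np
  r <- if (ng == 0L) 0 else 100 * tp / ng
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f = f)
}

#' Fit a threshold rule on development data
#'
#' Searches all three formulas over a grid consisting of the midpoints
#' between consecutive distinct statistic values observed on the
#' development set (plus sentinels below the minimum and above the
#' maximum). Since the evaluation metric only changes at observed
#' statistic values this search is exact over the development set. Ties
#' are broken by formula order A, B, C, then by the lower threshold.
#'
#' @param dev_scores Numeric matrix (n x 6) of development score vectors.
#' @param dev_labels Integer gold labels in 0..5 for the same candidates.
#' @param evaluator Function `(pred_labels, gold_labels) -> F` used as
#'   the objective; defaults to candidate-level micro-F.
#' @return A [threshold_rule()] with attribute `dev_f`, the objective at
#'   the optimum.
#' @export
fit_threshold <- function(dev_scores, dev_labels,
                          evaluator = function(pred, gold) .micro_f_labels(pred, gold)[["f"]]) {
  if (is.null(dim(dev_scores))) dev_scores <- matrix(dev_scores, 1L)
  stopifnot(nrow(dev_scores) == length(dev_labels), nrow(dev_scores) >= 1L)
  best <- NULL
  x <- best_positive(dev_scores)
  for (formula in c("A", "B", "C")) {
    stat <- threshold_value(dev_scores, formula)
    fin <- sort(unique(stat[is.finite(stat)]))
    grid <- if (length(fin) == 0L) {
      0
    } else if (length(fin) == 1L) {
      c(fin - 1, fin + 1)
    } else {
      c(fin[1L] - 1, (fin[-1L] + fin[-length(fin)]) / 2, fin[length(fin)] + 1)
    }
    for (thr in grid) {
      pred <- ifelse(stat > thr, x, 0L)
      f <- evaluator(pred, dev_labels)
      if (is.null(best) || f > best$dev_f + 1e-12) {
        best <- list(formula = formula, threshold = thr, dev_f = f)
      }
    }
  }
  rule <- threshold_rule(best$formula, best$threshold)
  attr(rule, "dev_f") <- best$dev_f
  rule
}

#' Save / load a fitted threshold rule as JSON
#'
#' @param rule A [threshold_rule()].
#' @param path JSON file path.
#' @return `path` (save) or a `threshold_rule` (load).
#' @export
save_threshold_rule <- function(rule, path) {
  jsonlite::write_json(list(formula = rule$formula, threshold = rule$threshold),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_threshold_rule
#' @export
load_threshold_rule <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  threshold_rule(x$formula, x$threshold)
}
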