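# Challenge-style scoring: micro-averaged precision/recall/F over unique
# (doc_id, group, chem_id, gene_id) relation tuples, a per-class
# breakdown, and a candidate-level 6x6 confusion matrix.

#' Round half-up
#'
#' The tables this package reproduces use half-up rounding of
#' percentages; R's `round()` rounds half to even, so this helper is
#' used wherever printed values are matched.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Harmonic-mean F score from precision and recall percentages
#'
#' `f = 2pr / (p + r)`, defined as 0 when `p + r = 0`. By default the
#' result is reported to two decimals (half-up), matching printed
#' tables; `digits = NULL` returns the unrounded value.
#'
#' @param p,r Precision and recall in percent.
#' @param digits Decimal places (default 2); `NULL` for unrounded.
#' @return F score in percent.
#' @export
f_score <- function(p, r, digits = 2L) {
  stopifnot(all(p >= 0 & p <= 100), all(r >= 0 & r <= 100))
  f <- ifelse(p + r == 0, 0, 2 * p * r / (p + r))
  if (is.null(digits)) f else round_half_up(f, digits)
}

.tuple_key <- function(rel) {
  paste(rel$doc_id, .normalize_group(rel$group), rel$chem_id, rel$gene_id,
        sep = "\r")
}

#' Micro-averaged precision, recall and F over relation tuples
#'
#' Predictions and gold are deduplicated to unique
#' `(doc_id, group, chem_id, gene_id)` tuples before counting, so the
#' same relation predicted via several mention pairs scores once.
#' Precision is `|pred & gold| / |pred|`, recall `|pred & gold| / |gold|`
#' (0 when a denominator is 0), F their harmonic mean.
#'
#' @param preds,gold Data frames with columns `doc_id`, `group`,
#'   `chem_id`, `gene_id`.
#' @param digits Decimal places for the returned percentages (default 2,
#'   half-up); `NULL` for unrounded.
#' @return Named numeric vector `precision`, `recall`, `f` (percent).
#' @export
micro_prf <- function(preds, gold, digits = 2L) {
  pk <- unique(.tuple_key(preds))
  gk <- unique(.tuple_key(gold))
  tp <- length(intersect(pk, gk))
  p <- if (length(pk) == 0L) 0 else 100 * tp / length(pk)
  r <- if (length(gk) == 0L) 0 else 100 * tp / length(gk)
  f <- f_score(p, r, digits = NULL)
  out <- c(precision = p, recall = r, f = f)
  if (is.null(digits)) out else round_half_up(out, digits)
}

#' Per-class precision, recall and F
#'
#' [micro_prf()] restricted to each evaluated relation group in turn.
#'
#' @inheritParams micro_prf
#' @return Data frame with one row per group: `group`, `precision`,
#'   `recall`, `f`, `n_pred`, `n_gold`, and `no_instances` flagging
#'   groups absent from both sets.
#' @export
per_class_prf <- function(preds, gold, digits = 2L) {
  out <- lapply(cpr_groups(), function(g) {
    ps <- preds[.normalize_group(preds$group) == g, , drop = FALSE]
    gs <- gold[.normalize_group(gold$group) == g, , drop = FALSE]
    m <- micro_prf(ps, gs, digits = digits)
    data.frame(group = g, precision = m[["precision"]], recall = m[["recall"]],
               f = m[["f"]], n_pred = length(unique(.tuple_key(ps))),
               n_gold = length(unique(.tuple_key(gs))),
               no_instances = nrow(ps) == 0L && nrow(gs) == 0L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Candidate-level confusion matrix
#'
#' Counts candidates by (actual, predicted) label pair. Unlike the
#' tuple-level scores, this is computed per candidate, without
#' deduplication.
#'
#' @param gold_labels,pred_labels Integer labels in 0..5.
#' @return A 6x6 integer matrix, rows = actual, columns = predicted,
#'   dimnames NONE, CPR:3..CPR:9.
#' @export
confusion <- function(gold_labels, pred_labels) {
  stopifnot(length(gold_labels) == length(pred_labels),
            all(gold_labels %in% 0:5), all(pred_labels %in% 0:5))
  lev <- c("NONE", cpr_groups())
  tab <- table(factor(label_to_group(gold_labels), levels = lev),
               factor(label_to_group(pred_labels), levels = lev))
  m <- matrix(as.integer(tab), 6L, 6L, dimnames = list(actual = lev, predicted = lev))
  m
}

#' Evaluate a predictions file against a gold file
#'
#' Convenience wrapper reading both files and reporting overall and
#' per-class scores.
#'
#' @param pred_path,gold_path Paths to tab-separated relation files.
#' @return List with `overall` (from [micro_prf()]) and `by_class`
#'   (from [per_class_prf()]).
#' @export
evaluate_files <- function(pred_path, gold_path) {
  preds <- read_gold_relations(pred_path)
  gold <- read_gold_relations(gold_path)
  list(overall = micro_prf(preds, gold), by_class = per_class_prf(preds, gold))
}
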