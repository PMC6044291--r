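test_that("F scores reproduce printed task-table values", {
  # triples that recompute exactly from their printed precision/recall
  exact <- rbind(
    c(56.52, 70.42, 62.71), c(56.10, 67.84, 61.41), # overall dev/test
    c(54.16, 52.28, 53.20), c(63.37, 82.20, 71.57), # per-class
    c(63.75, 80.40, 71.11),
    c(62.97, 57.25, 59.97), c(61.69, 56.96, 59.23), # pre-training levels
    c(71.08, 59.92, 65.02), c(63.05, 66.25, 64.61),
    c(63.33, 65.42, 64.36), c(62.56, 62.52, 62.54)
  )
  for (i in seq_len(nrow(exact))) {
    expect_equal(f_score(exact[i, 1L], exact[i, 2L]), exact[i, 3L])
  }
  # triples whose printed F was computed from unrounded P/R: agreement
  # to within one unit in the last printed digit
  rounded <- rbind(
    c(52.04, 76.72, 62.02), c(41.35, 57.85, 48.22), c(45.05, 50.66, 47.70),
    c(58.22, 68.79, 63.06), c(68.87, 62.58, 65.58), c(59.38, 68.29, 63.53)
  )
  for (i in seq_len(nrow(rounded))) {
    expect_lt(abs(f_score(rounded[i, 1L], rounded[i, 2L]) - rounded[i, 3L]),
              0.015)
  }
})

test_that("F score honours its boundary and symmetry properties", {
  expect_equal(f_score(100, 100), 100)
  expect_equal(f_score(0, 0), 0)
  expect_equal(f_score(0, 80), 0)
  set.seed(8)
  p <- runif(30, 0, 100); r <- runif(30, 0, 100)
  expect_equal(f_score(p, r, digits = NULL), f_score(r, p, digits = NULL))
  expect_true(all(f_score(p, r, digits = NULL) <= pmax(p, r) + 1e-12))
  expect_equal(f_score(p, p, digits = NULL), p)
})

test_that("micro scores count unique relation tuples", {
  tup <- function(doc, grp, c, g) data.frame(
    doc_id = doc, group = grp, chem_id = c, gene_id = g,
    stringsAsFactors = FALSE
  )
  gold <- tup("D1", c("CPR:4", "CPR:4", "CPR:3"), c("T1", "T3", "T5"),
              c("T2", "T4", "T6"))
  expect_equal(unname(micro_prf(gold, gold)), c(100, 100, 100))
  expect_equal(unname(micro_prf(gold[0, ], gold)), c(0, 0, 0))

  preds <- tup("D1", c("CPR:4", "CPR:4", "CPR:9"), c("T1", "T3", "T7"),
               c("T2", "T4", "T8"))
  gold2 <- tup("D1", c("CPR:4", "CPR:4", "CPR:3"), c("T3", "T1", "T9"),
               c("T4", "T2", "T9"))
  m <- micro_prf(preds, gold2) # {a,b,c} vs {b,a,d}: 2 of 3 each
  expect_equal(unname(m), c(66.67, 66.67, 66.67))

  # duplicated predictions of the same tuple count once
  dup <- rbind(preds, preds[1L, ])
  expect_equal(micro_prf(dup, gold2), m)
})

test_that("per-class scores reduce to micro scores per group", {
  tup <- function(grp, c) data.frame(
    doc_id = "D1", group = grp, chem_id = c, gene_id = paste0(c, "g"),
    stringsAsFactors = FALSE
  )
  preds <- tup(c("CPR:4", "CPR:4", "CPR:3"), c("a", "b", "c"))
  gold <- tup(c("CPR:4", "CPR:3", "CPR:3"), c("a", "c", "d"))
  pc <- per_class_prf(preds, gold)
  r4 <- pc[pc$group == "CPR:4", ]
  expect_equal(r4$precision, 50) # 1 of 2 predicted
  expect_equal(r4$recall, 100) # 1 of 1 gold
  expect_equal(r4$f, f_score(50, 100))
  r3 <- pc[pc$group == "CPR:3", ]
  expect_equal(r3$precision, 100)
  expect_equal(r3$recall, 50)
  r5 <- pc[pc$group == "CPR:5", ]
  expect_true(r5$no_instances)
  expect_equal(unname(unlist(r5[, c("precision", "recall", "f")])), c(0, 0, 0))
})

test_that("confusion matrices count candidates and conserve totals", {
  gold <- c(0L, 0L, 2L, 3L, 5L)
  pred <- c(0L, 2L, 2L, 3L, 0L)
  cm <- confusion(gold, pred)
  expect_equal(dim(cm), c(6L, 6L))
  expect_equal(sum(cm), 5L)
  expect_equal(cm["NONE", "CPR:4"], 1L)
  expect_equal(cm["CPR:4", "CPR:4"], 1L)
  expect_equal(cm["CPR:9", "NONE"], 1L)
  expect_equal(unname(rowSums(cm)), unname(as.vector(table(factor(gold, levels = 0:5)))))
  # diagonal sum / total is candidate-level accuracy
  expect_equal(sum(diag(cm)) / sum(cm), mean(gold == pred))
  all_right <- confusion(gold, gold)
  expect_equal(sum(diag(all_right)), 5L)
})

test_that("file-level evaluation wraps the readers and scorers", {
  d <- withr::local_tempdir()
  gold <- data.frame(doc_id = "D1", group = c("CPR:4", "CPR:3"),
                     chem_id = c("T1", "T3"), gene_id = c("T2", "T4"),
                     stringsAsFactors = FALSE)
  write_predictions(gold, file.path(d, "gold.tsv"))
  write_predictions(gold[1L, ], file.path(d, "pred.tsv"))
  res <- evaluate_files(file.path(d, "pred.tsv"), file.path(d, "gold.tsv"))
  expect_equal(unname(res$overall), c(100, 50, f_score(100, 50)))
})
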