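test_that("a mocked full schedule consumes exactly the expected phase-1 lines", {
  sched <- train_schedule(n_epochs = 50L, phase1_epochs = 5L,
                          subepochs_per_epoch = 25L,
                          lines_per_subepoch = 12000L)
  run <- run_training(NULL, NULL, schedule = sched, dry_run = TRUE)
  expect_equal(run$phase1_lines_consumed, 1500000L)

  # the counter scales with each schedule knob
  expect_equal(run_training(NULL, NULL, dry_run = TRUE,
                            schedule = train_schedule(n_epochs = 7L))$phase1_lines_consumed,
               1500000L) # phase 1 runs only in the first five epochs
  expect_equal(run_training(NULL, NULL, dry_run = TRUE,
                            schedule = train_schedule(subepochs_per_epoch = 0L))$phase1_lines_consumed,
               0L)
  expect_equal(run_training(NULL, NULL, dry_run = TRUE,
                            schedule = train_schedule(n_epochs = 3L, subepochs_per_epoch = 10L,
                                                      lines_per_subepoch = 100L))$phase1_lines_consumed,
               3000L)
})

test_that("best-epoch selection is an argmax with earliest-epoch ties", {
  expect_equal(select_best_epoch(c(50, 60, 55)), 2L)
  expect_equal(select_best_epoch(rep(42, 4L)), 1L)
  expect_error(select_best_epoch(numeric(0)), "empty")
  set.seed(55)
  for (i in 1:20) {
    f <- round(runif(sample(3:30, 1L), 0, 100), 1)
    expect_equal(select_best_epoch(f), which(f == max(f))[1L]) # brute-force scan
  }
})

test_that("training runs are reproducible and follow the two-phase schedule", {
  train <- generate_corpus(synth_config(n_abstracts = 8L), seed = 61)
  dev <- generate_corpus(synth_config(n_abstracts = 4L), seed = 62)
  pt <- generate_pretrain_text(60L, seed = 63)
  cfg <- scaled_config(emb_dim = 8L, shared_lstm_units = 8L, l3_units = 4L,
                       pretrain_dense_units = 8L)
  sched <- train_schedule(n_epochs = 3L, phase1_epochs = 2L,
                          subepochs_per_epoch = 1L, lines_per_subepoch = 20L,
                          seed = 64L)
  r1 <- suppressMessages(run_training(train, dev, pretrain_lines = pt,
                                      cfg = cfg, schedule = sched))
  r2 <- suppressMessages(run_training(train, dev, pretrain_lines = pt,
                                      cfg = cfg, schedule = sched))
  expect_identical(r1$log, r2$log)
  expect_identical(r1$dev_scores, r2$dev_scores)

  # phase 1 ran in the first two epochs only
  expect_false(anyNA(r1$log$phase1_loss[1:2]))
  expect_true(is.na(r1$log$phase1_loss[3L]))
  expect_equal(r1$phase1_lines_consumed, 2L * 20L)
  expect_equal(r1$best_epoch, select_best_epoch(r1$log$dev_f))
  expect_equal(dim(r1$dev_scores[[1L]]), c(nrow(r1$dev_meta), 6L))
})

test_that("disabling phase 1 skips pre-training text entirely", {
  train <- generate_corpus(synth_config(n_abstracts = 6L), seed = 65)
  dev <- generate_corpus(synth_config(n_abstracts = 3L), seed = 66)
  cfg <- scaled_config(emb_dim = 8L, shared_lstm_units = 8L, l3_units = 4L,
                       pretrain_dense_units = 8L)
  sched <- train_schedule(n_epochs = 2L, subepochs_per_epoch = 0L, seed = 67L)
  # no pretrain_lines supplied: would fail if phase 1 tried to read them
  r <- run_training(train, dev, pretrain_lines = NULL, cfg = cfg,
                    schedule = sched)
  expect_equal(r$phase1_lines_consumed, 0L)
  expect_true(all(is.na(r$log$phase1_loss)))
  expect_null(r$pre_net)
})

test_that("dev predictions can be regenerated with argmax or a fitted rule", {
  train <- generate_corpus(synth_config(n_abstracts = 6L), seed = 68)
  dev <- generate_corpus(synth_config(n_abstracts = 3L), seed = 69)
  cfg <- scaled_config(emb_dim = 8L, shared_lstm_units = 8L, l3_units = 4L,
                       pretrain_dense_units = 8L)
  r <- run_training(train, dev, cfg = cfg,
                    schedule = train_schedule(n_epochs = 1L,
                                              subepochs_per_epoch = 0L,
                                              seed = 70L))
  preds <- run_dev_predictions(r)
  expect_true(all(c("doc_id", "group", "chem_id", "gene_id") %in% names(preds)))
  rule <- threshold_rule("A", -1) # accept everything
  preds_all <- run_dev_predictions(r, rule = rule)
  expect_equal(nrow(preds_all), nrow(r$dev_meta))
})

test_that("checkpoint directories receive metric logs and test predictions", {
  train <- generate_corpus(synth_config(n_abstracts = 6L), seed = 71)
  dev <- generate_corpus(synth_config(n_abstracts = 3L), seed = 72)
  test <- generate_corpus(synth_config(n_abstracts = 3L), seed = 73)
  d <- withr::local_tempdir()
  cfg <- scaled_config(emb_dim = 8L, shared_lstm_units = 8L, l3_units = 4L,
                       pretrain_dense_units = 8L)
  r <- run_training(train, dev, test = test, cfg = cfg,
                    schedule = train_schedule(n_epochs = 2L,
                                              subepochs_per_epoch = 0L,
                                              seed = 74L),
                    checkpoint_dir = d)
  expect_true(file.exists(file.path(d, "metrics.tsv")))
  expect_true(file.exists(file.path(d, "test_predictions_epoch02.tsv")))
  log <- utils::read.delim(file.path(d, "metrics.tsv"))
  expect_equal(nrow(log), 2L)
  expect_equal(nrow(r$log), 2L)
})
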