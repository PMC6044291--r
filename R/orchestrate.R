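# Two-phase training schedule.
#
# Epochs 1..phase1_epochs each run phase 1 (subepochs_per_epoch
# sub-epochs of unlabelled lines through the pre-training network) and
# then phase 2 (one pass over the labelled training candidates through
# the recognition network, which shares e1/l1/l2 with the pre-training
# network). Later epochs run phase 2 only. After every epoch the
# development candidates are scored, micro-P/R/F is logged, and test
# predictions (if a test corpus is given) are produced; the epoch with
# the best development F is selected afterwards.

#' Training schedule
#'
#' @param n_epochs Total epochs (default 50).
#' @param phase1_epochs Number of leading epochs that include phase 1
#'   (default 5).
#' @param subepochs_per_epoch Sub-epochs of unlabelled text per phase-1
#'   epoch, 0..25 (default 25; 0 disables pre-training entirely).
#' @param lines_per_subepoch Unlabelled lines per sub-epoch
#'   (default 12000).
#' @param batch_size Examples per batch in both phases (default 32).
#' @param seed Integer seed driving all randomness of the run.
#' @return A list of class `train_schedule`.
#' @export
train_schedule <- function(n_epochs = 50L, phase1_epochs = 5L,
                           subepochs_per_epoch = 25L,
                           lines_per_subepoch = 12000L,
                           batch_size = 32L, seed = 1L) {
  stopifnot(n_epochs >= 1L, phase1_epochs >= 0L, subepochs_per_epoch >= 0L,
            lines_per_subepoch >= 1L, batch_size >= 1L)
  structure(
    list(n_epochs = as.integer(n_epochs),
         phase1_epochs = as.integer(phase1_epochs),
         subepochs_per_epoch = as.integer(subepochs_per_epoch),
         lines_per_subepoch = as.integer(lines_per_subepoch),
         batch_size = as.integer(batch_size), seed = as.integer(seed)),
    class = "train_schedule"
  )
}

# decisions -> unique predicted relation tuples for tuple-level scoring
.decisions_to_preds <- function(meta, labels) {
  keep <- labels > 0L
  data.frame(doc_id = meta$doc_id[keep],
             group = label_to_group(labels[keep]),
             chem_id = meta$chem_id[keep],
             gene_id = meta$gene_id[keep],
             stringsAsFactors = FALSE)
}

.instance_meta <- function(instances) {
  data.frame(
    doc_id = vapply(instances, `[[`, "", "doc_id"),
    chem_id = vapply(instances, `[[`, "", "chem_id"),
    gene_id = vapply(instances, `[[`, "", "gene_id"),
    label = vapply(instances, function(x) as.integer(x$label), 1L),
    stringsAsFactors = FALSE
  )
}

#' Run the two-phase training schedule
#'
#' Builds the vocabulary from the training abstracts (min-count rule),
#' assembles the embedding matrix from an optional GloVe table,
#' constructs candidate sets, and trains. All randomness (initialization,
#' substitution, dropout, batch order) flows from `schedule$seed`, so
#' identical inputs give identical runs.
#'
#' @param train,dev Corpora: lists with `abstracts`, `entities`,
#'   `relations` data frames (e.g. a `chemprot_corpus`).
#' @param test Optional test corpus (`relations` may be absent).
#' @param pretrain_lines Character vector, file path or [line_source()]
#'   of unlabelled text; required when `schedule$subepochs_per_epoch > 0`.
#' @param cfg A [model_config()].
#' @param schedule A [train_schedule()].
#' @param glove Optional `glove_table` for embedding initialization.
#' @param max_distance,context Candidate-window settings (defaults 60, 5).
#' @param dry_run Only count phase-1 lines and epochs; no example
#'   building, no training, no evaluation.
#' @param checkpoint_dir Optional directory; when given, per-epoch
#'   development metrics are appended to `metrics.tsv` and per-epoch
#'   test predictions are written as `test_predictions_epoch<e>.tsv`.
#' @param verbose Print per-epoch progress.
#' @return A list of class `chemrel_run`: `log` (per-epoch data frame
#'   with phase losses and dev precision/recall/F), `dev_scores` (list of
#'   per-epoch score matrices), `dev_meta` (candidate metadata),
#'   `test_scores`/`test_meta` (when `test` given), `best_epoch`,
#'   `vocab`, `cfg`, `schedule`, the trained networks, and
#'   `phase1_lines_consumed`.
#' @export
run_training <- function(train, dev, test = NULL, pretrain_lines = NULL,
                         cfg = model_config(), schedule = train_schedule(),
                         glove = NULL, max_distance = 60L, context = 5L,
                         dry_run = FALSE, checkpoint_dir = NULL,
                         verbose = FALSE) {
  set.seed(schedule$seed)
  use_phase1 <- schedule$subepochs_per_epoch > 0L
  lines_consumed <- 0L

  if (dry_run) {
    for (e in seq_len(schedule$n_epochs)) {
      if (use_phase1 && e <= schedule$phase1_epochs) {
        lines_consumed <- lines_consumed +
          schedule$subepochs_per_epoch * schedule$lines_per_subepoch
      }
    }
    return(structure(list(phase1_lines_consumed = lines_consumed,
                          log = NULL, dry_run = TRUE),
                     class = "chemrel_run"))
  }

  # vocabulary from the training abstracts only
  train_tokens <- lapply(seq_len(nrow(train$abstracts)), function(i) {
    tokenize_with_spans(document_text(train$abstracts$title[i],
                                      train$abstracts$body[i]))$surface
  })
  vocab <- build_vocab(train_tokens)
  emb <- build_embedding_matrix(vocab, glove, dim = cfg$emb_dim)

  train_inst <- build_candidate_set(train$abstracts, train$entities,
                                    train$relations, vocab,
                                    max_distance = max_distance,
                                    context = context)
  dev_inst <- build_candidate_set(dev$abstracts, dev$entities,
                                  dev$relations, vocab,
                                  max_distance = max_distance,
                                  context = context)
  if (length(train_inst) == 0L) stop("no training candidates")
  test_inst <- if (!is.null(test)) {
    build_candidate_set(test$abstracts, test$entities, test$relations,
                        vocab, max_distance = max_distance, context = context)
  }

  shared <- build_shared_layers(cfg, vocab$size, emb)
  pre_net <- if (use_phase1) build_pretraining_network(cfg, shared)
  rec_net <- build_recognition_network(cfg, shared)

  src <- if (use_phase1) {
    if (is.null(pretrain_lines)) {
      stop("pretrain_lines required when subepochs_per_epoch > 0")
    }
    if (inherits(pretrain_lines, "line_source")) pretrain_lines
    else line_source(pretrain_lines)
  }

  pad <- vocab$reserved[["PAD"]]
  train_batches <- batch_candidates(train_inst, schedule$batch_size, pad)
  dev_batches <- batch_candidates(dev_inst, schedule$batch_size, pad)
  test_batches <- if (!is.null(test_inst)) {
    batch_candidates(test_inst, schedule$batch_size, pad)
  }
  dev_meta <- .instance_meta(dev_inst)

  log <- data.frame(epoch = integer(0), phase1_loss = numeric(0),
                    phase2_loss = numeric(0), dev_precision = numeric(0),
                    dev_recall = numeric(0), dev_f = numeric(0))
  dev_scores <- vector("list", schedule$n_epochs)
  test_scores <- if (!is.null(test_inst)) vector("list", schedule$n_epochs)
  if (!is.null(checkpoint_dir)) {
    dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
  }

  for (e in seq_len(schedule$n_epochs)) {
    p1_loss <- NA_real_
    if (use_phase1 && e <= schedule$phase1_epochs) {
      losses <- numeric(0)
      for (s in seq_len(schedule$subepochs_per_epoch)) {
        sub <- sample_subepoch(src, schedule$lines_per_subepoch)
        lines_consumed <- lines_consumed + schedule$lines_per_subepoch
        exs <- make_subepoch_examples(sub, vocab)
        batches <- batch_by_length(exs, schedule$batch_size, pad)
        for (b in sample(batches)) losses <- c(losses, train_step(pre_net, b))
      }
      p1_loss <- mean(losses)
    }
    p2_losses <- vapply(sample(train_batches),
                        function(b) as.numeric(train_step(rec_net, b)), 1)
    scores <- predict_scores(rec_net, dev_batches)
    dev_scores[[e]] <- scores
    preds <- .decisions_to_preds(dev_meta, argmax_decision(scores))
    prf <- micro_prf(preds, dev$relations, digits = NULL)
    log <- rbind(log, data.frame(epoch = e, phase1_loss = p1_loss,
                                 phase2_loss = mean(p2_losses),
                                 dev_precision = prf[["precision"]],
                                 dev_recall = prf[["recall"]],
                                 dev_f = prf[["f"]]))
    if (!is.null(test_inst)) {
      test_scores[[e]] <- predict_scores(rec_net, test_batches)
    }
    if (!is.null(checkpoint_dir)) {
      utils::write.table(log, file.path(checkpoint_dir, "metrics.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      if (!is.null(test_inst)) {
        tp <- .decisions_to_preds(.instance_meta(test_inst),
                                  argmax_decision(test_scores[[e]]))
        write_predictions(tp, file.path(checkpoint_dir,
                                        sprintf("test_predictions_epoch%02d.tsv", e)))
      }
    }
    if (verbose) {
      message(sprintf("epoch %d: phase1 %.4f phase2 %.4f dev F %.2f",
                      e, p1_loss, mean(p2_losses), prf[["f"]]))
    }
  }

  structure(
    list(log = log, dev_scores = dev_scores, dev_meta = dev_meta,
         test_scores = test_scores,
         test_meta = if (!is.null(test_inst)) .instance_meta(test_inst),
         best_epoch = select_best_epoch(log$dev_f),
         vocab = vocab, cfg = cfg, schedule = schedule,
         pre_net = pre_net, rec_net = rec_net,
         phase1_lines_consumed = lines_consumed, dry_run = FALSE),
    class = "chemrel_run"
  )
}

#' @export
print.chemrel_run <- function(x, ...) {
  if (isTRUE(x$dry_run)) {
    cat("<chemrel_run> dry run, ", x$phase1_lines_consumed,
        " phase-1 lines counted\n", sep = "")
  } else {
    cat("<chemrel_run> ", nrow(x$log), " epochs, best epoch ", x$best_epoch,
        " (dev F ", sprintf("%.2f", x$log$dev_f[x$best_epoch]), ")\n", sep = "")
  }
  invisible(x)
}

#' Select the best epoch from a development metric log
#'
#' @param dev_f Numeric vector of per-epoch development F scores.
#' @return 1-based index of the maximum; ties go to the earliest epoch.
#' @export
select_best_epoch <- function(dev_f) {
  if (length(dev_f) == 0L) stop("empty development metric log")
  which(dev_f == max(dev_f))[1L]
}

#' Development predictions of a run at a given epoch
#'
#' Applies either the plain argmax decision or a fitted threshold rule
#' to the stored development scores of one epoch and returns relation
#' tuples ready for [micro_prf()].
#'
#' @param run A `chemrel_run`.
#' @param epoch Epoch number (default: the run's best epoch).
#' @param rule Optional [threshold_rule()]; `NULL` for argmax.
#' @return Data frame of predicted relation tuples.
#' @export
run_dev_predictions <- function(run, epoch = run$best_epoch, rule = NULL) {
  scores <- run$dev_scores[[epoch]]
  labels <- if (is.null(rule)) argmax_decision(scores)
  else thresholded_decision(scores, rule)
  .decisions_to_preds(run$dev_meta, labels)
}
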