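# Shared fixtures: a tiny hand-built corpus, file writers, and a tiny
# network configuration used across test files.

# one-document corpus with known offsets:
# title: "Aspirin study" (chars 0..12), tab at 13, body from 14
fixture_corpus <- function() {
  title <- "Aspirin study"
  body <- "Aspirin inhibits COX-2 in cells."
  abstracts <- data.frame(doc_id = "D1", title = title, body = body,
                          stringsAsFactors = FALSE)
  # body offsets: Aspirin 14-21, inhibits 22-30, COX-2 31-36
  entities <- data.frame(
    doc_id = "D1",
    entity_id = c("T1", "T2"),
    kind = c("CHEMICAL", "GENE"),
    char_start = c(14L, 31L),
    char_end = c(21L, 36L),
    surface = c("Aspirin", "COX-2"),
    stringsAsFactors = FALSE
  )
  relations <- data.frame(doc_id = "D1", group = "CPR:4",
                          chem_id = "T1", gene_id = "T2",
                          stringsAsFactors = FALSE)
  list(abstracts = abstracts, entities = entities, relations = relations)
}

write_corpus_files <- function(corpus, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  write_chemprot_corpus(corpus, dir)
}

tiny_cfg <- function(...) {
  defaults <- list(emb_dim = 4L, shared_lstm_units = 3L, i4_conv_filters = 2L,
                   i5_conv_filters = 2L, l3_units = 2L,
                   pretrain_dense_units = 3L, dropout = 0,
                   recurrent_dropout = 0)
  do.call(model_config, utils::modifyList(defaults, list(...)))
}

random_pretrain_batch <- function(V = 12L, B = 2L, Tt = 5L) {
  list(
    i1 = matrix(sample(0:(V - 1L), B * Tt, TRUE), B, Tt),
    i2 = matrix(sample(0:(V - 1L), B * Tt, TRUE), B, Tt),
    i3 = matrix(sample(0:(V - 1L), B * Tt, TRUE), B, Tt),
    y_left = matrix(stats::rbinom(B * Tt, 1L, 0.5), B, Tt),
    y_right = matrix(stats::rbinom(B * Tt, 1L, 0.5), B, Tt),
    loss_mask = matrix(rep(c(0L, rep(1L, Tt - 2L), 0L), each = B), B, Tt)
  )
}

random_recognition_batch <- function(V = 12L, B = 2L, Tt = 5L) {
  list(
    token_ids = matrix(sample(0:(V - 1L), B * Tt, TRUE), B, Tt),
    i4 = array(stats::rbinom(B * Tt * 10L, 1L, 0.3), c(B, Tt, 10L)),
    i5 = array(stats::rbinom(B * Tt * 2L, 1L, 0.3), c(B, Tt, 2L)),
    pos_mask = matrix(1L, B, Tt),
    labels = sample(0:5, B, TRUE),
    idx = seq_len(B)
  )
}

# random softmax-like score matrix (rows on the simplex)
random_scores <- function(n) {
  m <- matrix(stats::rexp(n * 6L), n, 6L)
  m / rowSums(m)
}
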