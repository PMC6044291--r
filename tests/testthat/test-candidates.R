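# candidate enumeration, masking, feature construction and labelling

# document with single-token entities at chosen token positions
doc_with_entities <- function(n_tokens, chem_at, gene_at) {
  words <- sprintf("w%03d", seq_len(n_tokens))
  text <- paste(words, collapse = " ")
  tok <- tokenize_with_spans(text)
  mk <- function(pos, kind, id) data.frame(
    doc_id = "D1", entity_id = id, kind = kind,
    char_start = tok$char_start[pos], char_end = tok$char_end[pos],
    surface = tok$surface[pos], stringsAsFactors = FALSE
  )
  ents <- rbind(
    do.call(rbind, lapply(seq_along(chem_at), function(i)
      mk(chem_at[i], "CHEMICAL", paste0("C", i)))),
    do.call(rbind, lapply(seq_along(gene_at), function(i)
      mk(gene_at[i], "GENE", paste0("G", i))))
  )
  list(tokens = tok, entities = ents)
}

test_that("pair enumeration applies the 60-token window rule", {
  d <- doc_with_entities(80, chem_at = 1, gene_at = 71)
  expect_equal(nrow(enumerate_pairs(d$tokens, d$entities)), 0L) # distance 70

  d2 <- doc_with_entities(80, chem_at = 1, gene_at = 61)
  p2 <- enumerate_pairs(d2$tokens, d2$entities)
  expect_equal(nrow(p2), 1L) # distance 60, inclusive bound
  expect_equal(p2$distance, 60L)

  d3 <- doc_with_entities(20, chem_at = c(3, 7), gene_at = c(5, 10, 12))
  expect_equal(nrow(enumerate_pairs(d3$tokens, d3$entities)), 6L) # 2 x 3
})

test_that("multi-token entities measure distance from first to last token", {
  # chemical spanning tokens 4-5, gene at 11 -> distance 11 - 4 = 7
  words <- sprintf("w%03d", 1:20)
  text <- paste(words, collapse = " ")
  tok <- tokenize_with_spans(text)
  ents <- data.frame(
    doc_id = "D1", entity_id = c("C1", "G1"), kind = c("CHEMICAL", "GENE"),
    char_start = c(tok$char_start[4], tok$char_start[11]),
    char_end = c(tok$char_end[5], tok$char_end[11]),
    surface = c(paste(words[4:5], collapse = " "), words[11]),
    stringsAsFactors = FALSE
  )
  p <- enumerate_pairs(tok, ents, max_distance = 60L)
  expect_equal(p$distance, 7L)
  expect_equal(nrow(enumerate_pairs(tok, ents, max_distance = 6L)), 0L)
})

test_that("enumeration matches a brute-force scan on random documents", {
  set.seed(202)
  for (rep in 1:40) {
    n <- sample(10:100, 1)
    n_chem <- sample(1:4, 1); n_gene <- sample(1:4, 1)
    pos <- sample(n, n_chem + n_gene)
    d <- doc_with_entities(n, chem_at = pos[seq_len(n_chem)],
                           gene_at = pos[n_chem + seq_len(n_gene)])
    maxd <- sample(c(5L, 20L, 60L), 1)
    got <- enumerate_pairs(d$tokens, d$entities, max_distance = maxd)
    # brute force over all chemical x gene pairs (single-token entities:
    # token index == position)
    chem <- d$entities[d$entities$kind == "CHEMICAL", ]
    gene <- d$entities[d$entities$kind == "GENE", ]
    want <- list()
    for (i in seq_len(nrow(chem))) for (j in seq_len(nrow(gene))) {
      ci <- pos[i]; gj <- pos[n_chem + j]
      if (max(ci, gj) - min(ci, gj) <= maxd) {
        want[[length(want) + 1L]] <- paste(chem$entity_id[i], gene$entity_id[j])
      }
    }
    want <- if (length(want)) sort(unlist(want)) else character(0)
    expect_equal(sort(paste(got$chem_id, got$gene_id)), want,
                 info = paste("rep", rep))
  }
})

test_that("instances clip the context window and mask the candidate pair", {
  d <- doc_with_entities(20, chem_at = 4, gene_at = 11)
  v <- build_vocab(list(rep(sprintf("w%03d", 1:20), 2)))
  inst <- build_instance(d$tokens, d$entities, "C1", "G1", v)
  # window: 5 before token 4 clips to 1; 5 after token 11 -> 16
  expect_equal(length(inst$token_ids), 16L)
  expect_equal(inst$surfaces[4], "$CHEMICAL")
  expect_equal(inst$surfaces[11], "$PROTEIN")
  res <- v$reserved
  expect_equal(inst$token_ids[4], res[["MASK_CHEMICAL"]])
  expect_equal(inst$token_ids[11], res[["MASK_PROTEIN"]])
  expect_equal(unname(inst$i5[4, ]), c(1L, 0L))
  expect_equal(unname(inst$i5[11, ]), c(0L, 1L))
  expect_equal(dim(inst$i4), c(16L, 10L))
})

test_that("a token in both candidate entities becomes $BOTH with i5 = (1,1)", {
  words <- c("alpha", "shared", "omega")
  tok <- tokenize_with_spans(paste(words, collapse = " "))
  ents <- data.frame(
    doc_id = "D1", entity_id = c("C1", "G1"), kind = c("CHEMICAL", "GENE"),
    char_start = tok$char_start[2], char_end = tok$char_end[2],
    surface = "shared", stringsAsFactors = FALSE
  )
  v <- build_vocab(list(rep(words, 2)))
  inst <- build_instance(tok, ents, "C1", "G1", v)
  expect_equal(inst$surfaces[2], "$BOTH")
  expect_equal(inst$token_ids[2], v$reserved[["MASK_BOTH"]])
  expect_equal(unname(inst$i5[2, ]), c(1L, 1L))
})

test_that("i4 sees all entities but i5 only the candidate pair", {
  d <- doc_with_entities(20, chem_at = c(4, 7), gene_at = 11)
  v <- build_vocab(list(rep(sprintf("w%03d", 1:20), 2)))
  inst <- build_instance(d$tokens, d$entities, "C1", "G1", v)
  # token 7 is another chemical inside the window: i4 chemical bits set,
  # i5 zero, and its surface is NOT masked
  expect_equal(unname(inst$i4[7, 1]), 1L)
  expect_equal(unname(inst$i5[7, ]), c(0L, 0L))
  expect_equal(inst$surfaces[7], "w007")
})

test_that("labelling picks the gold group and resolves conflicts low", {
  gold <- data.frame(doc_id = "D1", group = c("CPR:4"),
                     chem_id = "C1", gene_id = "G1", stringsAsFactors = FALSE)
  expect_equal(label_candidate("C1", "G1", gold), 2L)
  expect_equal(label_candidate("C1", "G2", gold), 0L)
  gold2 <- rbind(gold, data.frame(doc_id = "D1", group = "CPR:3",
                                  chem_id = "C1", gene_id = "G1"))
  gold2$group <- c("CPR:9", "CPR:3")
  expect_warning(lab <- label_candidate("C1", "G1", gold2), "lowest")
  expect_equal(lab, 1L)
})

test_that("mask/feature invariants hold on generated synthetic corpora", {
  corpus <- generate_corpus(synth_config(n_abstracts = 15), seed = 33)
  v <- build_vocab(lapply(seq_len(nrow(corpus$abstracts)), function(i)
    tokenize_with_spans(document_text(corpus$abstracts$title[i],
                                      corpus$abstracts$body[i]))$surface))
  inst <- build_candidate_set(corpus$abstracts, corpus$entities,
                              corpus$relations, v)
  expect_gt(length(inst), 0L)
  res <- v$reserved
  for (x in inst) {
    L <- length(x$token_ids)
    expect_equal(nrow(x$i4), L)
    expect_equal(nrow(x$i5), L)
    # pair-feature bits imply the corresponding mask token
    chem_pos <- x$i5[, 1] == 1L
    gene_pos <- x$i5[, 2] == 1L
    expect_true(all(x$token_ids[chem_pos] %in%
                      res[c("MASK_CHEMICAL", "MASK_BOTH")]))
    expect_true(all(x$token_ids[gene_pos] %in%
                      res[c("MASK_PROTEIN", "MASK_BOTH")]))
  }
  # nonzero-labelled instances match the evaluable gold relations
  n_pos <- sum(vapply(inst, function(x) x$label > 0L, TRUE))
  expect_equal(n_pos, nrow(corpus$relations))
})
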