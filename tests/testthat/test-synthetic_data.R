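test_that("generated corpora have the requested size and byte-identical reruns", {
  cfg <- synth_config(n_abstracts = 10L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_chemprot_corpus(generate_corpus(cfg, seed = 9), d1)
  write_chemprot_corpus(generate_corpus(cfg, seed = 9), d2)
  expect_length(readLines(file.path(d1, "abstracts.tsv")), 10L)
  for (f in c("abstracts.tsv", "entities.tsv", "relations.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # a different seed changes the corpus
  write_chemprot_corpus(generate_corpus(cfg, seed = 10), d2)
  expect_false(identical(readLines(file.path(d1, "abstracts.tsv")),
                         readLines(file.path(d2, "abstracts.tsv"))))
})

test_that("generated offsets pass strict verification after file round-trip", {
  corpus <- generate_corpus(synth_config(n_abstracts = 12L), seed = 21)
  d <- withr::local_tempdir()
  paths <- write_chemprot_corpus(corpus, d)
  ab <- read_abstracts(paths[["abstracts"]])
  expect_silent(en <- read_entities(paths[["entities"]], ab, strict = TRUE))
  expect_silent(re <- read_gold_relations(paths[["relations"]], entities = en,
                                          strict = TRUE))
  expect_equal(nrow(re), nrow(corpus$relations))
  expect_true(all(re$group %in% cpr_groups()))
})

test_that("every gold relation survives the candidate window filter", {
  corpus <- generate_corpus(synth_config(n_abstracts = 20L), seed = 22)
  v <- build_vocab(lapply(seq_len(nrow(corpus$abstracts)), function(i)
    tokenize_with_spans(document_text(corpus$abstracts$title[i],
                                      corpus$abstracts$body[i]))$surface))
  inst <- build_candidate_set(corpus$abstracts, corpus$entities,
                              corpus$relations, v)
  expect_equal(sum(vapply(inst, function(x) x$label > 0L, TRUE)),
               nrow(corpus$relations))
})

test_that("trigger words determine the relation group bijectively", {
  cfg <- synth_config(n_abstracts = 40L)
  corpus <- generate_corpus(cfg, seed = 23)
  trigger_of <- function(doc_id, chem_id, gene_id) {
    # the trigger is the token between the pair in the relation sentence
    i <- which(corpus$abstracts$doc_id == doc_id)
    text <- document_text(corpus$abstracts$title[i], corpus$abstracts$body[i])
    tok <- tokenize_with_spans(text)
    ents <- corpus$entities[corpus$entities$doc_id == doc_id, ]
    ce <- ents[ents$entity_id == chem_id, ]
    ge <- ents[ents$entity_id == gene_id, ]
    between <- tok$surface[tok$char_start >= ce$char_end &
                             tok$char_end <= ge$char_start]
    all_triggers <- unlist(cfg$triggers, use.names = FALSE)
    intersect(between, all_triggers)
  }
  # an oracle reading only the trigger recovers every gold group
  for (i in seq_len(nrow(corpus$relations))) {
    r <- corpus$relations[i, ]
    trig <- trigger_of(r$doc_id, r$chem_id, r$gene_id)
    expect_length(trig, 1L)
    grp <- names(Filter(function(tr) trig %in% tr, cfg$triggers))
    expect_equal(grp, r$group)
  }
  # disjointness is enforced at configuration time
  bad <- .synth_triggers()
  bad[["CPR:3"]] <- c(bad[["CPR:3"]], bad[["CPR:4"]][1L])
  expect_error(synth_config(triggers = bad), "disjoint")
})

test_that("pre-training text is deterministic with non-uniform bigrams", {
  l1 <- generate_pretrain_text(100L, seed = 31)
  expect_length(l1, 100L)
  expect_identical(l1, generate_pretrain_text(100L, seed = 31))

  # bigram structure deviates strongly from independence
  lines <- generate_pretrain_text(400L, seed = 32)
  toks <- strsplit(lines, " ", fixed = TRUE)
  first <- unlist(lapply(toks, function(x) x[-length(x)]))
  second <- unlist(lapply(toks, function(x) x[-1L]))
  # restrict to frequent tokens so expected cell counts are meaningful
  top <- names(sort(table(first), decreasing = TRUE))[1:20]
  keep <- first %in% top & second %in% top
  tab <- table(first[keep], second[keep])
  chi <- suppressWarnings(stats::chisq.test(tab))
  expect_gt(chi$statistic, stats::qchisq(0.999, chi$parameter))
})

test_that("toy GloVe files round-trip through the reader", {
  p <- withr::local_tempfile()
  toks <- c("alpha", "beta", "gamma", "delta", "epsilon")
  generate_toy_glove(toks, dim = 3L, seed = 41, path = p)
  lines <- readLines(p)
  expect_length(lines, 5L)
  expect_true(all(lengths(strsplit(lines, " ")) == 4L))
  g <- read_glove(p, 3L)
  expect_equal(sort(rownames(g$vectors)), sort(toks))
  expect_true(all(abs(g$vectors) <= 1))
  p2 <- withr::local_tempfile()
  generate_toy_glove(toks, dim = 3L, seed = 41, path = p2)
  expect_identical(readLines(p2), lines)
})
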