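# Candidate chemical-protein pair generation.
#
# For every abstract, all CHEMICAL x GENE mention pairs whose token
# distance is within a window (default 60) become classification
# candidates. Each candidate carries (i) the masked token-index
# subsequence from 5 tokens before the earlier entity to 5 tokens after
# the later one, (ii) a 10-bit per-token feature sequence describing
# overlap with *all* entities in the document (input i4), and (iii) a
# 2-bit per-token sequence flagging membership in the candidate pair
# itself (input i5). Labels: 0 = NONE, 1..5 = CPR:3,4,5,6,9.

.group_label_map <- c("CPR:3" = 1L, "CPR:4" = 2L, "CPR:5" = 3L,
                      "CPR:6" = 4L, "CPR:9" = 5L)

#' Map relation group labels to candidate label indices
#'
#' @param group Character vector of group labels (`"CPR:3"` ... `"CPR:9"`).
#' @return Integer labels in 1..5 (`NA` for non-evaluated groups).
#' @export
group_to_label <- function(group) {
  unname(.group_label_map[.normalize_group(group)])
}

#' Map candidate label indices back to group labels
#'
#' @param label Integer vector in 0..5.
#' @return Character vector; label 0 maps to `"NONE"`.
#' @export
label_to_group <- function(label) {
  c("NONE", names(.group_label_map))[label + 1L]
}

# token index range of each entity: a token belongs to an entity iff any
# of the five overlap flags is set. Returns first/last 1-based token
# indices (NA when no token overlaps).
.entity_token_ranges <- function(tokens, entities) {
  n_ent <- nrow(entities)
  first_tok <- integer(n_ent)
  last_tok <- integer(n_ent)
  for (i in seq_len(n_ent)) {
    hits <- which(token_in_entity(tokens$char_start, tokens$char_end,
                                  entities$char_start[i], entities$char_end[i]))
    if (length(hits) == 0L) {
      first_tok[i] <- NA_integer_
      last_tok[i] <- NA_integer_
    } else {
      first_tok[i] <- hits[1L]
      last_tok[i] <- hits[length(hits)]
    }
  }
  data.frame(entity_id = entities$entity_id, kind = entities$kind,
             char_start = entities$char_start, first_tok = first_tok,
             last_tok = last_tok, stringsAsFactors = FALSE)
}

#' Enumerate candidate chemical-protein pairs in one document
#'
#' Entities are mapped to token index ranges via any-overlap; all
#' CHEMICAL x GENE pairs whose token distance — the index of the last
#' token of the later entity minus the index of the first token of the
#' earlier one ("earlier/later" ordered by first-token index, ties by
#' character start) — is at most `max_distance` are returned. Entities
#' overlapping no token are skipped with a warning.
#'
#' @param tokens Token data frame from [tokenize_with_spans()] on the
#'   document text.
#' @param entities Entity rows for this document.
#' @param max_distance Inclusive token-distance bound (default 60).
#' @return Data frame with columns `chem_id`, `gene_id`, `win_first`,
#'   `win_last` (token index range spanned by the pair) and `distance`.
#' @export
enumerate_pairs <- function(tokens, entities, max_distance = 60L) {
  empty <- data.frame(chem_id = character(0), gene_id = character(0),
                      win_first = integer(0), win_last = integer(0),
                      distance = integer(0), stringsAsFactors = FALSE)
  if (nrow(entities) == 0L || nrow(tokens) == 0L) return(empty)
  rng <- .entity_token_ranges(tokens, entities)
  if (anyNA(rng$first_tok)) {
    warning("skipping ", sum(is.na(rng$first_tok)),
            " entity(ies) overlapping no token")
    rng <- rng[!is.na(rng$first_tok), , drop = FALSE]
  }
  chem <- rng[rng$kind == "CHEMICAL", , drop = FALSE]
  gene <- rng[rng$kind == "GENE", , drop = FALSE]
  if (nrow(chem) == 0L || nrow(gene) == 0L) return(empty)
  grid <- expand.grid(ci = seq_len(nrow(chem)), gi = seq_len(nrow(gene)))
  c_first <- chem$first_tok[grid$ci]; c_last <- chem$last_tok[grid$ci]
  g_first <- gene$first_tok[grid$gi]; g_last <- gene$last_tok[grid$gi]
  # earlier entity: smaller first-token index, ties by char_start
  chem_earlier <- (c_first < g_first) |
    (c_first == g_first & chem$char_start[grid$ci] <= gene$char_start[grid$gi])
  ef <- ifelse(chem_earlier, c_first, g_first)
  ll <- ifelse(chem_earlier, g_last, c_last)
  distance <- ll - ef
  keep <- distance <= max_distance
  out <- data.frame(
    chem_id = chem$entity_id[grid$ci][keep],
    gene_id = gene$entity_id[grid$gi][keep],
    win_first = ef[keep],
    win_last = pmax(ifelse(chem_earlier, c_last, g_last),
                    ifelse(chem_earlier, g_last, c_last))[keep],
    distance = distance[keep],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Build one classification instance for a candidate pair
#'
#' Takes the token subsequence from `context` tokens before the earlier
#' entity to `context` tokens after the later one (clipped to the
#' document). Tokens of the candidate chemical become `$CHEMICAL`, of the
#' candidate gene `$PROTEIN`, of both `$BOTH` (one mask token per original
#' token); all other tokens map through the vocabulary with unknowns
#' falling back to `<UNK>`. The i4 features are computed against all
#' entities of the document, i5 against the candidate pair only.
#'
#' @param tokens Token data frame for the document text.
#' @param entities All entity rows for the document.
#' @param chem_id,gene_id Candidate pair entity ids.
#' @param vocab A `chemrel_vocab`.
#' @param context Number of flanking tokens (default 5).
#' @return A list of class `candidate_instance` with elements `doc_id`,
#'   `chem_id`, `gene_id`, `token_ids` (0-based), `i4` (L x 10 0/1 matrix),
#'   `i5` (L x 2), `surfaces` (masked token surfaces, for inspection) and
#'   `label` (`NA` until [label_candidate()] assigns it).
#' @export
build_instance <- function(tokens, entities, chem_id, gene_id, vocab,
                           context = 5L) {
  chem <- entities[entities$entity_id == chem_id, , drop = FALSE]
  gene <- entities[entities$entity_id == gene_id, , drop = FALSE]
  stopifnot(nrow(chem) == 1L, nrow(gene) == 1L)
  in_chem <- token_in_entity(tokens$char_start, tokens$char_end,
                             chem$char_start, chem$char_end)
  in_gene <- token_in_entity(tokens$char_start, tokens$char_end,
                             gene$char_start, gene$char_end)
  c_rng <- range(which(in_chem)); g_rng <- range(which(in_gene))
  first <- min(c_rng[1L], g_rng[1L]); last <- max(c_rng[2L], g_rng[2L])
  ws <- max(1L, first - context)
  we <- min(nrow(tokens), last + context)
  idx <- ws:we
  mem_chem <- in_chem[idx]
  mem_gene <- in_gene[idx]
  surf <- tokens$surface[idx]
  surf[mem_chem & !mem_gene] <- "$CHEMICAL"
  surf[mem_gene & !mem_chem] <- "$PROTEIN"
  surf[mem_chem & mem_gene] <- "$BOTH"
  ids <- vocab_lookup(vocab, surf)
  res <- vocab$reserved
  ids[mem_chem & !mem_gene] <- res[["MASK_CHEMICAL"]]
  ids[mem_gene & !mem_chem] <- res[["MASK_PROTEIN"]]
  ids[mem_chem & mem_gene] <- res[["MASK_BOTH"]]

  # i4: 5 overlap flags vs any CHEMICAL entity, then 5 vs any GENE entity
  i4 <- matrix(0L, nrow = length(idx), ncol = 10L)
  colnames(i4) <- c(paste0("chem_", c("in", "at_start", "at_end", "ov_start", "ov_end")),
                    paste0("gene_", c("in", "at_start", "at_end", "ov_start", "ov_end")))
  for (k in seq_len(nrow(entities))) {
    fl <- overlap_flags(tokens$char_start[idx], tokens$char_end[idx],
                        entities$char_start[k], entities$char_end[k])
    cols <- if (entities$kind[k] == "CHEMICAL") 1:5 else 6:10
    i4[, cols] <- pmax(i4[, cols], fl + 0L)
  }
  i5 <- cbind(chem = mem_chem + 0L, gene = mem_gene + 0L)
  structure(
    list(doc_id = entities$doc_id[1L], chem_id = chem_id, gene_id = gene_id,
         token_ids = ids, i4 = i4, i5 = i5, surfaces = surf,
         label = NA_integer_),
    class = "candidate_instance"
  )
}

#' Label a candidate pair against gold relations
#'
#' Returns 0 when no gold relation joins the pair; otherwise the label
#' index of the gold group. When several groups join the same pair the
#' lowest-numbered CPR group wins, with a warning.
#'
#' @param chem_id,gene_id Candidate pair entity ids.
#' @param gold Gold relations restricted to the pair's document.
#' @return Integer label in 0..5.
#' @export
label_candidate <- function(chem_id, gene_id, gold) {
  hit <- gold$chem_id == chem_id & gold$gene_id == gene_id
  if (!any(hit)) return(0L)
  labels <- sort(unique(group_to_label(gold$group[hit])))
  if (length(labels) > 1L) {
    warning("pair ", chem_id, "/", gene_id, " carries ", length(labels),
            " gold groups; keeping the lowest-numbered one")
  }
  labels[1L]
}

#' Build all labelled candidate instances for a corpus
#'
#' Tokenizes every document, enumerates pairs under the distance window,
#' builds masked instances and attaches gold labels.
#'
#' @param abstracts,entities,gold Corpus data frames as returned by the
#'   readers in this package (`gold` may be `NULL` for unlabelled data).
#' @param vocab A `chemrel_vocab`.
#' @param max_distance,context See [enumerate_pairs()] and [build_instance()].
#' @return A list of `candidate_instance` objects.
#' @export
build_candidate_set <- function(abstracts, entities, gold = NULL, vocab,
                                max_distance = 60L, context = 5L) {
  out <- list()
  for (i in seq_len(nrow(abstracts))) {
    did <- abstracts$doc_id[i]
    toks <- tokenize_with_spans(document_text(abstracts$title[i], abstracts$body[i]))
    ents <- entities[entities$doc_id == did, , drop = FALSE]
    if (nrow(ents) == 0L) next
    pairs <- enumerate_pairs(toks, ents, max_distance = max_distance)
    if (nrow(pairs) == 0L) next
    gold_doc <- if (is.null(gold)) NULL else gold[gold$doc_id == did, , drop = FALSE]
    for (j in seq_len(nrow(pairs))) {
      inst <- build_instance(toks, ents, pairs$chem_id[j], pairs$gene_id[j],
                             vocab, context = context)
      inst$label <- if (is.null(gold_doc)) NA_integer_ else {
        label_candidate(pairs$chem_id[j], pairs$gene_id[j], gold_doc)
      }
      out[[length(out) + 1L]] <- inst
    }
  }
  out
}

#' @export
print.candidate_instance <- function(x, ...) {
  cat("<candidate_instance> ", x$doc_id, " ", x$chem_id, "/", x$gene_id,
      " label=", x$label, " len=", length(x$token_ids), "\n", sep = "")
  invisible(x)
}

#' Serialize candidate instances to JSON lines
#'
#' One JSON object per line with the document id, pair ids, masked token
#' surfaces and label — a human-inspectable debug format.
#'
#' @param instances List of `candidate_instance` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_instances_jsonl <- function(instances, path) {
  lines <- vapply(instances, function(x) {
    jsonlite::toJSON(
      list(doc_id = x$doc_id, chem_id = x$chem_id, gene_id = x$gene_id,
           tokens = x$surfaces, label = x$label),
      auto_unbox = TRUE
    )
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
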