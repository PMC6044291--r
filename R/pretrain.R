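# Phase-1 negative-sampling task construction.
#
# Unlabelled text, one paragraph per line, is consumed in sub-epochs of
# `n` lines. Within a sub-epoch every token of every line is replaced
# with probability p = 0.5 by a token drawn (occurrence-weighted) from
# the sub-epoch's own token pool; the network then has to judge, for each
# position, whether the token it sees is original (1) or a substituted
# "negative sample" (0), from the left and from the right context.

#' A cycling line source over unlabelled text
#'
#' Wraps a character vector (or a plain-text file, one paragraph per
#' line) with a moving cursor. Reads past the end wrap around to the
#' beginning; each wrap is reported via `message()`.
#'
#' @param x Character vector of lines, or a file path.
#' @return An object of class `line_source`.
#' @export
line_source <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) {
    readLines(x, encoding = "UTF-8", warn = FALSE)
  } else {
    as.character(x)
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("line source is empty")
  env <- new.env(parent = emptyenv())
  env$lines <- lines
  env$pos <- 0L
  class(env) <- "line_source"
  env
}

#' Read the next `n` lines from a source, cycling at EOF
#'
#' @param src A [line_source()].
#' @param n Number of lines.
#' @return Character vector of length `n`.
#' @export
next_lines <- function(src, n) {
  stopifnot(inherits(src, "line_source"), n >= 1L)
  total <- length(src$lines)
  idx <- ((src$pos + seq_len(n) - 1L) %% total) + 1L
  if (src$pos + n > total) {
    message("line source cycled (", ceiling((src$pos + n) / total) - 1L,
            " wrap(s) so far)")
  }
  src$pos <- (src$pos + n) %% total
  src$lines[idx]
}

#' Sample and tokenize one sub-epoch of unlabelled lines
#'
#' Reads `n` lines from the source (cycling if needed) and tokenizes
#' them. The substitution pool for the sub-epoch is the multiset of all
#' tokens in these lines.
#'
#' @param src A [line_source()].
#' @param n Lines per sub-epoch (default 12000, the full-scale setting).
#' @return List with `sequences` (list of character vectors) and `pool`
#'   (character vector, occurrence-weighted token pool).
#' @export
sample_subepoch <- function(src, n = 12000L) {
  lines <- next_lines(src, n)
  seqs <- lapply(lines, function(l) tokenize_with_spans(l)$surface)
  list(sequences = seqs, pool = unlist(seqs, use.names = FALSE))
}

#' Randomly substitute tokens to create negative samples
#'
#' Each position is independently replaced with probability `p` by a
#' token drawn uniformly from the pool of token *occurrences*. The
#' returned flags record the replacement event — a flag is 0 whenever the
#' position was substituted, even if the sampled token happens to equal
#' the original.
#'
#' @param tokens Character vector.
#' @param pool Non-empty character vector of candidate replacements.
#' @param p Replacement probability (default 0.5).
#' @return List with `tokens` (substituted sequence) and `flags`
#'   (integer vector: 1 = original, 0 = replaced).
#' @export
substitute_tokens <- function(tokens, pool, p = 0.5) {
  if (length(pool) == 0L) stop("substitution pool is empty")
  L <- length(tokens)
  replaced <- stats::runif(L) < p
  out <- tokens
  if (any(replaced)) {
    out[replaced] <- pool[sample.int(length(pool), sum(replaced), replace = TRUE)]
  }
  list(tokens = out, flags = as.integer(!replaced))
}

#' Assemble one pretraining example
#'
#' Builds the three input sequences and two targets: `i1` is the original
#' token-id sequence; `i2` the substituted sequence shifted one right
#' (padding first); `i3` shifted one left (padding last). `y_left` and
#' `y_right` are the replacement flags shifted in step with `i2`/`i3`.
#' One shared `loss_mask` is zero exactly at the two shift-introduced
#' padding positions (the first and last), so those positions never
#' contribute to the loss.
#'
#' @param original_ids,substituted_ids Equal-length integer id sequences.
#' @param flags Replacement flags from [substitute_tokens()].
#' @param pad_id Padding index (default 0).
#' @return A list of class `pretrain_example` with elements `i1`, `i2`,
#'   `i3`, `y_left`, `y_right`, `loss_mask`, all of equal length.
#' @export
make_pretrain_example <- function(original_ids, substituted_ids, flags,
                                  pad_id = 0L) {
  L <- length(original_ids)
  stopifnot(length(substituted_ids) == L, length(flags) == L, L >= 1L)
  if (L == 1L) {
    ex <- list(i1 = original_ids, i2 = pad_id, i3 = pad_id,
               y_left = 0L, y_right = 0L, loss_mask = 0L)
  } else {
    ex <- list(
      i1 = original_ids,
      i2 = c(pad_id, substituted_ids[-L]),
      i3 = c(substituted_ids[-1L], pad_id),
      y_left = c(0L, flags[-L]),
      y_right = c(flags[-1L], 0L),
      loss_mask = c(0L, rep(1L, L - 2L), 0L)
    )
  }
  structure(ex, class = "pretrain_example")
}

#' Build all pretraining examples for a sub-epoch
#'
#' Applies substitution and example assembly to every tokenized line,
#' mapping tokens through the vocabulary.
#'
#' @param subepoch Result of [sample_subepoch()].
#' @param vocab A `chemrel_vocab`.
#' @param p Replacement probability.
#' @return List of `pretrain_example` objects (empty lines are skipped).
#' @export
make_subepoch_examples <- function(subepoch, vocab, p = 0.5) {
  out <- vector("list", length(subepoch$sequences))
  for (i in seq_along(subepoch$sequences)) {
    toks <- subepoch$sequences[[i]]
    if (length(toks) == 0L) next
    sub <- substitute_tokens(toks, subepoch$pool, p = p)
    out[[i]] <- make_pretrain_example(vocab_lookup(vocab, toks),
                                      vocab_lookup(vocab, sub$tokens),
                                      sub$flags,
                                      pad_id = vocab$reserved[["PAD"]])
  }
  out[!vapply(out, is.null, TRUE)]
}

# pad an integer vector to length T
.pad_to <- function(x, T, fill = 0L) c(x, rep(fill, T - length(x)))

#' Group examples into length-sorted padded batches
#'
#' Examples are sorted by length (stable) and chunked into groups of at
#' most `batch_size`: the shortest `batch_size` examples form one batch,
#' the next shortest the next, and so on. Within a batch every field is
#' padded to the batch's maximum length; the loss mask is zero at padded
#' positions. The union of all batches is exactly the input multiset.
#'
#' @param examples List of `pretrain_example` objects.
#' @param batch_size Maximum examples per batch (default 32).
#' @param pad_id Padding index.
#' @return List of batches; each batch is a list of integer matrices
#'   `i1`, `i2`, `i3`, `y_left`, `y_right`, `loss_mask` of shape
#'   batch x max-length, plus `lengths`.
#' @export
batch_by_length <- function(examples, batch_size = 32L, pad_id = 0L) {
  if (length(examples) == 0L) return(list())
  lens <- vapply(examples, function(e) length(e$i1), 1L)
  ord <- order(lens) # stable
  chunks <- split(ord, ceiling(seq_along(ord) / batch_size))
  lapply(unname(chunks), function(ix) {
    exs <- examples[ix]
    tmax <- max(lens[ix])
    fields <- c("i1", "i2", "i3", "y_left", "y_right", "loss_mask")
    fill <- c(pad_id, pad_id, pad_id, 0L, 0L, 0L)
    b <- stats::setNames(lapply(seq_along(fields), function(f) {
      do.call(rbind, lapply(exs, function(e) .pad_to(e[[fields[f]]], tmax, fill[f])))
    }), fields)
    b$lengths <- lens[ix]
    b
  })
}

#' Group candidate instances into length-sorted padded batches
#'
#' The recognition-phase analogue of [batch_by_length()]: candidates are
#' sorted by sequence length, chunked into groups of at most
#' `batch_size`, and padded per group. `pos_mask` marks real (non-pad)
#' positions; it gates the max-pooling layer.
#'
#' @param instances List of `candidate_instance` objects.
#' @param batch_size Maximum instances per batch (default 32).
#' @param pad_id Padding index.
#' @return List of batches with `token_ids` (B x T), `i4` (B x T x 10),
#'   `i5` (B x T x 2), `pos_mask` (B x T), `labels`, `lengths` and `idx`
#'   (positions of the batch's instances in the input list).
#' @export
batch_candidates <- function(instances, batch_size = 32L, pad_id = 0L) {
  if (length(instances) == 0L) return(list())
  lens <- vapply(instances, function(e) length(e$token_ids), 1L)
  ord <- order(lens)
  chunks <- split(ord, ceiling(seq_along(ord) / batch_size))
  lapply(unname(chunks), function(ix) {
    exs <- instances[ix]
    B <- length(exs)
    tmax <- max(lens[ix])
    ids <- do.call(rbind, lapply(exs, function(e) .pad_to(e$token_ids, tmax, pad_id)))
    pos_mask <- do.call(rbind, lapply(exs, function(e) .pad_to(rep(1L, length(e$token_ids)), tmax)))
    i4 <- array(0, dim = c(B, tmax, 10L))
    i5 <- array(0, dim = c(B, tmax, 2L))
    for (b in seq_len(B)) {
      Lb <- lens[ix][b]
      i4[b, seq_len(Lb), ] <- exs[[b]]$i4
      i5[b, seq_len(Lb), ] <- exs[[b]]$i5
    }
    labels <- vapply(exs, function(e) as.integer(e$label), 1L)
    list(token_ids = ids, i4 = i4, i5 = i5, pos_mask = pos_mask,
         labels = labels, lengths = lens[ix], idx = ix)
  })
}
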