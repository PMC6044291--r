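# Token vocabulary with the min-count out-of-vocab policy, and assembly of
# the initial embedding matrix from GloVe vectors.
#
# Index layout (0-based, as used in serialized instances): 0 = padding,
# 1 = unknown, 2/3/4 = the $CHEMICAL/$PROTEIN/$BOTH masks, corpus tokens
# from 5 upward. Tokens seen fewer than `min_count` times in the training
# corpus fall back to the unknown index at lookup time.

.reserved_tokens <- c("<PAD>", "<UNK>", "$CHEMICAL", "$PROTEIN", "$BOTH")

#' Reserved vocabulary indices
#'
#' @return Named integer vector: `PAD = 0`, `UNK = 1`, `MASK_CHEMICAL = 2`,
#'   `MASK_PROTEIN = 3`, `MASK_BOTH = 4`.
#' @export
reserved_indices <- function() {
  c(PAD = 0L, UNK = 1L, MASK_CHEMICAL = 2L, MASK_PROTEIN = 3L, MASK_BOTH = 4L)
}

#' Build a token vocabulary
#'
#' Counts tokens over the supplied streams and retains those occurring at
#' least `min_count` times (default 2: hapax tokens are treated as
#' out-of-vocab). Retained tokens receive dense indices after the five
#' reserved entries, ordered by decreasing count with alphabetical
#' tie-break, so the mapping is deterministic.
#'
#' @param token_streams A list of character vectors (e.g. one per document).
#' @param min_count Minimum corpus frequency for a token to be in-vocab.
#' @return An object of class `chemrel_vocab`.
#' @export
build_vocab <- function(token_streams, min_count = 2L) {
  stopifnot(is.list(token_streams) || is.character(token_streams))
  if (is.character(token_streams)) token_streams <- list(token_streams)
  tokens <- unlist(token_streams, use.names = FALSE)
  tokens <- tokens[!(tokens %in% .reserved_tokens)]
  counts <- table(tokens)
  keep <- counts[counts >= min_count]
  kept <- if (length(keep) == 0L) character(0) else {
    names(keep)[order(-as.integer(keep), names(keep), method = "radix")]
  }
  index <- stats::setNames(seq_along(kept) + 4L, kept) # after reserved 0..4
  structure(
    list(
      index = c(stats::setNames(0:4, .reserved_tokens), index),
      reserved = reserved_indices(),
      min_count = as.integer(min_count),
      size = length(kept) + 5L
    ),
    class = "chemrel_vocab"
  )
}

#' @export
print.chemrel_vocab <- function(x, ...) {
  cat("<chemrel_vocab> ", x$size, " entries (", x$size - 5L,
      " corpus tokens, min_count = ", x$min_count, ")\n", sep = "")
  invisible(x)
}

#' Number of retained corpus tokens
#'
#' @param vocab A `chemrel_vocab`.
#' @return Integer count, excluding the five reserved entries.
#' @export
vocab_retained <- function(vocab) vocab$size - 5L

#' Look up token indices
#'
#' Total lookup: any token absent from the vocabulary (including tokens
#' dropped by the min-count rule) maps to the unknown index.
#'
#' @param vocab A `chemrel_vocab`.
#' @param tokens Character vector.
#' @return Integer vector of 0-based vocabulary indices.
#' @export
vocab_lookup <- function(vocab, tokens) {
  idx <- vocab$index[tokens]
  idx[is.na(idx)] <- vocab$reserved[["UNK"]]
  as.integer(unname(idx))
}

#' Assemble the initial embedding matrix
#'
#' Rows for vocabulary tokens present in the GloVe table copy the GloVe
#' vector; rows for tokens absent from GloVe, and all five reserved rows,
#' are initialized to zero. Every row remains trainable downstream.
#'
#' @param vocab A `chemrel_vocab`.
#' @param glove A `glove_table` from [read_glove()], or `NULL` for all-zero
#'   initialization.
#' @param dim Embedding dimension (default 300); must match `glove$dim`
#'   when a table is given.
#' @return A numeric matrix of shape `vocab$size` x `dim` with the
#'   vocabulary tokens as rownames (in index order).
#' @export
build_embedding_matrix <- function(vocab, glove = NULL, dim = 300L) {
  dim <- as.integer(dim)
  if (!is.null(glove)) {
    stopifnot(inherits(glove, "glove_table"))
    if (glove$dim != dim) {
      stop("GloVe dimension ", glove$dim, " does not match embedding dim ", dim)
    }
  }
  ord <- names(sort(vocab$index))
  emb <- matrix(0, nrow = vocab$size, ncol = dim, dimnames = list(ord, NULL))
  if (!is.null(glove) && nrow(glove$vectors)) {
    hit <- intersect(ord[-(1:5)], rownames(glove$vectors))
    if (length(hit)) emb[hit, ] <- glove$vectors[hit, , drop = FALSE]
  }
  emb
}

#' Save / load an embedding checkpoint
#'
#' The matrix is stored as a flat text array of numbers beside a JSON
#' token-index map, keeping checkpoints plain-text and portable.
#'
#' @param emb Embedding matrix with token rownames.
#' @param path Basename; writes `<path>.values.txt` and `<path>.index.json`.
#' @return `path`, invisibly.
#' @export
save_embedding <- function(emb, path) {
  utils::write.table(emb, paste0(path, ".values.txt"),
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(tokens = rownames(emb), dim = ncol(emb)),
    paste0(path, ".index.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname save_embedding
#' @export
load_embedding <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".index.json"), simplifyVector = TRUE)
  emb <- as.matrix(utils::read.table(paste0(path, ".values.txt")))
  dimnames(emb) <- list(meta$tokens, NULL)
  stopifnot(ncol(emb) == meta$dim)
  emb
}
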