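# Chemistry-aware tokenization with character spans.
#
# Chemical names make naive punctuation splitting destructive: "COX-2",
# "(S)-ibuprofen" or "1,2-diol" must survive as single tokens while a
# sentence-final "." or an unbalanced bracket must not. The rule set here:
# split on whitespace, then iteratively peel off leading/trailing
# clause punctuation and *unbalanced* brackets as one-character tokens,
# keeping internal hyphens, digits and balanced brackets intact.

.punct_strip <- c(".", ",", ";", ":", "!", "?", "\"", "'")
.bracket_open <- c("(", "[", "{")
.bracket_close <- c(")", "]", "}")

# Should the leading/trailing bracket at position `pos` be peeled off?
# A leading opener is peeled when it has no matching closer in the chunk;
# a trailing closer when it has no matching opener.
.bracket_unbalanced <- function(chars, lo, hi, leading) {
  ch <- if (leading) chars[lo] else chars[hi]
  side <- if (leading) match(ch, .bracket_open) else match(ch, .bracket_close)
  if (is.na(side)) return(FALSE)
  region <- chars[lo:hi]
  n_open <- sum(region == .bracket_open[side])
  n_close <- sum(region == .bracket_close[side])
  if (leading) n_open > n_close else n_close > n_open
}

.split_chunk <- function(chunk) {
  chars <- strsplit(chunk, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  lo <- 1L
  hi <- n
  repeat {
    if (lo > hi) break
    changed <- FALSE
    if (chars[hi] %in% .punct_strip || .bracket_unbalanced(chars, lo, hi, FALSE)) {
      hi <- hi - 1L
      changed <- TRUE
    }
    if (lo <= hi &&
        (chars[lo] %in% .punct_strip || .bracket_unbalanced(chars, lo, hi, TRUE))) {
      lo <- lo + 1L
      changed <- TRUE
    }
    if (!changed) break
  }
  # relative 0-based half-open spans, in text order
  starts <- integer(0)
  ends <- integer(0)
  if (lo > 1L) {
    starts <- c(starts, 0L:(lo - 2L))
    ends <- c(ends, 1L:(lo - 1L))
  }
  if (lo <= hi) {
    starts <- c(starts, lo - 1L)
    ends <- c(ends, hi)
  }
  if (hi < n) {
    starts <- c(starts, hi:(n - 1L))
    ends <- c(ends, (hi + 1L):n)
  }
  list(starts = starts, ends = ends)
}

#' Tokenize text into tokens with character spans
#'
#' Splits `text` on whitespace, then strips clause punctuation
#' (`. , ; : ! ? " '`) and unbalanced brackets from token edges as
#' single-character tokens. Internal hyphens, digits and balanced brackets
#' are preserved, so chemical names such as `"COX-2"` and `"(S)-ibuprofen"`
#' remain whole. Offsets are 0-based half-open into `text`, and every
#' surface equals the corresponding slice of `text`.
#'
#' @param text A single character string (may be empty).
#' @return A data frame with columns `surface`, `char_start`, `char_end`,
#'   one row per token, in increasing span order.
#' @examples
#' tokenize_with_spans("Aspirin inhibits COX-2.")$surface
#' @export
tokenize_with_spans <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  empty <- data.frame(surface = character(0), char_start = integer(0),
                      char_end = integer(0), stringsAsFactors = FALSE)
  if (nchar(text) == 0L) return(empty)
  m <- gregexpr("\\S+", text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(empty)
  chunk_start <- as.integer(m) - 1L # 0-based
  chunk_len <- attr(m, "match.length")
  out_start <- vector("list", length(chunk_start))
  out_end <- vector("list", length(chunk_start))
  for (i in seq_along(chunk_start)) {
    chunk <- substr(text, chunk_start[i] + 1L, chunk_start[i] + chunk_len[i])
    sp <- .split_chunk(chunk)
    out_start[[i]] <- chunk_start[i] + sp$starts
    out_end[[i]] <- chunk_start[i] + sp$ends
  }
  char_start <- unlist(out_start)
  char_end <- unlist(out_end)
  data.frame(
    surface = substring(text, char_start + 1L, char_end),
    char_start = as.integer(char_start),
    char_end = as.integer(char_end),
    stringsAsFactors = FALSE
  )
}

#' Token/entity overlap flags
#'
#' Classifies how a token span relates to an entity span. All five flags are
#' defined on 0-based half-open intervals:
#' * `in`: token lies entirely inside the entity,
#' * `at_start` / `at_end`: inside and sharing the entity's start/end,
#' * `overlaps_start` / `overlaps_end`: the token straddles the entity
#'   boundary (and is therefore not `in`).
#'
#' Arguments are recycled, so one token can be tested against many entities
#' or vice versa.
#'
#' @param tok_start,tok_end Token span offsets (0-based half-open).
#' @param ent_start,ent_end Entity span offsets in the same coordinates.
#' @return A logical matrix with columns
#'   `in`, `at_start`, `at_end`, `overlaps_start`, `overlaps_end`.
#' @export
overlap_flags <- function(tok_start, tok_end, ent_start, ent_end) {
  n <- max(length(tok_start), length(ent_start))
  ts <- rep_len(as.integer(tok_start), n)
  te <- rep_len(as.integer(tok_end), n)
  es <- rep_len(as.integer(ent_start), n)
  ee <- rep_len(as.integer(ent_end), n)
  inside <- ts >= es & te <= ee
  cbind(
    `in` = inside,
    at_start = inside & ts == es,
    at_end = inside & te == ee,
    overlaps_start = !inside & ts < es & es < te,
    overlaps_end = !inside & ts < ee & ee < te
  )
}

#' Does a token belong to an entity?
#'
#' A token counts as part of an entity when any of the five
#' [overlap_flags()] is set, i.e. on any overlap at all. Partial overlaps
#' count: this is what makes a token shared by a chemical and a protein
#' annotation maskable as `$BOTH`.
#'
#' @inheritParams overlap_flags
#' @return Logical vector.
#' @export
token_in_entity <- function(tok_start, tok_end, ent_start, ent_end) {
  rowSums(overlap_flags(tok_start, tok_end, ent_start, ent_end)) > 0
}
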