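# Readers/writers for the CHEMPROT-style tab-separated corpus files and
# GloVe text-format word vectors.
#
# Offset convention: entity character offsets index the document text
# formed as title + one tab character + body, 0-based half-open. Strict
# mode verifies every annotated surface against that slice and fails
# loudly if the corpus at hand uses a different dialect.

.evaluated_groups <- c("CPR:3", "CPR:4", "CPR:5", "CPR:6", "CPR:9")

#' The five evaluated relation groups
#'
#' Canonical labels of the chemical-protein relation groups scored by the
#' task: CPR:3 upregulator/activator, CPR:4 downregulator/inhibitor,
#' CPR:5 agonist, CPR:6 antagonist, CPR:9 substrate/product.
#'
#' @return Character vector of length 5.
#' @export
cpr_groups <- function() .evaluated_groups

# "CPR:4", "CPR-4", "CPR 4", "CPR4" -> "CPR:4"; anything else unchanged
.normalize_group <- function(x) {
  sub("^CPR[ :-]?([0-9]+)$", "CPR:\\1", toupper(trimws(x)))
}

.read_tsv_lines <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

#' Assemble the document text of an abstract
#'
#' Title and body joined by a single tab character; entity offsets index
#' this string (0-based half-open).
#'
#' @param title,body Character scalars.
#' @return Character scalar.
#' @export
document_text <- function(title, body) paste(title, body, sep = "\t")

#' Read a CHEMPROT-style abstracts file
#'
#' Each non-empty line holds `doc_id<TAB>title<TAB>body`. Tabs beyond the
#' second are treated as part of the body.
#'
#' @param path Path to a tab-separated abstracts file.
#' @return A data frame with columns `doc_id`, `title`, `body`, one row per
#'   line, order preserved.
#' @export
read_abstracts <- function(path) {
  tsv <- .read_tsv_lines(path)
  out <- data.frame(doc_id = character(0), title = character(0),
                    body = character(0), stringsAsFactors = FALSE)
  if (length(tsv$lines) == 0L) return(out)
  parts <- strsplit(tsv$lines, "\t", fixed = TRUE)
  n_fields <- lengths(parts)
  if (any(n_fields < 3L)) {
    bad <- tsv$lineno[which(n_fields < 3L)[1L]]
    stop("malformed abstract line ", bad, ": expected at least 3 tab-separated fields")
  }
  doc_id <- vapply(parts, `[[`, "", 1L)
  if (any(!nzchar(doc_id))) {
    stop("malformed abstract line ", tsv$lineno[which(!nzchar(doc_id))[1L]],
         ": empty doc_id")
  }
  if (anyDuplicated(doc_id)) {
    stop("duplicate doc_id in abstracts file: ", doc_id[anyDuplicated(doc_id)])
  }
  data.frame(
    doc_id = doc_id,
    title = vapply(parts, `[[`, "", 2L),
    body = vapply(parts, function(p) paste(p[-(1:2)], collapse = "\t"), ""),
    stringsAsFactors = FALSE
  )
}

#' Read a CHEMPROT-style entity mentions file
#'
#' Each line holds `doc_id<TAB>entity_id<TAB>type<TAB>start<TAB>end<TAB>surface`.
#' Types `CHEMICAL` map to `CHEMICAL`; `GENE`, `GENE-Y` and `GENE-N` map to
#' `GENE`; anything else is an error. In strict mode the annotated surface is
#' checked against the document-text slice at the given offsets.
#'
#' @param path Path to a tab-separated entities file.
#' @param abstracts Optional abstracts data frame (required for `strict`).
#' @param strict Verify surfaces against document slices.
#' @return Data frame with columns `doc_id`, `entity_id`, `kind`,
#'   `char_start`, `char_end`, `surface`.
#' @export
read_entities <- function(path, abstracts = NULL, strict = FALSE) {
  tsv <- .read_tsv_lines(path)
  out <- data.frame(doc_id = character(0), entity_id = character(0),
                    kind = character(0), char_start = integer(0),
                    char_end = integer(0), surface = character(0),
                    stringsAsFactors = FALSE)
  if (length(tsv$lines) == 0L) return(out)
  parts <- strsplit(tsv$lines, "\t", fixed = TRUE)
  n_fields <- lengths(parts)
  if (any(n_fields < 6L)) {
    stop("malformed entity line ", tsv$lineno[which(n_fields < 6L)[1L]],
         ": expected 6 tab-separated fields")
  }
  type_raw <- toupper(vapply(parts, `[[`, "", 3L))
  kind <- ifelse(type_raw == "CHEMICAL", "CHEMICAL",
                 ifelse(type_raw %in% c("GENE", "GENE-Y", "GENE-N"), "GENE", NA))
  if (anyNA(kind)) {
    i <- which(is.na(kind))[1L]
    stop("unknown entity type '", vapply(parts, `[[`, "", 3L)[i],
         "' at line ", tsv$lineno[i])
  }
  ent <- data.frame(
    doc_id = vapply(parts, `[[`, "", 1L),
    entity_id = vapply(parts, `[[`, "", 2L),
    kind = kind,
    char_start = as.integer(vapply(parts, `[[`, "", 4L)),
    char_end = as.integer(vapply(parts, `[[`, "", 5L)),
    surface = vapply(parts, `[[`, "", 6L),
    stringsAsFactors = FALSE
  )
  if (anyNA(ent$char_start) || anyNA(ent$char_end) ||
      any(ent$char_start < 0L) || any(ent$char_start >= ent$char_end)) {
    stop("invalid character offsets in entity file ", path)
  }
  if (strict) {
    if (is.null(abstracts)) stop("strict = TRUE requires `abstracts`")
    doc_text <- stats::setNames(document_text(abstracts$title, abstracts$body),
                                abstracts$doc_id)
    if (any(!(ent$doc_id %in% names(doc_text)))) {
      stop("entity refers to unknown doc_id: ",
           ent$doc_id[!(ent$doc_id %in% names(doc_text))][1L])
    }
    slice <- substring(doc_text[ent$doc_id], ent$char_start + 1L, ent$char_end)
    bad <- which(slice != ent$surface)
    if (length(bad)) {
      stop("offset convention mismatch for entity ", ent$entity_id[bad[1L]],
           " in ", ent$doc_id[bad[1L]], ": annotated '", ent$surface[bad[1L]],
           "' but document slice is '", slice[bad[1L]], "'")
    }
  }
  ent
}

#' Read a CHEMPROT-style gold relations file
#'
#' Accepts the challenge dialect (`Arg1:T1` / `Arg2:T2` argument fields,
#' possibly with extra columns between the group and the arguments) and a
#' plain dialect (bare entity ids in fields 3 and 4). Only the five
#' evaluated groups (see [cpr_groups()]) are retained; records in other
#' groups are dropped, with a message reporting the count.
#'
#' @param path Path to a tab-separated relations file.
#' @param entities Optional entities data frame (required for `strict`).
#' @param strict Check that arguments resolve to a CHEMICAL and a GENE
#'   mention in the same document.
#' @return Data frame with columns `doc_id`, `group`, `chem_id`, `gene_id`.
#' @export
read_gold_relations <- function(path, entities = NULL, strict = FALSE) {
  tsv <- .read_tsv_lines(path)
  out <- data.frame(doc_id = character(0), group = character(0),
                    chem_id = character(0), gene_id = character(0),
                    stringsAsFactors = FALSE)
  if (length(tsv$lines) == 0L) return(out)
  parts <- strsplit(tsv$lines, "\t", fixed = TRUE)
  n_fields <- lengths(parts)
  if (any(n_fields < 4L)) {
    stop("malformed relation line ", tsv$lineno[which(n_fields < 4L)[1L]],
         ": expected at least 4 tab-separated fields")
  }
  pick_arg <- function(p, argno, fallback) {
    pat <- paste0("^[Aa][Rr][Gg]", argno, ":")
    hit <- grep(pat, p, value = TRUE)
    if (length(hit)) sub(pat, "", hit[1L]) else p[[fallback]]
  }
  rel <- data.frame(
    doc_id = vapply(parts, `[[`, "", 1L),
    group = .normalize_group(vapply(parts, `[[`, "", 2L)),
    chem_id = vapply(parts, pick_arg, "", argno = 1L, fallback = 3L),
    gene_id = vapply(parts, pick_arg, "", argno = 2L, fallback = 4L),
    stringsAsFactors = FALSE
  )
  keep <- rel$group %in% .evaluated_groups
  if (any(!keep)) {
    message("read_gold_relations: dropped ", sum(!keep),
            " relation(s) outside the five evaluated groups")
  }
  rel <- rel[keep, , drop = FALSE]
  rownames(rel) <- NULL
  if (strict && nrow(rel)) {
    if (is.null(entities)) stop("strict = TRUE requires `entities`")
    key <- paste(entities$doc_id, entities$entity_id)
    kind <- stats::setNames(entities$kind, key)
    ck <- kind[paste(rel$doc_id, rel$chem_id)]
    gk <- kind[paste(rel$doc_id, rel$gene_id)]
    if (anyNA(ck) || anyNA(gk)) {
      i <- which(is.na(ck) | is.na(gk))[1L]
      stop("relation argument not resolvable against entities: ",
           rel$doc_id[i], " ", rel$chem_id[i], "/", rel$gene_id[i])
    }
    if (any(ck != "CHEMICAL") || any(gk != "GENE")) {
      i <- which(ck != "CHEMICAL" | gk != "GENE")[1L]
      stop("relation arguments have wrong entity kinds in ", rel$doc_id[i])
    }
  }
  rel
}

#' Write relation predictions
#'
#' Writes one tab-separated line per prediction. The `plain` dialect writes
#' bare entity ids (and round-trips through [read_gold_relations()]); the
#' `challenge` dialect writes `Arg1:`/`Arg2:` prefixed arguments as used in
#' the shared-task answer files.
#'
#' @param preds Data frame with columns `doc_id`, `group`, `chem_id`, `gene_id`.
#' @param path Output file path.
#' @param dialect `"plain"` (default) or `"challenge"`.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(preds, path, dialect = c("plain", "challenge")) {
  dialect <- match.arg(dialect)
  stopifnot(all(c("doc_id", "group", "chem_id", "gene_id") %in% names(preds)))
  grp <- .normalize_group(preds$group)
  if (nrow(preds) && any(!(grp %in% .evaluated_groups))) {
    stop("predictions contain a non-evaluated group: ",
         grp[!(grp %in% .evaluated_groups)][1L])
  }
  lines <- if (nrow(preds) == 0L) character(0) else if (dialect == "plain") {
    paste(preds$doc_id, grp, preds$chem_id, preds$gene_id, sep = "\t")
  } else {
    paste(preds$doc_id, grp, paste0("Arg1:", preds$chem_id),
          paste0("Arg2:", preds$gene_id), sep = "\t")
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read GloVe text-format word vectors
#'
#' Each line is a token followed by `d` space-separated reals, no header.
#' All vectors must share one dimension; when a token occurs on several
#' lines the last occurrence wins.
#'
#' @param path Path to a GloVe text file.
#' @param expected_dim Required vector dimension; `NULL` infers it from the
#'   first line.
#' @return An object of class `glove_table`: a list with `vectors` (matrix,
#'   tokens as rownames) and `dim`.
#' @export
read_glove <- function(path, expected_dim = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    d <- if (is.null(expected_dim)) 0L else as.integer(expected_dim)
    return(structure(list(vectors = matrix(numeric(0), 0L, d), dim = d),
                     class = "glove_table"))
  }
  parts <- strsplit(trimws(lines), "[ \t]+")
  tokens <- vapply(parts, `[[`, "", 1L)
  dims <- lengths(parts) - 1L
  d <- if (is.null(expected_dim)) dims[1L] else as.integer(expected_dim)
  if (any(dims != d)) {
    i <- which(dims != d)[1L]
    stop("GloVe dimension mismatch for token '", tokens[i], "': expected ",
         d, " values, found ", dims[i])
  }
  vec <- matrix(as.numeric(unlist(lapply(parts, `[`, -1L))), ncol = d, byrow = TRUE)
  if (anyNA(vec)) stop("non-numeric vector component in GloVe file ", path)
  keep <- !duplicated(tokens, fromLast = TRUE)
  vec <- vec[keep, , drop = FALSE]
  rownames(vec) <- tokens[keep]
  structure(list(vectors = vec, dim = as.integer(d)), class = "glove_table")
}

#' @export
print.glove_table <- function(x, ...) {
  cat("<glove_table> ", nrow(x$vectors), " tokens x ", x$dim, " dims\n", sep = "")
  invisible(x)
}
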