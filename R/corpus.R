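#' Construct a corpus tibble
#'
#' A corpus is a tibble with one row per document. Each document is a
#' tokenized participant transcript for one elicitation task, optionally
#' carrying a binary word-by-tag annotation matrix.
#'
#' @param id Character vector of unique document ids.
#' @param label Diagnostic label, one of `"AS"`, `"nonAS"`, `"unknown"`.
#' @param task Elicitation task, one of `"interview"`, `"recounting"`.
#' @param tokens List of character vectors (the words, length `L >= 1`).
#' @param tags List of `L x 147` binary integer matrices, or `NULL` entries
#'   for untagged documents.
#' @param annotation_source One of `"manual"`, `"auto"`, `"none"` per document.
#' @param schema Tag schema used to validate matrix width.
#' @return A tibble of class `sfl_corpus` with columns `id`, `label`, `task`,
#'   `tokens` (list), `tags` (list), `annotation_source`.
#' @export
corpus_tibble <- function(id, label, task, tokens, tags = NULL,
                          annotation_source = NULL,
                          schema = default_schema()) {
  n <- length(id)
  if (is.null(tags)) tags <- rep(list(NULL), n)
  if (is.null(annotation_source)) {
    annotation_source <- ifelse(vapply(tags, is.null, logical(1)),
                                "none", "manual")
  }
  out <- tibble::tibble(
    id = as.character(id),
    label = as.character(label),
    task = as.character(task),
    tokens = as.list(tokens),
    tags = as.list(tags),
    annotation_source = as.character(annotation_source)
  )
  validate_corpus(out, schema)
}

#' Validate a corpus tibble
#'
#' Checks id uniqueness, label/task vocabularies, token lengths, and the
#' shape and 0/1 content of every tag matrix.
#'
#' @param corpus A corpus tibble.
#' @param schema Tag schema (defines the expected number of tag columns).
#' @return The corpus with class `sfl_corpus`, or an error naming the first
#'   offending document.
#' @export
validate_corpus <- function(corpus, schema = default_schema()) {
  corpus <- tibble::as_tibble(corpus)
  need <- c("id", "label", "task", "tokens", "tags", "annotation_source")
  if (!all(need %in% names(corpus))) {
    abort(paste0("corpus is missing columns: ",
                 paste(setdiff(need, names(corpus)), collapse = ", ")))
  }
  if (anyDuplicated(corpus$id)) abort("document ids must be unique")
  bad <- setdiff(unique(corpus$label), c("AS", "nonAS", "unknown"))
  if (length(bad)) abort(paste0("unknown label(s): ", paste(bad, collapse = ", ")))
  bad <- setdiff(unique(corpus$task), c("interview", "recounting"))
  if (length(bad)) abort(paste0("unknown task(s): ", paste(bad, collapse = ", ")))
  C <- tag_count(schema)
  for (i in seq_len(nrow(corpus))) {
    toks <- corpus$tokens[[i]]
    if (!is.character(toks) || length(toks) < 1L) {
      abort(sprintf("document '%s': tokens must be a non-empty character vector",
                    corpus$id[i]))
    }
    tg <- corpus$tags[[i]]
    if (!is.null(tg)) {
      if (!is.matrix(tg) || nrow(tg) != length(toks) || ncol(tg) != C) {
        abort(sprintf(
          "document '%s': tag matrix must be %d x %d (got %s)",
          corpus$id[i], length(toks), C,
          if (is.matrix(tg)) paste(dim(tg), collapse = " x ") else "non-matrix"))
      }
      if (!all(tg %in% c(0L, 1L))) {
        abort(sprintf("document '%s': tag matrix entries must be 0/1",
                      corpus$id[i]))
      }
    }
  }
  if (!inherits(corpus, "sfl_corpus")) {
    class(corpus) <- c("sfl_corpus", class(corpus))
  }
  corpus
}

#' Read and write a corpus as JSON-lines
#'
#' One JSON object per line with fields `id`, `label`, `task`,
#' `annotation_source`, `tokens` (array of words) and `tags` (either `null`
#' or an array of per-word arrays of active tag names). `write_corpus()`
#' followed by `read_corpus()` restores all fields; documents keep file
#' order.
#'
#' @param path File path.
#' @param corpus A corpus tibble.
#' @param schema Tag schema used to resolve tag names.
#' @return `read_corpus()`: a corpus tibble (empty file gives an empty,
#'   zero-row corpus). `write_corpus()`: `path`, invisibly.
#' @export
read_corpus <- function(path, schema = default_schema()) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(corpus_tibble(character(), character(), character(), list(),
                         list(), character(), schema = schema))
  }
  C <- tag_count(schema)
  recs <- vector("list", length(lines))
  for (ln in seq_along(lines)) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[ln], simplifyVector = FALSE),
      error = function(e) {
        abort(sprintf("parse error on line %d: %s", ln, conditionMessage(e)))
      })
    for (f in c("id", "label", "task", "tokens")) {
      if (is.null(rec[[f]])) {
        abort(sprintf("parse error on line %d: missing field '%s'", ln, f))
      }
    }
    tokens <- as.character(unlist(rec$tokens))
    tags <- NULL
    if (!is.null(rec$tags)) {
      if (length(rec$tags) != length(tokens)) {
        abort(sprintf(
          "document '%s': tag rows (%d) do not match token count (%d)",
          rec$id, length(rec$tags), length(tokens)))
      }
      tags <- matrix(0L, nrow = length(tokens), ncol = C)
      for (t in seq_along(rec$tags)) {
        active <- as.character(unlist(rec$tags[[t]]))
        if (length(active)) {
          tags[t, tag_index(schema, active) + 1L] <- 1L
        }
      }
    }
    recs[[ln]] <- list(
      id = as.character(rec$id), label = as.character(rec$label),
      task = as.character(rec$task), tokens = tokens, tags = tags,
      annotation_source = if (is.null(rec$annotation_source)) {
        if (is.null(tags)) "none" else "manual"
      } else as.character(rec$annotation_source))
  }
  corpus_tibble(
    id = vapply(recs, `[[`, character(1), "id"),
    label = vapply(recs, `[[`, character(1), "label"),
    task = vapply(recs, `[[`, character(1), "task"),
    tokens = lapply(recs, `[[`, "tokens"),
    tags = lapply(recs, `[[`, "tags"),
    annotation_source = vapply(recs, `[[`, character(1), "annotation_source"),
    schema = schema)
}

#' @rdname read_corpus
#' @export
write_corpus <- function(corpus, path, schema = default_schema()) {
  corpus <- validate_corpus(corpus, schema)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus))) {
    tg <- corpus$tags[[i]]
    tag_field <- if (is.null(tg)) NULL else {
      lapply(seq_len(nrow(tg)), function(t) {
        active <- which(tg[t, ] == 1L) - 1L
        if (length(active)) as.list(tag_name(schema, active)) else list()
      })
    }
    rec <- list(id = corpus$id[i], label = corpus$label[i],
                task = corpus$task[i],
                annotation_source = corpus$annotation_source[i],
                tokens = as.list(corpus$tokens[[i]]))
    rec$tags <- tag_field
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"), con)
  }
  invisible(path)
}

#' Convert documents to and from a CoNLL-style token table
#'
#' The token table has one row per token with columns `doc_id`,
#' `token_index` (1-based), `token`, and `tags`: the `"|"`-joined names of
#' the active tags, or `"_"` when no tag is active.
#'
#' @param corpus A corpus tibble (all documents must carry tag matrices,
#'   or none).
#' @param table A token table as produced by `to_token_table()`.
#' @param meta Optional tibble with columns `id`, `label`, `task`,
#'   `annotation_source` giving per-document metadata; defaults to
#'   `label = "unknown"`, `task = "interview"`.
#' @param schema Tag schema.
#' @return `to_token_table()`: a tibble of token rows. `from_token_table()`:
#'   a corpus tibble.
#' @export
to_token_table <- function(corpus, schema = default_schema()) {
  corpus <- validate_corpus(corpus, schema)
  purrr::map_dfr(seq_len(nrow(corpus)), function(i) {
    toks <- corpus$tokens[[i]]
    tg <- corpus$tags[[i]]
    cells <- if (is.null(tg)) rep("_", length(toks)) else {
      vapply(seq_along(toks), function(t) {
        active <- which(tg[t, ] == 1L) - 1L
        if (length(active)) paste(tag_name(schema, active), collapse = "|")
        else "_"
      }, character(1))
    }
    tibble::tibble(doc_id = corpus$id[i],
                   token_index = seq_along(toks),
                   token = toks, tags = cells)
  })
}

#' @rdname to_token_table
#' @export
from_token_table <- function(table, meta = NULL, schema = default_schema()) {
  table <- tibble::as_tibble(table)
  C <- tag_count(schema)
  ids <- unique(table$doc_id)
  docs <- lapply(ids, function(did) {
    rows <- table[table$doc_id == did, ]
    rows <- rows[order(rows$token_index), ]
    tg <- matrix(0L, nrow = nrow(rows), ncol = C)
    for (t in seq_len(nrow(rows))) {
      cell <- rows$tags[t]
      if (!identical(cell, "_") && nzchar(cell)) {
        nm <- strsplit(cell, "|", fixed = TRUE)[[1]]
        idx <- tryCatch(tag_index(schema, nm), error = function(e) {
          abort(sprintf("document '%s', row %d: %s", did, t,
                        conditionMessage(e)))
        })
        tg[t, idx + 1L] <- 1L
      }
    }
    list(tokens = rows$token, tags = tg)
  })
  if (is.null(meta)) {
    meta <- tibble::tibble(id = ids, label = "unknown", task = "interview",
                           annotation_source = "manual")
  }
  meta <- meta[match(ids, meta$id), ]
  corpus_tibble(id = ids, label = meta$label, task = meta$task,
                tokens = lapply(docs, `[[`, "tokens"),
                tags = lapply(docs, `[[`, "tags"),
                annotation_source = meta$annotation_source,
                schema = schema)
}

#' Per-document tag frequency features
#'
#' The tag-frequency vector of a document is, for each tag, the number of
#' words on which the tag is active divided by the total number of words.
#' Because a tag is binary per word, every frequency lies in `[0, 1]`. Token
#' order is discarded, which is exactly the information reduction the linear
#' classifier operates under.
#'
#' @param corpus A corpus tibble; every document must carry a tag matrix.
#' @param schema Tag schema (provides feature column names).
#' @return A tibble with one row per document: `id`, `label`, `task`,
#'   `n_tokens`, then one numeric column per tag (147 columns, named by tag).
#' @export
tag_frequencies <- function(corpus, schema = default_schema()) {
  corpus <- validate_corpus(corpus, schema)
  miss <- vapply(corpus$tags, is.null, logical(1))
  if (any(miss)) {
    abort(paste0("documents without tag matrices: ",
                 paste(head(corpus$id[miss], 5), collapse = ", ")))
  }
  freq <- t(vapply(corpus$tags, function(tg) colMeans(tg),
                   numeric(tag_count(schema))))
  colnames(freq) <- schema$name[order(schema$index)]
  dplyr::bind_cols(
    tibble::tibble(id = corpus$id, label = corpus$label, task = corpus$task,
                   n_tokens = vapply(corpus$tokens, length, integer(1))),
    tibble::as_tibble(freq))
}
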