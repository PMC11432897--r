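#' Configure the automatic tag annotator
#'
#' The annotator casts tag annotation as multi-label sequence labeling: a
#' single-layer bidirectional LSTM over learned word embeddings, with a
#' per-token linear layer feeding 147 independent sigmoids. Defaults are the
#' standard training recipe used throughout the package: 300-dimensional
#' embeddings and hidden states, 50 epochs, batch size 32, Adam at learning
#' rate 0.001.
#'
#' @param embedding_dim Word-embedding dimensionality `d`.
#' @param hidden_dim LSTM hidden size per direction.
#' @param epochs Training epochs (the model trains for exactly this many;
#'   there is no early stopping).
#' @param batch_size Minibatch size.
#' @param learning_rate Adam learning rate.
#' @param threshold Decision threshold `tau`; a tag is emitted when its
#'   sigmoid score strictly exceeds `tau`.
#' @param unk_min_count Words with training-fold frequency at or below this
#'   count are mapped to the UNK embedding (0 disables).
#' @param seed Integer seed controlling initialisation and epoch shuffling.
#' @return A list of class `sfl_annotator_config`.
#' @export
annotator_config <- function(embedding_dim = 300, hidden_dim = 300,
                             epochs = 50, batch_size = 32,
                             learning_rate = 0.001, threshold = 0.5,
                             unk_min_count = 0, seed = 1L) {
  cfg <- list(embedding_dim = as.integer(embedding_dim),
              hidden_dim = as.integer(hidden_dim),
              epochs = as.integer(epochs),
              batch_size = as.integer(batch_size),
              learning_rate = learning_rate, threshold = threshold,
              unk_min_count = as.integer(unk_min_count),
              seed = as.integer(seed))
  if (any(unlist(cfg[c("embedding_dim", "hidden_dim", "epochs",
                       "batch_size")]) <= 0)) {
    abort("annotator dimensions, epochs and batch size must be positive")
  }
  if (cfg$threshold <= 0 || cfg$threshold >= 1) {
    abort("threshold must lie in (0, 1)")
  }
  class(cfg) <- "sfl_annotator_config"
  cfg
}

#' Train the Bi-LSTM tag annotator
#'
#' Trains on per-token, per-tag binary cross-entropy over sigmoid outputs
#' for exactly `config$epochs` epochs. The vocabulary is built from the
#' training documents only. Given a fixed seed, training is deterministic.
#'
#' @param corpus Training corpus; every document must carry a (manual) tag
#'   matrix.
#' @param config An [annotator_config()].
#' @param schema Tag schema.
#' @return An object of class `sfl_annotator`: the trained parameters,
#'   vocabulary, config snapshot, and per-epoch loss history.
#' @export
train_annotator <- function(corpus, config = annotator_config(),
                            schema = default_schema()) {
  stopifnot(inherits(config, "sfl_annotator_config"))
  corpus <- validate_corpus(corpus, schema)
  if (nrow(corpus) == 0L) abort("training corpus is empty")
  miss <- vapply(corpus$tags, is.null, logical(1))
  if (any(miss)) {
    abort(paste0("training documents lack tag matrices: ",
                 paste(head(corpus$id[miss], 5), collapse = ", ")))
  }
  C <- tag_count(schema)
  vocab <- build_vocab(corpus$tokens, config$unk_min_count)
  docs <- lapply(seq_len(nrow(corpus)), function(i) {
    list(words = words_to_idx(corpus$tokens[[i]], vocab),
         tags = empty_tags(),
         target = matrix(as.numeric(corpus$tags[[i]]),
                         nrow = nrow(corpus$tags[[i]]), ncol = C))
  })
  fit <- withr::with_seed(config$seed, {
    params <- init_net("tagger", config$embedding_dim, config$hidden_dim,
                       V = length(vocab), C = C)
    orders <- shuffle_orders(config$epochs, nrow(corpus))
    cpp_bilstm_train(docs, params,
                     list(epochs = config$epochs,
                          batch_size = config$batch_size,
                          learning_rate = config$learning_rate),
                     orders, "tagger")
  })
  structure(list(params = fit$params, vocab = vocab, config = config,
                 loss = as.numeric(fit$loss),
                 schema_version = attr(schema, "schema_version")),
            class = "sfl_annotator")
}

#' Automatically annotate a token sequence
#'
#' Runs the trained annotator over a word sequence and thresholds the
#' per-tag sigmoid scores: cell `(l, c)` is 1 iff the score strictly exceeds
#' the decision threshold. Unknown words map to the UNK embedding.
#'
#' @param model A trained [train_annotator()] model.
#' @param tokens Character vector of words, length `L >= 1`.
#' @return An `L x 147` binary integer matrix.
#' @export
annotate <- function(model, tokens) {
  stopifnot(inherits(model, "sfl_annotator"))
  if (!is.character(tokens) || length(tokens) < 1L) {
    abort("tokens must be a non-empty character vector")
  }
  probs <- cpp_tagger_predict(words_to_idx(tokens, model$vocab), model$params)
  matrix((probs > model$config$threshold) + 0L, nrow = nrow(probs))
}

#' Annotate every document of a corpus
#'
#' Replaces each document's tag matrix by the annotator's output and marks
#' `annotation_source = "auto"`.
#'
#' @param model A trained annotator.
#' @param corpus A corpus tibble.
#' @return The corpus with automatic tags.
#' @export
annotate_corpus <- function(model, corpus) {
  corpus$tags <- lapply(corpus$tokens, function(toks) annotate(model, toks))
  corpus$annotation_source <- "auto"
  corpus
}

#' Micro-averaged annotation metrics
#'
#' Precision, recall and F1 pooled over all (word, tag) cells of the
#' prediction and gold matrices, with the 0-when-empty convention for
#' undefined ratios.
#'
#' @param pred,gold Binary matrices of identical shape (or lists of such
#'   matrices, which are pooled — the micro property).
#' @return A one-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
annotation_metrics <- function(pred, gold) {
  if (is.matrix(pred)) pred <- list(pred)
  if (is.matrix(gold)) gold <- list(gold)
  if (length(pred) != length(gold)) abort("pred and gold lengths differ")
  tp <- fp <- fn <- 0
  for (i in seq_along(pred)) {
    p <- pred[[i]]; g <- gold[[i]]
    if (!all(dim(p) == dim(g))) {
      abort(sprintf("shape mismatch in element %d: %s vs %s", i,
                    paste(dim(p), collapse = "x"),
                    paste(dim(g), collapse = "x")))
    }
    tp <- tp + sum(p == 1 & g == 1)
    fp <- fp + sum(p == 1 & g == 0)
    fn <- fn + sum(p == 0 & g == 1)
  }
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  tibble::tibble(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1)
}
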