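#' Configure a diagnostic classifier
#'
#' Four model variants differentiate AS from non-AS documents:
#'
#' * `tag_linear` — L2-regularised logistic regression on the 147
#'   tag-frequency features (token order discarded). Transparent: its
#'   coefficients are exposed via [tidy()].
#' * `tag_dnn` — a Bi-LSTM over per-word tag embeddings: each word is
#'   represented by the sum of the embedding vectors of its active tags.
#' * `text_dnn` — the same Bi-LSTM over learned word embeddings.
#' * `text_tag_dnn` — the Bi-LSTM over the per-timestep concatenation of tag
#'   and word embeddings (input width `2d`).
#'
#' All DNN variants feed the Bi-LSTM "last state" (forward state at the last
#' token joined with backward state at the first token) into a fully
#' connected layer producing a single AS-probability sigmoid. Defaults are
#' the shared training recipe: `d = 300`, hidden 300, 50 epochs, batch 32,
#' Adam at 0.001. AS is the positive class throughout; the decision
#' threshold is 0.5 with no calibration.
#'
#' @param variant One of `"tag_linear"`, `"tag_dnn"`, `"text_dnn"`,
#'   `"text_tag_dnn"`.
#' @param embedding_dim,hidden_dim,epochs,batch_size,learning_rate DNN
#'   hyperparameters (ignored by `tag_linear`).
#' @param threshold Probability threshold for the AS label.
#' @param l2_penalty Ridge penalty for `tag_linear`. The default is a tiny
#'   value (1e-4) so the fit is essentially unpenalised maximum likelihood —
#'   the plain logistic-regression model — with just enough shrinkage to keep
#'   the separable high-dimensional case numerically identified.
#' @param seed Integer seed controlling initialisation and shuffling.
#' @return A list of class `sfl_classifier_config`.
#' @export
classifier_config <- function(variant = c("tag_linear", "tag_dnn", "text_dnn",
                                          "text_tag_dnn"),
                              embedding_dim = 300, hidden_dim = 300,
                              epochs = 50, batch_size = 32,
                              learning_rate = 0.001, threshold = 0.5,
                              l2_penalty = 1e-4, seed = 1L) {
  variant <- match.arg(variant)
  cfg <- list(variant = variant, embedding_dim = as.integer(embedding_dim),
              hidden_dim = as.integer(hidden_dim), epochs = as.integer(epochs),
              batch_size = as.integer(batch_size),
              learning_rate = learning_rate, threshold = threshold,
              l2_penalty = l2_penalty, seed = as.integer(seed))
  if (any(unlist(cfg[c("embedding_dim", "hidden_dim", "epochs",
                       "batch_size")]) <= 0)) {
    abort("classifier dimensions, epochs and batch size must be positive")
  }
  class(cfg) <- "sfl_classifier_config"
  cfg
}

variant_mode <- function(variant) {
  switch(variant, tag_dnn = "clf_tag", text_dnn = "clf_text",
         text_tag_dnn = "clf_concat",
         abort(paste0("no DNN mode for variant ", variant)))
}

needs_tags <- function(variant) variant %in% c("tag_linear", "tag_dnn",
                                               "text_tag_dnn")
needs_text <- function(variant) variant %in% c("text_dnn", "text_tag_dnn")

#' Sum-of-embeddings tag representation
#'
#' Each word's tag embedding is the sum of the embedding-table rows of its
#' active tags; a word with no active tags maps to the zero vector.
#'
#' @param tag_matrix Binary `L x C` matrix.
#' @param tag_table `C x d` embedding table.
#' @return An `L x d` real matrix.
#' @export
embed_tags <- function(tag_matrix, tag_table) {
  if (!is.matrix(tag_matrix) || !is.matrix(tag_table) ||
      ncol(tag_matrix) != nrow(tag_table)) {
    abort(sprintf("shape mismatch: tag matrix has %s columns, table %s rows",
                  ncol(tag_matrix), nrow(tag_table)))
  }
  tag_matrix %*% tag_table
}

#' Train a diagnostic classifier
#'
#' @param corpus Training corpus; every document must be labeled `AS` or
#'   `nonAS`, with tag matrices for tag-using variants and tokens for
#'   text-using variants. Both classes must be present.
#' @param config A [classifier_config()].
#' @param schema Tag schema.
#' @return An object of class `sfl_classifier` holding the fitted
#'   parameters (ridge-logistic coefficients for `tag_linear`; embedding
#'   tables plus recurrent and output weights otherwise), the vocabulary
#'   for text variants, and a config + seed snapshot.
#' @export
train_classifier <- function(corpus, config, schema = default_schema()) {
  stopifnot(inherits(config, "sfl_classifier_config"))
  corpus <- validate_corpus(corpus, schema)
  if (nrow(corpus) == 0L) abort("training corpus is empty")
  if (!all(corpus$label %in% c("AS", "nonAS"))) {
    abort("all training documents must be labeled AS or nonAS")
  }
  if (length(unique(corpus$label)) < 2L) {
    abort("training labels contain a single class; both AS and nonAS required")
  }
  if (needs_tags(config$variant)) {
    miss <- vapply(corpus$tags, is.null, logical(1))
    if (any(miss)) {
      abort(paste0("variant ", config$variant,
                   " requires tag matrices; missing for: ",
                   paste(head(corpus$id[miss], 5), collapse = ", ")))
    }
  }
  y <- as.numeric(corpus$label == "AS")

  if (config$variant == "tag_linear") {
    feats <- tag_frequencies(corpus, schema)
    x <- as.matrix(feats[, schema$name[order(schema$index)]])
    fit <- suppressWarnings(
      glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                     lambda = config$l2_penalty, standardize = FALSE))
    beta <- as.numeric(fit$beta[, 1])
    names(beta) <- rownames(fit$beta)
    model <- list(variant = config$variant, intercept = as.numeric(fit$a0),
                  coefficients = beta, config = config,
                  schema_version = attr(schema, "schema_version"))
    return(structure(model, class = "sfl_classifier"))
  }

  mode <- variant_mode(config$variant)
  vocab <- if (needs_text(config$variant)) build_vocab(corpus$tokens) else NULL
  C <- tag_count(schema)
  docs <- lapply(seq_len(nrow(corpus)), function(i) {
    list(words = if (needs_text(config$variant))
      words_to_idx(corpus$tokens[[i]], vocab) else integer(0),
      tags = if (needs_tags(config$variant))
        matrix(as.numeric(corpus$tags[[i]]),
               nrow = nrow(corpus$tags[[i]]), ncol = C) else empty_tags(),
      y = y[i])
  })
  fit <- withr::with_seed(config$seed, {
    params <- init_net(mode, config$embedding_dim, config$hidden_dim,
                       V = if (is.null(vocab)) 0L else length(vocab), C = C)
    orders <- shuffle_orders(config$epochs, nrow(corpus))
    cpp_bilstm_train(docs, params,
                     list(epochs = config$epochs,
                          batch_size = config$batch_size,
                          learning_rate = config$learning_rate),
                     orders, mode)
  })
  structure(list(variant = config$variant, params = fit$params, vocab = vocab,
                 config = config, loss = as.numeric(fit$loss),
                 schema_version = attr(schema, "schema_version")),
            class = "sfl_classifier")
}

#' Predict AS probabilities for documents
#'
#' A pure function of (model, document): repeated calls return identical
#' values. The predicted label is `AS` when the probability is at least the
#' configured threshold (default 0.5).
#'
#' @param model A trained [train_classifier()] model.
#' @param corpus Corpus tibble of documents to score; tag-using variants
#'   require tag matrices (use [annotate_corpus()] for automatic tags).
#' @param schema Tag schema.
#' @return A tibble with columns `id`, `p_AS`, `label`.
#' @export
predict_proba <- function(model, corpus, schema = default_schema()) {
  stopifnot(inherits(model, "sfl_classifier"))
  corpus <- validate_corpus(corpus, schema)
  if (needs_tags(model$variant)) {
    miss <- vapply(corpus$tags, is.null, logical(1))
    if (any(miss)) {
      abort(paste0("variant ", model$variant,
                   " requires tag matrices; missing for: ",
                   paste(head(corpus$id[miss], 5), collapse = ", ")))
    }
  }
  C <- tag_count(schema)
  p <- if (model$variant == "tag_linear") {
    feats <- tag_frequencies(corpus, schema)
    x <- as.matrix(feats[, names(model$coefficients)])
    as.numeric(stats::plogis(model$intercept +
                               x %*% model$coefficients))
  } else {
    mode <- variant_mode(model$variant)
    vapply(seq_len(nrow(corpus)), function(i) {
      doc <- list(
        words = if (needs_text(model$variant))
          words_to_idx(corpus$tokens[[i]], model$vocab) else integer(0),
        tags = if (needs_tags(model$variant))
          matrix(as.numeric(corpus$tags[[i]]),
                 nrow = nrow(corpus$tags[[i]]), ncol = C) else empty_tags())
      cpp_clf_predict(doc, model$params, mode)
    }, numeric(1))
  }
  tibble::tibble(id = corpus$id, p_AS = p,
                 label = ifelse(p >= model$config$threshold, "AS", "nonAS"))
}

#' @describeIn train_classifier Broom-style coefficient table. For
#'   `tag_linear`, one row per model term (intercept plus each tag) with the
#'   fitted log-odds `estimate`; for DNN variants, one row per parameter
#'   block with its dimensions and Frobenius norm.
#' @param x A fitted `sfl_classifier`.
#' @param ... Unused.
#' @export
tidy.sfl_classifier <- function(x, ...) {
  if (x$variant == "tag_linear") {
    tibble::tibble(term = c("(Intercept)", names(x$coefficients)),
                   estimate = c(x$intercept, unname(x$coefficients)))
  } else {
    blocks <- x$params[vapply(x$params, function(m) length(m) > 0, logical(1))]
    tibble::tibble(term = names(blocks),
                   rows = vapply(blocks, nrow, integer(1)),
                   cols = vapply(blocks, ncol, integer(1)),
                   norm = vapply(blocks, function(m) sqrt(sum(m^2)),
                                 numeric(1)))
  }
}

#' @describeIn train_classifier One-row model summary: variant, parameter
#'   count, epochs trained and final training loss (NA for `tag_linear`).
#' @export
glance.sfl_classifier <- function(x, ...) {
  n_par <- if (x$variant == "tag_linear") length(x$coefficients) + 1L else {
    sum(vapply(x$params, length, integer(1)))
  }
  tibble::tibble(variant = x$variant, n_parameters = n_par,
                 epochs = if (is.null(x$loss)) NA_integer_ else length(x$loss),
                 final_loss = if (is.null(x$loss)) NA_real_ else
                   x$loss[length(x$loss)],
                 seed = x$config$seed)
}

#' @exportS3Method base::print
print.sfl_classifier <- function(x, ...) {
  cat("<sfl_classifier>", x$variant, "\n")
  if (x$variant == "tag_linear") {
    nz <- sum(abs(x$coefficients) > 1e-8)
    cat("  ridge logistic regression on 147 tag frequencies;",
        nz, "non-zero coefficients\n")
  } else {
    cat("  Bi-LSTM (d =", x$config$embedding_dim, ", hidden =",
        x$config$hidden_dim, "), trained", length(x$loss), "epochs\n")
  }
  invisible(x)
}
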