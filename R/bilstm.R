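# Internal helpers shared by the tagger and the DNN classifiers: vocabulary
# construction, parameter initialisation, and epoch shuffling. All randomness
# is drawn inside withr::with_seed() by the callers, so training runs are
# reproducible from the recorded seed.

# Vocabulary: UNK sentinel first, then words by decreasing training-fold
# frequency (alphabetical within ties) for a deterministic index map.
build_vocab <- function(token_lists, unk_min_count = 0L) {
  counts <- table(unlist(token_lists))
  words <- names(counts)
  if (unk_min_count > 0L) words <- words[counts[words] > unk_min_count]
  ord <- order(-as.integer(counts[words]), words)
  c("<unk>", words[ord])
}

# 0-based indices for the C++ engine; OOV -> 0 (the UNK row).
words_to_idx <- function(tokens, vocab) {
  idx <- match(tokens, vocab)
  idx[is.na(idx)] <- 1L
  as.integer(idx - 1L)
}

rmat <- function(nr, nc, scale = 0.08) {
  matrix(runif(nr * nc, -scale, scale), nrow = nr, ncol = nc)
}

# Parameter initialisation. Embeddings and weights are uniform(-0.08, 0.08);
# forget-gate biases start at +1 so early training retains state.
init_net <- function(mode, d, H, V = 0L, C = 147L, K = 1L) {
  Din <- switch(mode, tagger = d, clf_tag = d, clf_text = d,
                clf_concat = 2L * d)
  lstm_bias <- function() {
    b <- matrix(0, 4 * H, 1)
    b[(H + 1):(2 * H), 1] <- 1
    b
  }
  list(
    Wword = if (mode %in% c("tagger", "clf_text", "clf_concat"))
      rmat(V, d) else matrix(0, 0, 0),
    Wtag = if (mode %in% c("clf_tag", "clf_concat"))
      rmat(C, d) else matrix(0, 0, 0),
    Wxf = rmat(4 * H, Din, 1 / sqrt(Din)), Whf = rmat(4 * H, H, 1 / sqrt(H)),
    bf = lstm_bias(),
    Wxb = rmat(4 * H, Din, 1 / sqrt(Din)), Whb = rmat(4 * H, H, 1 / sqrt(H)),
    bb = lstm_bias(),
    Wout = rmat(if (mode == "tagger") C else K, 2 * H, 0.08),
    bout = matrix(0, if (mode == "tagger") C else K, 1)
  )
}

shuffle_orders <- function(epochs, n) {
  t(vapply(seq_len(epochs), function(e) sample.int(n) - 1L, integer(n)))
}

empty_tags <- function() matrix(0, 0, 0)
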