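# Shared fixtures: all corpora are generated in code at test time.

schema <- default_schema()

# Small synthetic corpus for IO and protocol tests.
tiny_corpus <- function(n_per = 4, length_mean = 30, seed = 7, ...) {
  generate_corpus(generator_config(n_AS = n_per, n_nonAS = n_per,
                                   length_mean = length_mean, seed = seed,
                                   ...))
}

# Hand-built two-document corpus with known tags for exact-value tests.
handmade_corpus <- function() {
  C <- tag_count(schema)
  t1 <- matrix(0L, 4, C)
  t1[1, tag_index(schema, "modality.ability") + 1] <- 1L
  t1[2, tag_index(schema, "modality.ability") + 1] <- 1L
  t1[2, tag_index(schema, "filler.maa") + 1] <- 1L
  t2 <- matrix(0L, 3, C)
  corpus_tibble(id = c("d1", "d2"), label = c("AS", "nonAS"),
                task = "interview",
                tokens = list(c("a", "b", "c", "d"), c("x", "y", "z")),
                tags = list(t1, t2))
}

# Fast, deliberately small network settings for DNN unit tests.
dnn_test_config <- function(variant, seed = 3, epochs = 4) {
  classifier_config(variant, embedding_dim = 8, hidden_dim = 8,
                    epochs = epochs, batch_size = 4, learning_rate = 0.01,
                    seed = seed)
}

ann_test_config <- function(seed = 3, epochs = 4, ...) {
  annotator_config(embedding_dim = 8, hidden_dim = 8, epochs = epochs,
                   batch_size = 4, learning_rate = 0.01, seed = seed, ...)
}

# Linearly separable corpus: one tag active on 90% of AS words, 10% of
# non-AS words.
separable_corpus <- function(n_per = 6, L = 20, seed = 11) {
  C <- tag_count(schema)
  idx <- tag_index(schema, "modality.ability") + 1L
  withr::with_seed(seed, {
    mk <- function(i, lab, frac) {
      tg <- matrix(0L, L, C)
      tg[seq_len(round(frac * L)), idx] <- 1L
      list(id = paste0(lab, i), label = lab,
           tokens = sample(letters, L, TRUE), tags = tg)
    }
    docs <- c(lapply(seq_len(n_per), mk, lab = "AS", frac = 0.9),
              lapply(seq_len(n_per), mk, lab = "nonAS", frac = 0.1))
    corpus_tibble(id = vapply(docs, `[[`, character(1), "id"),
                  label = vapply(docs, `[[`, character(1), "label"),
                  task = "interview",
                  tokens = lapply(docs, `[[`, "tokens"),
                  tags = lapply(docs, `[[`, "tags"))
  })
}
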