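test_that("annotator training is deterministic and predictions are pure", {
  corp <- tiny_corpus(n_per = 3, length_mean = 15)
  a <- train_annotator(corp, ann_test_config(seed = 5))
  b <- train_annotator(corp, ann_test_config(seed = 5))
  probe <- c("w00001", "w00002", "zzz-unseen")
  expect_identical(annotate(a, probe), annotate(b, probe))
  expect_identical(annotate(a, probe), annotate(a, probe))
})

test_that("annotation output has shape L x 147 and handles unknown words", {
  corp <- tiny_corpus(n_per = 2, length_mean = 10)
  ann <- train_annotator(corp, ann_test_config())
  for (L in c(1, 7)) {
    m <- annotate(ann, rep("never-seen-word", L))
    expect_equal(dim(m), c(L, 147L))
    expect_true(all(m %in% c(0L, 1L)))
  }
  expect_error(annotate(ann, character()), "non-empty")
})

test_that("scores exactly at the threshold do not fire (strict inequality)", {
  # all-zero parameters give sigmoid(0) = 0.5 at every cell
  zero <- init_net("tagger", 4L, 4L, V = 1L, C = 147L)
  zero <- lapply(zero, function(m) m * 0)
  model <- structure(list(params = zero, vocab = "<unk>",
                          config = annotator_config(embedding_dim = 4,
                                                    hidden_dim = 4,
                                                    threshold = 0.5),
                          loss = NA_real_, schema_version = "v1"),
                     class = "sfl_annotator")
  m <- annotate(model, c("a", "b"))
  expect_true(all(m == 0L))
})

test_that("training on an all-negative corpus predicts no tags", {
  corp <- tiny_corpus(n_per = 3, length_mean = 12)
  corp$tags <- lapply(corp$tags, function(tg) tg * 0L)
  ann <- train_annotator(corp, ann_test_config(epochs = 10))
  m <- annotate(ann, corp$tokens[[1]])
  expect_true(all(m == 0L))
})

test_that("training requires non-empty, fully tagged corpora", {
  corp <- tiny_corpus(n_per = 2, length_mean = 8)
  expect_error(train_annotator(corp[0, ], ann_test_config()), "empty")
  corp$tags[2] <- list(NULL)
  corp$annotation_source[2] <- "none"
  expect_error(train_annotator(corp, ann_test_config()), corp$id[2])
})

test_that("micro metrics match closed-form counts and conventions", {
  # TP=8, FP=1, FN=2
  pred <- matrix(0L, 4, 147); gold <- matrix(0L, 4, 147)
  gold[1, 1:10] <- 1L
  pred[1, 1:8] <- 1L   # 8 TP, 2 FN
  pred[2, 5] <- 1L     # 1 FP
  m <- annotation_metrics(pred, gold)
  expect_equal(m$precision, 8 / 9, tolerance = 1e-12)
  expect_equal(m$recall, 0.8)
  expect_equal(round(m$f1, 4), 0.8421)

  ident <- annotation_metrics(gold, gold)
  expect_equal(c(ident$precision, ident$recall, ident$f1), c(1, 1, 1))

  zero <- annotation_metrics(matrix(0L, 4, 147), gold)
  expect_equal(c(zero$precision, zero$recall, zero$f1), c(0, 0, 0))

  expect_error(annotation_metrics(pred[1:2, ], gold), "shape")
})

test_that("metrics pool over documents (micro property) and obey the harmonic identity", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      p1 <- matrix(rbinom(2 * 147, 1, 0.2), ncol = 147)
      g1 <- matrix(rbinom(2 * 147, 1, 0.2), ncol = 147)
      p2 <- matrix(rbinom(3 * 147, 1, 0.3), ncol = 147)
      g2 <- matrix(rbinom(3 * 147, 1, 0.3), ncol = 147)
      pooled <- annotation_metrics(list(p1, p2), list(g1, g2))
      stacked <- annotation_metrics(rbind(p1, p2), rbind(g1, g2))
      expect_equal(pooled, stacked)
      # F1 * (P + R) = 2 * P * R
      expect_equal(pooled$f1 * (pooled$precision + pooled$recall),
                   2 * pooled$precision * pooled$recall, tolerance = 1e-12)
    }
  })
})
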