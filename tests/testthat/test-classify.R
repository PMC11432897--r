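test_that("tag embeddings are sums of active-tag rows", {
  table <- matrix(seq_len(147 * 3) / 100, nrow = 147, ncol = 3)
  tm <- matrix(0L, 4, 147)
  tm[2, 5] <- 1L
  tm[3, c(5, 9)] <- 1L
  e <- embed_tags(tm, table)
  expect_equal(e[1, ], c(0, 0, 0))               # empty sum
  expect_equal(e[2, ], table[5, ])               # singleton
  expect_equal(e[3, ], table[5, ] + table[9, ])  # elementwise sum
  expect_error(embed_tags(tm[, 1:10], table), "shape")
})

test_that("separable tag frequencies yield perfect training fit and a positive coefficient", {
  corp <- separable_corpus()
  clf <- train_classifier(corp, classifier_config("tag_linear"))
  pp <- predict_proba(clf, corp)
  expect_equal(pp$label, corp$label)
  co <- tidy(clf)
  expect_gt(co$estimate[co$term == "modality.ability"], 0)
})

test_that("tag_linear probability at the zero frequency vector is sigmoid(intercept)", {
  corp <- separable_corpus()
  clf <- train_classifier(corp, classifier_config("tag_linear"))
  zero <- corpus_tibble(id = "z", label = "unknown", task = "interview",
                        tokens = list(c("a", "b")),
                        tags = list(matrix(0L, 2, 147)))
  expect_equal(predict_proba(clf, zero)$p_AS, stats::plogis(clf$intercept),
               tolerance = 1e-10)
})

test_that("tag_linear is invariant to token order", {
  corp <- tiny_corpus(n_per = 3, length_mean = 20)
  clf <- train_classifier(corp, classifier_config("tag_linear"))
  p1 <- predict_proba(clf, corp[1, ])$p_AS
  perm <- withr::with_seed(3, sample(length(corp$tokens[[1]])))
  corp$tokens[[1]] <- corp$tokens[[1]][perm]
  corp$tags[[1]] <- corp$tags[[1]][perm, , drop = FALSE]
  expect_equal(predict_proba(clf, corp[1, ])$p_AS, p1, tolerance = 1e-12)
})

test_that("DNN predictions are sensitive to token order (unlike tag_linear)", {
  corp <- tiny_corpus(n_per = 3, length_mean = 25)
  clf <- train_classifier(corp, dnn_test_config("tag_dnn", epochs = 6))
  doc <- corp[1, ]
  p1 <- predict_proba(clf, doc)$p_AS
  L <- length(doc$tokens[[1]])
  doc$tokens[[1]] <- rev(doc$tokens[[1]])
  doc$tags[[1]] <- doc$tags[[1]][L:1, , drop = FALSE]
  p2 <- predict_proba(clf, doc)$p_AS
  expect_false(isTRUE(all.equal(p1, p2, tolerance = 1e-12)))
})

test_that("DNN training is seed-deterministic and prediction is pure", {
  corp <- tiny_corpus(n_per = 3, length_mean = 12)
  for (v in c("tag_dnn", "text_dnn", "text_tag_dnn")) {
    a <- train_classifier(corp, dnn_test_config(v, seed = 6))
    b <- train_classifier(corp, dnn_test_config(v, seed = 6))
    expect_identical(a$params, b$params)
    pa <- predict_proba(a, corp)$p_AS
    expect_identical(pa, predict_proba(a, corp)$p_AS)
    expect_true(all(pa >= 0 & pa <= 1))
  }
})

test_that("the combined model degenerates to each single-input model when the other table is zeroed", {
  corp <- tiny_corpus(n_per = 3, length_mean = 12)
  both <- train_classifier(corp, dnn_test_config("text_tag_dnn", seed = 9))
  d <- both$config$embedding_dim

  # zero word table -> equal to a tag-only model built from the tag blocks
  z1 <- both
  z1$params$Wword <- z1$params$Wword * 0
  tag_only <- both
  tag_only$variant <- "tag_dnn"
  tag_only$params$Wword <- matrix(0, 0, 0)
  tag_only$params$Wxf <- both$params$Wxf[, 1:d, drop = FALSE]
  tag_only$params$Wxb <- both$params$Wxb[, 1:d, drop = FALSE]
  expect_equal(predict_proba(z1, corp)$p_AS, predict_proba(tag_only, corp)$p_AS,
               tolerance = 1e-12)

  # zero tag table -> equal to a text-only model built from the word blocks
  z2 <- both
  z2$params$Wtag <- z2$params$Wtag * 0
  text_only <- both
  text_only$variant <- "text_dnn"
  text_only$params$Wtag <- matrix(0, 0, 0)
  text_only$params$Wxf <- both$params$Wxf[, (d + 1):(2 * d), drop = FALSE]
  text_only$params$Wxb <- both$params$Wxb[, (d + 1):(2 * d), drop = FALSE]
  expect_equal(predict_proba(z2, corp)$p_AS, predict_proba(text_only, corp)$p_AS,
               tolerance = 1e-12)
})

test_that("training rejects invalid inputs", {
  corp <- tiny_corpus(n_per = 3, length_mean = 10)
  single <- corp[corp$label == "AS", ]
  expect_error(train_classifier(single, classifier_config("tag_linear")),
               "single class")
  corp$tags[1] <- list(NULL)
  corp$annotation_source[1] <- "none"
  expect_error(train_classifier(corp, classifier_config("tag_dnn")),
               "requires tag matrices")
  expect_error(predict_proba(train_classifier(tiny_corpus(3, 10, seed = 2),
                                              dnn_test_config("tag_dnn")),
                             corp), "requires tag matrices")
})

test_that("tidy and glance summarise fitted classifiers", {
  corp <- tiny_corpus(n_per = 3, length_mean = 10)
  lin <- train_classifier(corp, classifier_config("tag_linear"))
  td <- tidy(lin)
  expect_equal(nrow(td), 148L)  # intercept + 147 tags
  expect_true("(Intercept)" %in% td$term)
  gl <- glance(lin)
  expect_equal(gl$variant, "tag_linear")

  dnn <- train_classifier(corp, dnn_test_config("tag_dnn"))
  expect_true(all(c("term", "rows", "cols") %in% names(tidy(dnn))))
  expect_equal(glance(dnn)$epochs, dnn$config$epochs)
})
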