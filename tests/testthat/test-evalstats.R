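fold_tbl <- function(y, p) {
  tibble::tibble(doc_id = paste0("d", seq_along(y)), y_true = y,
                 p_manual = p, p_auto = NA_real_, fold_seed = seq_along(y))
}

test_that("confusion metrics match closed-form arithmetic", {
  # tp=3, fp=1, fn=2, tn=4
  y <- c(rep("AS", 5), rep("nonAS", 5))
  p <- c(0.9, 0.8, 0.7, 0.2, 0.1, 0.6, 0.4, 0.3, 0.2, 0.1)
  m <- confusion_metrics(fold_tbl(y, p), "manual")
  expect_equal(c(m$tp, m$fp, m$fn, m$tn), c(3, 1, 2, 4))
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$precision, 0.75)
  expect_equal(m$sensitivity, 0.6)
  expect_equal(m$specificity, 0.8)
})

test_that("perfect predictions give unit metrics and AUC", {
  y <- c("AS", "AS", "nonAS", "nonAS")
  m <- confusion_metrics(fold_tbl(y, c(0.9, 0.8, 0.1, 0.2)), "manual")
  expect_equal(c(m$accuracy, m$precision, m$sensitivity, m$specificity,
                 m$auc), rep(1, 5))
})

test_that("tied scores contribute one half to the AUC (midranks)", {
  expect_equal(auc_wmw(c(0.6, 0.6), c(TRUE, FALSE)), 0.5)
  expect_true(is.na(auc_wmw(c(0.3, 0.6), c(TRUE, TRUE))))
})

test_that("rank-based AUC equals brute-force all-pairs comparison", {
  brute_auc <- function(s, pos) {
    sp <- s[pos]; sn <- s[!pos]
    tot <- 0
    for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(sp) * length(sn))
  }
  withr::with_seed(17, {
    for (rep in 1:10) {
      n <- sample(5:50, 1)
      s <- round(runif(n), 2)  # rounding forces ties
      pos <- runif(n) > 0.5
      if (!any(pos) || all(pos)) next
      expect_equal(auc_wmw(s, pos), brute_auc(s, pos), tolerance = 1e-12)
    }
  })
})

test_that("Wald intervals reproduce printed two-decimal endpoints", {
  ci <- wald_ci(0.78, 135)
  expect_equal(round(c(ci$lower, ci$upper), 2), c(0.71, 0.85))
  ci <- wald_ci(0.80, 135)
  expect_equal(round(c(ci$lower, ci$upper), 2), c(0.73, 0.87))
  ci <- wald_ci(0, 50)
  expect_equal(c(ci$lower, ci$upper), c(0, 0))
  expect_error(wald_ci(0.5, 0), "positive")
})

test_that("Wald interval width scales exactly as 1/sqrt(n)", {
  for (p in c(0.3, 0.64, 0.8)) {
    w1 <- with(wald_ci(p, 30), upper - lower)
    w4 <- with(wald_ci(p, 120), upper - lower)
    expect_equal(w4, w1 / 2, tolerance = 1e-12)
  }
})

test_that("McNemar chi-square forms match their closed forms and tails", {
  # printed statistic 5.50 with 1 df has upper-tail p 0.02 at two decimals
  expect_equal(round(pchisq(5.50, 1, lower.tail = FALSE), 2), 0.02)

  r <- mcnemar_counts(7, 7, "chi2")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  r <- mcnemar_counts(7, 7, "chi2_corrected")
  expect_equal(r$statistic, 0)

  r <- mcnemar_counts(10, 2, "chi2_corrected")
  expect_equal(r$statistic, 49 / 12, tolerance = 1e-12)
  # independent numerical upper-tail oracle for the chi-square(1) density
  oracle <- stats::integrate(function(x) stats::dchisq(x, 1), 49 / 12,
                             Inf)$value
  expect_equal(r$p_value, oracle, tolerance = 1e-4)
  expect_equal(round(r$p_value, 3), 0.043)

  r0 <- mcnemar_counts(0, 0)
  expect_equal(c(r0$statistic, r0$p_value), c(0, 1))
})

test_that("exact McNemar equals brute-force tail enumeration for b+c <= 12", {
  enum_p <- function(b, c) {
    n <- b + c
    if (n == 0) return(1)
    lo <- min(b, c)
    ks <- 0:n
    min(1, sum(stats::dbinom(ks[ks <= lo], n, 0.5)) +
          sum(stats::dbinom(ks[ks >= n - lo], n, 0.5)))
  }
  for (n in 0:12) {
    for (b in 0:n) {
      got <- mcnemar_counts(b, n - b, "exact")$p_value
      expect_equal(got, enum_p(b, n - b), tolerance = 1e-12,
                   info = sprintf("b=%d c=%d", b, n - b))
    }
  }
})

test_that("corrected and uncorrected chi-square agree for many discordant pairs", {
  for (bc in list(c(240, 200), c(130, 90), c(260, 140))) {
    p1 <- mcnemar_counts(bc[1], bc[2], "chi2")$p_value
    p2 <- mcnemar_counts(bc[1], bc[2], "chi2_corrected")$p_value
    expect_lt(abs(p1 - p2), 0.01)
  }
})

test_that("McNemar on prediction vectors counts discordances correctly", {
  truth <- c("AS", "AS", "AS", "nonAS", "nonAS")
  m1 <- c("AS", "AS", "nonAS", "nonAS", "AS")   # right on 1,2,4
  m2 <- c("AS", "nonAS", "AS", "AS", "AS")      # right on 1,3
  r <- mcnemar_test(m1, m2, truth, method = "exact")
  expect_equal(r$b, 2)  # only model 1: docs 2 and 4
  expect_equal(r$c, 1)  # only model 2: doc 3
  # the default falls back to the exact method for few discordances
  expect_equal(mcnemar_test(m1, m2, truth)$method, "exact")
})

test_that("2x2 chi-square matches the demographic-table conventions", {
  sex <- matrix(c(24, 39, 40, 32), nrow = 2)  # M/F by group
  r <- chi2_2x2(sex, yates = TRUE)
  expect_equal(round(r$p_value, 2), 0.06)
  r2 <- chi2_2x2(sex, yates = FALSE)
  # brute-force expected-count oracle
  E <- outer(rowSums(sex), colSums(sex)) / sum(sex)
  expect_equal(r2$statistic, sum((sex - E)^2 / E), tolerance = 1e-12)
  expect_equal(round(r2$statistic, 2), 4.11)

  flat <- matrix(c(10, 20, 10, 20), nrow = 2)
  r3 <- chi2_2x2(flat, yates = FALSE)
  expect_equal(r3$statistic, 0)
  expect_equal(r3$p_value, 1)
  expect_error(chi2_2x2(matrix(c(0, 0, 5, 5), nrow = 2)), "margin")
})

test_that("LOOCV produces one record per document with no training leakage", {
  corp <- tiny_corpus(n_per = 3, length_mean = 12)
  fl <- loocv_run(corp, classifier_config("tag_linear"), annotator = NULL,
                  base_seed = 20)
  expect_equal(nrow(fl), nrow(corp))
  expect_equal(fl$doc_id, corp$id)
  expect_equal(fl$fold_seed, 20 + seq_len(nrow(corp)))
  train_ids <- attr(fl, "train_ids")
  for (i in seq_len(nrow(corp))) {
    expect_false(corp$id[i] %in% train_ids[[i]])
    expect_setequal(train_ids[[i]], setdiff(corp$id, corp$id[i]))
  }
})

test_that("an oracle annotator makes the manual and automatic arms coincide", {
  corp <- tiny_corpus(n_per = 3, length_mean = 12)
  for (v in c("tag_linear", "tag_dnn")) {
    cfg <- if (v == "tag_linear") classifier_config(v) else dnn_test_config(v)
    fl <- loocv_run(corp, cfg, annotator = "oracle", base_seed = 1)
    expect_equal(fl$p_auto, fl$p_manual, tolerance = 1e-12)
  }
})

test_that("LOOCV is deterministic and text-only models skip the annotation arm", {
  corp <- tiny_corpus(n_per = 2, length_mean = 10)
  cfg <- dnn_test_config("text_dnn", epochs = 2)
  a <- loocv_run(corp, cfg, annotator = "oracle", base_seed = 3)
  b <- loocv_run(corp, cfg, annotator = "oracle", base_seed = 3)
  expect_identical(a$p_manual, b$p_manual)
  expect_true(all(is.na(a$p_auto)))
})

test_that("LOOCV validates its inputs", {
  corp <- tiny_corpus(n_per = 1, length_mean = 8)
  expect_error(loocv_run(corp, classifier_config("tag_linear")), "at least 3")
  corp <- tiny_corpus(n_per = 3, length_mean = 8)
  corp$label[1] <- "unknown"
  expect_error(loocv_run(corp, classifier_config("tag_linear")), "labeled")
})

test_that("reports contain one row per variant and source plus McNemar pairs", {
  corp <- tiny_corpus(n_per = 3, length_mean = 12)
  fl1 <- loocv_run(corp, classifier_config("tag_linear"),
                   annotator = "oracle", base_seed = 2)
  fl2 <- loocv_run(corp, dnn_test_config("tag_dnn"), annotator = "oracle",
                   base_seed = 2)
  rep <- build_report(list(tag_linear = fl1, tag_dnn = fl2))
  expect_equal(nrow(rep$metrics), 4L)  # 2 variants x manual/auto
  expect_equal(nrow(rep$mcnemar), 2L)  # 1 pair x manual/auto
  expect_true(all(rep$metrics$accuracy == round(rep$metrics$accuracy, 2)))
  expect_match(rep$metrics$ci[1], "^\\[\\d\\.\\d\\d, \\d\\.\\d\\d\\]$")
  expect_error(build_report(list()), "empty")
})
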