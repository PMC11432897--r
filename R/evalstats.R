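#' Nested leave-one-out cross-validation
#'
#' The evaluation protocol holds out each document once. For fold `n`: the
#' tag annotator is trained on the remaining documents (manual tags), the
#' held-out document's tokens are automatically annotated, the classifier is
#' trained on the remaining documents (always with manual tags), and the
#' held-out document is scored twice — under its manual tags and under the
#' automatic tags. Both the annotator and the classifier are retrained in
#' every fold; the held-out document never enters any training set.
#'
#' @param corpus Corpus tibble; every document needs a manual tag matrix and
#'   an `AS`/`nonAS` label. At least 3 documents.
#' @param classifier_config A [classifier_config()]; its seed is replaced by
#'   the fold seed `base_seed + n` in fold `n`.
#' @param annotator An [annotator_config()] to train the per-fold tagger;
#'   `NULL` to skip the automatic-annotation arm (`p_auto = NA`), or the
#'   string `"oracle"` to substitute an oracle annotator that returns the
#'   manual tags (a protocol audit: then `p_manual == p_auto`).
#' @param base_seed Integer; fold `n` uses seed `base_seed + n`.
#' @param schema Tag schema.
#' @return A tibble of class `sfl_folds` with one row per document:
#'   `doc_id`, `y_true`, `p_manual`, `p_auto`, `fold_seed`. The attribute
#'   `train_ids` records each fold's training document ids (for leakage
#'   audits); `variant` records the classifier variant. For the text-only
#'   variant the annotation arm is vacuous and `p_auto` is `NA`.
#' @export
loocv_run <- function(corpus, classifier_config, annotator = NULL,
                      base_seed = 1L, schema = default_schema()) {
  stopifnot(inherits(classifier_config, "sfl_classifier_config"))
  corpus <- validate_corpus(corpus, schema)
  n <- nrow(corpus)
  if (n < 3L) abort("LOOCV requires at least 3 documents")
  if (!all(corpus$label %in% c("AS", "nonAS"))) {
    abort("every document must be labeled AS or nonAS")
  }
  miss <- vapply(corpus$tags, is.null, logical(1))
  if (any(miss)) {
    abort(paste0("documents lack manual tags: ",
                 paste(head(corpus$id[miss], 5), collapse = ", ")))
  }
  use_annotator <- !is.null(annotator) &&
    classifier_config$variant != "text_dnn"
  oracle <- identical(annotator, "oracle")
  if (use_annotator && !oracle &&
      !inherits(annotator, "sfl_annotator_config")) {
    abort("annotator must be NULL, \"oracle\", or an annotator_config()")
  }

  p_manual <- p_auto <- rep(NA_real_, n)
  fold_seeds <- base_seed + seq_len(n)
  train_ids <- vector("list", n)
  for (i in seq_len(n)) {
    train <- corpus[-i, , drop = FALSE]
    test <- corpus[i, , drop = FALSE]
    train_ids[[i]] <- train$id
    ccfg <- classifier_config
    ccfg$seed <- fold_seeds[i]
    clf <- train_classifier(train, ccfg, schema)
    p_manual[i] <- predict_proba(clf, test, schema)$p_AS
    if (use_annotator) {
      auto_test <- test
      if (oracle) {
        # substitution audit: the "automatic" tags are the manual ones
        auto_test$annotation_source <- "auto"
      } else {
        acfg <- annotator
        acfg$seed <- fold_seeds[i]
        tagger <- train_annotator(train, acfg, schema)
        auto_test$tags <- list(annotate(tagger, test$tokens[[1]]))
        auto_test$annotation_source <- "auto"
      }
      p_auto[i] <- if (needs_tags(ccfg$variant)) {
        predict_proba(clf, auto_test, schema)$p_AS
      } else p_manual[i]
    }
  }
  out <- tibble::tibble(doc_id = corpus$id, y_true = corpus$label,
                        p_manual = p_manual, p_auto = p_auto,
                        fold_seed = fold_seeds)
  attr(out, "train_ids") <- train_ids
  attr(out, "variant") <- classifier_config$variant
  class(out) <- c("sfl_folds", class(out))
  out
}

#' Area under the ROC curve (rank statistic)
#'
#' The Wilcoxon--Mann--Whitney formulation with midranks for ties: the
#' probability that a random positive scores above a random negative, ties
#' counting one half.
#'
#' @param scores Numeric scores.
#' @param positive Logical vector; `TRUE` for the positive (AS) class.
#' @return AUC in `[0, 1]`, or `NA` if either class is absent.
#' @export
auc_wmw <- function(scores, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix metric suite for LOOCV folds
#'
#' Thresholds the fold probabilities at 0.5 with AS as the positive class
#' and reports the confusion counts, accuracy, precision, sensitivity
#' (AS recall), specificity (non-AS recall), and the pooled-probability AUC.
#'
#' @param folds An `sfl_folds` tibble from [loocv_run()] (or any data frame
#'   with `y_true` and the chosen probability column).
#' @param source `"manual"` or `"auto"`: which probability column to score.
#' @param threshold Decision threshold (default 0.5; a probability equal to
#'   the threshold is classified AS).
#' @return A one-row tibble: `source`, `tp`, `fp`, `fn`, `tn`, `n`,
#'   `accuracy`, `precision`, `sensitivity`, `specificity`, `auc`. With a
#'   single-class truth the AUC is `NA` and the class-conditional rates use
#'   the 0-when-empty convention.
#' @export
confusion_metrics <- function(folds, source = c("manual", "auto"),
                              threshold = 0.5) {
  source <- match.arg(source)
  p <- folds[[paste0("p_", source)]]
  if (is.null(p)) abort(paste0("no column p_", source, " in folds"))
  keep <- !is.na(p)
  if (!any(keep)) abort(paste0("no ", source, " probabilities available"))
  p <- p[keep]
  truth <- folds$y_true[keep] == "AS"
  pred <- p >= threshold
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  fn <- sum(!pred & truth); tn <- sum(!pred & !truth)
  n <- length(p)
  div <- function(a, b) if (b == 0) 0 else a / b
  tibble::tibble(
    source = source, tp = tp, fp = fp, fn = fn, tn = tn, n = n,
    accuracy = (tp + tn) / n,
    precision = div(tp, tp + fp),
    sensitivity = div(tp, tp + fn),
    specificity = div(tn, tn + fp),
    auc = auc_wmw(p, truth))
}

#' Wald confidence interval for a proportion
#'
#' `point +/- z * sqrt(point * (1 - point) / n)` with `z = 1.96`, clipped to
#' `[0, 1]`. This is the interval form whose width shrinks exactly as
#' `1 / sqrt(n)`.
#'
#' @param point Proportion in `[0, 1]`.
#' @param n Positive count the proportion was estimated from.
#' @param level Confidence level (fixed-z 0.95 interval).
#' @return A one-row tibble: `point`, `lower`, `upper`, `level`.
#' @export
wald_ci <- function(point, n, level = 0.95) {
  if (length(n) != 1 || n < 1) abort("n must be a positive count")
  if (point < 0 || point > 1) abort("point must lie in [0, 1]")
  z <- 1.96
  half <- z * sqrt(point * (1 - point) / n)
  tibble::tibble(point = point,
                 lower = max(0, point - half),
                 upper = min(1, point + half),
                 level = level)
}

#' McNemar paired-classifier test
#'
#' Compares two classifiers evaluated on the same samples through the
#' discordant counts `b` (samples only model 1 got right) and `c` (samples
#' only model 2 got right). Methods: `chi2` is `(b - c)^2 / (b + c)`;
#' `chi2_corrected` applies the continuity correction
#' `(max(|b - c| - 1, 0))^2 / (b + c)`; both are referred to the upper tail
#' of the 1-df chi-square. `exact` is the two-sided binomial test of
#' `b` successes in `b + c` trials at probability one half (twice the
#' smaller tail, capped at 1). `"auto"` (the default) uses the corrected
#' chi-square, falling back to the exact test when `b + c < 25`. With no
#' discordant pairs the statistic is 0 and `p = 1`.
#'
#' @param pred1,pred2 Predicted labels from the two models.
#' @param truth True labels.
#' @param method `"auto"`, `"chi2"`, `"chi2_corrected"` or `"exact"`.
#' @return A one-row tibble: `b`, `c`, `statistic`, `p_value`, `method`.
#' @export
mcnemar_test <- function(pred1, pred2, truth,
                         method = c("auto", "chi2", "chi2_corrected",
                                    "exact")) {
  method <- match.arg(method)
  if (length(pred1) != length(truth) || length(pred2) != length(truth)) {
    abort("pred1, pred2 and truth must have equal length")
  }
  ok1 <- pred1 == truth
  ok2 <- pred2 == truth
  mcnemar_counts(sum(ok1 & !ok2), sum(ok2 & !ok1), method)
}

#' @rdname mcnemar_test
#' @param b,c Discordant counts (model-1-only and model-2-only correct).
#' @export
mcnemar_counts <- function(b, c, method = c("auto", "chi2", "chi2_corrected",
                                            "exact")) {
  method <- match.arg(method)
  if (b < 0 || c < 0) abort("discordant counts must be non-negative")
  nd <- b + c
  if (method == "auto") method <- if (nd < 25) "exact" else "chi2_corrected"
  if (nd == 0) {
    return(tibble::tibble(b = b, c = c, statistic = 0, p_value = 1,
                          method = method))
  }
  if (method == "exact") {
    stat <- min(b, c)
    p <- min(1, 2 * pbinom(min(b, c), nd, 0.5))
  } else {
    stat <- if (method == "chi2") (b - c)^2 / nd else
      max(abs(b - c) - 1, 0)^2 / nd
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
  }
  tibble::tibble(b = b, c = c, statistic = stat, p_value = p, method = method)
}

#' Pearson chi-square test of independence on a 2x2 table
#'
#' Wraps the classical Pearson statistic (optionally Yates-corrected) with
#' the 1-df upper-tail p-value, as used for demographic group comparisons
#' such as a sex-by-group table.
#'
#' @param table A 2x2 matrix of non-negative counts with positive margins.
#' @param yates Apply the continuity correction.
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @export
chi2_2x2 <- function(table, yates = TRUE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) abort("table must be 2x2")
  if (any(table < 0)) abort("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("table has a zero margin")
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = yates))
  tibble::tibble(statistic = unname(ht$statistic), df = 1,
                 p_value = unname(ht$p.value))
}

#' Assemble an evaluation report
#'
#' Combines LOOCV fold records from several classifier variants into a
#' metrics table (one row per variant and annotation source, rounded to two
#' decimals, with the Wald interval of the accuracy) and, optionally, a
#' block of pairwise McNemar comparisons per annotation source.
#'
#' @param folds_list Named list of `sfl_folds` tibbles, one per variant
#'   (names are the variant labels).
#' @param task Task label recorded in the output rows.
#' @param mcnemar Include pairwise McNemar comparisons.
#' @param mcnemar_method Method passed to [mcnemar_counts()].
#' @return A list of class `sfl_report`: `metrics` (tibble) and `mcnemar`
#'   (tibble or `NULL`).
#' @export
build_report <- function(folds_list, task = "interview", mcnemar = TRUE,
                         mcnemar_method = "auto") {
  if (!length(folds_list)) abort("folds_list is empty")
  if (is.null(names(folds_list)) || any(!nzchar(names(folds_list)))) {
    abort("folds_list must be named by variant")
  }
  rows <- list()
  for (v in names(folds_list)) {
    fl <- folds_list[[v]]
    for (src in c("manual", "auto")) {
      p <- fl[[paste0("p_", src)]]
      if (all(is.na(p))) next
      m <- confusion_metrics(fl, src)
      ci <- wald_ci(m$accuracy, m$n)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        task = task, variant = v, annotation = src, n = m$n,
        accuracy = round(m$accuracy, 2),
        ci = sprintf("[%.2f, %.2f]", round(ci$lower, 2), round(ci$upper, 2)),
        precision = round(m$precision, 2),
        sensitivity = round(m$sensitivity, 2),
        specificity = round(m$specificity, 2),
        auc = round(m$auc, 2))
    }
  }
  metrics <- dplyr::bind_rows(rows)
  mc <- NULL
  if (mcnemar && length(folds_list) > 1L) {
    pairs <- utils::combn(names(folds_list), 2, simplify = FALSE)
    mc_rows <- list()
    for (pr in pairs) {
      f1 <- folds_list[[pr[1]]]; f2 <- folds_list[[pr[2]]]
      for (src in c("manual", "auto")) {
        p1 <- f1[[paste0("p_", src)]]; p2 <- f2[[paste0("p_", src)]]
        if (all(is.na(p1)) || all(is.na(p2))) next
        keep <- !is.na(p1) & !is.na(p2)
        res <- mcnemar_test(ifelse(p1[keep] >= 0.5, "AS", "nonAS"),
                            ifelse(p2[keep] >= 0.5, "AS", "nonAS"),
                            f1$y_true[keep], method = mcnemar_method)
        mc_rows[[length(mc_rows) + 1L]] <- tibble::tibble(
          task = task, comparison = paste(pr[1], "vs", pr[2]),
          annotation = src, b = res$b, c = res$c,
          statistic = round(res$statistic, 2),
          p_value = round(res$p_value, 2), method = res$method)
      }
    }
    mc <- dplyr::bind_rows(mc_rows)
  }
  structure(list(metrics = metrics, mcnemar = mc), class = "sfl_report")
}

#' @exportS3Method base::print
print.sfl_report <- function(x, ...) {
  cat("<sfl_report>\n\nMetrics:\n")
  print(x$metrics)
  if (!is.null(x$mcnemar) && nrow(x$mcnemar)) {
    cat("\nPairwise McNemar comparisons:\n")
    print(x$mcnemar)
  }
  invisible(x)
}
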