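#' Linear SVM with C sweep and cross-validated model selection
#'
#' Trains the evaluation classifier on word features: a linear-kernel SVM
#' (libsvm via e1071) whose single cost parameter C is swept over a grid,
#' each candidate scored by k-fold cross-validated accuracy; the best C
#' (ties towards the smallest) is refit on all data with probability
#' estimates enabled (standard pairwise-coupling method). Classes with
#' fewer than `folds` examples are dropped with a warning.
#'
#' @param x feature matrix (words x features), dense or sparse.
#' @param y labels (factor or character), one per row.
#' @param c_grid cost grid; default `2^seq(-5, 5, 2)`.
#' @param folds cross-validation folds.
#' @param seed seed for fold assignment.
#' @param cv_subsample optional cap on the number of (stratified) training
#'   examples used during the sweep; the final refit always uses all data.
#' @return an object of class `el_classifier`: list with `model`,
#'   `best_cost`, `cv_accuracy` (percent, at the best C), `cv_table`,
#'   `levels`, `dropped`.
#' @export
fit_classifier <- function(x, y, c_grid = 2^seq(-5, 5, 2), folds = 5L,
                           seed = 1L, cv_subsample = NULL,
                           probability = TRUE) {
  y <- factor(y)
  counts <- table(y)
  keep_lv <- names(counts)[counts >= folds]
  dropped <- setdiff(names(counts), keep_lv)
  if (length(dropped))
    warning("dropping classes with fewer than ", folds, " examples: ",
            paste(dropped, collapse = ", "))
  if (length(keep_lv) < 2L)
    stop("classifier needs at least two classes with >= ", folds,
         " examples", call. = FALSE)
  keep <- y %in% keep_lv
  x <- as.matrix(x)[keep, , drop = FALSE]
  y <- droplevels(y[keep])
  xs <- x; ys <- y
  if (!is.null(cv_subsample) && nrow(x) > cv_subsample) {
    idx <- with_seed(derive_seed(seed, "svm"), {
      unlist(lapply(split(seq_along(ys), ys), function(ii)
        sample(ii, max(folds, round(length(ii) * cv_subsample / nrow(x))))))
    })
    xs <- x[idx, , drop = FALSE]; ys <- droplevels(y[idx])
  }
  cv <- vapply(c_grid, function(C) {
    with_seed(derive_seed(seed, "svm"), {
      m <- e1071::svm(xs, ys, kernel = "linear", cost = C, scale = FALSE,
                      cross = folds)
      m$tot.accuracy
    })
  }, 1.0)
  best <- c_grid[which.max(cv)]  # which.max takes the first (smallest C) tie
  model <- with_seed(derive_seed(seed, "svm"), {
    e1071::svm(x, y, kernel = "linear", cost = best, scale = FALSE,
               probability = probability)
  })
  structure(list(model = model, best_cost = best,
                 cv_accuracy = max(cv),
                 cv_table = data.frame(cost = c_grid, accuracy = cv),
                 levels = levels(y), dropped = dropped),
            class = "el_classifier")
}

#' @export
predict.el_classifier <- function(object, x, probability = FALSE, ...) {
  pr <- predict(object$model, as.matrix(x), probability = probability)
  prob <- attr(pr, "probabilities")
  list(class = as.character(pr),
       prob = if (!is.null(prob)) prob[, order(colnames(prob)),
                                       drop = FALSE])
}

#' Per-tag classification accuracy
#'
#' @param predictions,labels aligned character vectors.
#' @param support_min tags with fewer test occurrences are flagged as
#'   low-support (they are still reported).
#' @return data frame with one row per tag present in `labels`: `tag`,
#'   `support`, `correct`, `accuracy` (percent), `low_support`.
#' @export
per_tag_accuracy <- function(predictions, labels, support_min = 10L) {
  if (length(predictions) != length(labels))
    stop("length mismatch between predictions and labels", call. = FALSE)
  tags <- sort(unique(labels))
  support <- vapply(tags, function(t) sum(labels == t), 1L)
  correct <- vapply(tags, function(t)
    sum(labels == t & predictions == t), 1L)
  data.frame(tag = tags, support = support, correct = correct,
             accuracy = 100 * correct / support,
             low_support = support < support_min,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-tailed paired t-test over matched per-corpus accuracies
#'
#' @param acc_a,acc_b equal-length (>= 2) numeric vectors of accuracies on
#'   the same corpora.
#' @param conf confidence level for the interval of the mean difference.
#' @return list with `mean_diff`, `t`, `df`, `p`, `ci`, `degenerate`. With
#'   zero-variance differences, `p` is exactly 1 when the mean difference is
#'   0, otherwise the result is flagged degenerate with `p = NA`.
#' @export
paired_comparison <- function(acc_a, acc_b, conf = 0.95) {
  if (length(acc_a) != length(acc_b) || length(acc_a) < 2L)
    stop("paired comparison needs two equal-length vectors of length >= 2",
         call. = FALSE)
  d <- acc_a - acc_b
  if (sd(d) == 0) {
    return(list(mean_diff = mean(d), t = if (mean(d) == 0) 0 else NA_real_,
                df = length(d) - 1L, p = if (mean(d) == 0) 1 else NA_real_,
                ci = c(mean(d), mean(d)), degenerate = TRUE))
  }
  tt <- t.test(acc_a, acc_b, paired = TRUE, conf.level = conf)
  list(mean_diff = unname(tt$estimate), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value,
       ci = as.numeric(tt$conf.int), degenerate = FALSE)
}

#' Holm-Bonferroni step-down correction with an explicit factor
#'
#' Sorts the p-values ascending, multiplies the i-th smallest by
#' `factor - i + 1`, takes the running maximum and caps at 1 — the
#' step-down procedure generalised to a correction factor at least as large
#' as the number of tests (so a family can be corrected against a larger
#' planned family size).
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @param factor correction factor, `>= length(p_values)`.
#' @return adjusted p-values in the original order.
#' @export
holm_bonferroni <- function(p_values, factor = length(p_values)) {
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (factor < length(p_values))
    stop("correction factor must be at least the number of tests",
         call. = FALSE)
  o <- order(p_values)
  mult <- factor - seq_along(p_values) + 1
  adj <- pmin(cummax(p_values[o] * mult), 1)
  adj[order(o)]
}

#' @importFrom stats sd dist
NULL

#' Run the grammar-classification experiment on prepared features
#'
#' The evaluation protocol: per feature source, fit the linear SVM on the
#' training corpus (C sweep, k-fold CV), evaluate on each held-out corpus,
#' disaggregate accuracy per tag on the pooled test predictions, and
#' compare every pair of sources with a two-tailed paired t-test over the
#' per-corpus accuracies, Holm-Bonferroni corrected.
#'
#' @param features named list, one entry per feature source, each a list
#'   with `train` (matrix) and `test` (list of matrices over the same
#'   held-out corpora).
#' @param labels list with `train` (vector) and `test` (list of vectors).
#' @param holm_factor correction factor (must be at least the number of
#'   source pairs).
#' @param support_min per-tag support threshold.
#' @param prob_corpus index of the test corpus for which the per-word
#'   probability table is emitted (NULL to skip).
#' @param meta optional list of per-test-corpus data frames (sentence,
#'   position, word) merged into the probability table.
#' @inheritParams fit_classifier
#' @return an object of class `el_report`: list with `cv` (percent CV
#'   accuracy per source), `chosen_c`, `accuracy` (corpora x sources
#'   matrix, percent), `per_tag` (per source), `comparisons` (data frame
#'   with raw and adjusted p), `probabilities` (top-5 table or NULL).
#' @export
run_experiment <- function(features, labels, holm_factor = 3,
                           c_grid = 2^seq(-5, 5, 2), folds = 5L,
                           seed = 1L, cv_subsample = NULL,
                           support_min = 10L, prob_corpus = 1L,
                           meta = NULL, fixed_c = NULL) {
  sources <- names(features)
  stopifnot(length(sources) >= 1L, !is.null(labels$train))
  n_corp <- length(labels$test)
  for (s in sources) {
    stopifnot(length(features[[s]]$test) == n_corp)
    for (k in seq_len(n_corp))
      if (identical(dim(features[[s]]$test[[k]]),
                    dim(features[[s]]$train)) &&
          isTRUE(all(features[[s]]$test[[k]] == features[[s]]$train)))
        stop("overlap between train and test corpora (source ", s,
             ", corpus ", k, ")", call. = FALSE)
  }
  fits <- list(); acc <- matrix(NA_real_, n_corp, length(sources),
                                dimnames = list(NULL, sources))
  per_tag <- list(); probs <- list()
  for (s in sources) {
    grid_s <- if (!is.null(fixed_c) && !is.na(fixed_c[s])) fixed_c[[s]]
              else c_grid
    fit <- fit_classifier(features[[s]]$train, labels$train,
                          c_grid = grid_s, folds = folds, seed = seed,
                          cv_subsample = cv_subsample,
                          probability = !is.null(prob_corpus))
    fits[[s]] <- fit
    pooled_pred <- character(0); pooled_lab <- character(0)
    for (k in seq_len(n_corp)) {
      emit_prob <- !is.null(prob_corpus) && k == prob_corpus
      pr <- predict(fit, features[[s]]$test[[k]], probability = emit_prob)
      lab <- as.character(labels$test[[k]])
      acc[k, s] <- 100 * mean(pr$class == lab)
      pooled_pred <- c(pooled_pred, pr$class)
      pooled_lab <- c(pooled_lab, lab)
      if (emit_prob) {
        top5 <- t(apply(pr$prob, 1L, function(p) {
          o <- order(-p)[1:min(5L, length(p))]
          paste0(colnames(pr$prob)[o], ":",
                 formatC(p[o], digits = 3, format = "f"))
        }))
        tab <- data.frame(gold = lab, predicted = pr$class,
                          stringsAsFactors = FALSE)
        tab$top5 <- apply(top5, 1L, paste, collapse = " ")
        if (!is.null(meta)) tab <- cbind(meta[[k]], tab)
        probs[[s]] <- list(table = tab, prob = pr$prob)
      }
    }
    per_tag[[s]] <- per_tag_accuracy(pooled_pred, pooled_lab, support_min)
  }
  comparisons <- NULL
  if (length(sources) >= 2L) {
    pairs <- utils::combn(sources, 2L)
    rows <- lapply(seq_len(ncol(pairs)), function(i) {
      a <- pairs[1L, i]; b <- pairs[2L, i]
      pc <- paired_comparison(acc[, a], acc[, b])
      data.frame(source_a = a, source_b = b, mean_diff = pc$mean_diff,
                 t = pc$t, df = pc$df, p = pc$p,
                 ci_lo = pc$ci[1L], ci_hi = pc$ci[2L],
                 degenerate = pc$degenerate, stringsAsFactors = FALSE)
    })
    comparisons <- do.call(rbind, rows)
    ok <- !is.na(comparisons$p)
    comparisons$p_adjusted <- NA_real_
    if (any(ok))
      comparisons$p_adjusted[ok] <-
        holm_bonferroni(comparisons$p[ok], max(holm_factor, sum(ok)))
  }
  structure(list(
    cv = vapply(fits, function(f) f$cv_accuracy, 1.0),
    chosen_c = vapply(fits, function(f) f$best_cost, 1.0),
    accuracy = acc, per_tag = per_tag, comparisons = comparisons,
    probabilities = if (length(probs)) probs else NULL, fits = fits),
    class = "el_report")
}

#' @export
print.el_report <- function(x, ...) {
  cat("Grammar-classification report\n")
  cat("  mean test accuracy (%):\n")
  m <- colMeans(x$accuracy)
  for (s in names(m))
    cat(sprintf("    %-12s %6.2f  (CV %6.2f, C = %g)\n", s, m[s],
                x$cv[s], x$chosen_c[s]))
  if (!is.null(x$comparisons)) {
    cat("  paired comparisons:\n")
    print(x$comparisons[, c("source_a", "source_b", "mean_diff", "t", "p",
                            "p_adjusted")], row.names = FALSE)
  }
  invisible(x)
}
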