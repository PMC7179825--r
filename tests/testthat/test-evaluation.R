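test_that("the classifier is perfect on linearly separable toys and chance on shuffles", {
  set.seed(1)
  x <- rbind(matrix(rnorm(100, 0), 50), matrix(rnorm(100, 4), 50))
  y <- rep(c("a", "b"), each = 50)
  fit <- fit_classifier(x, y, c_grid = c(0.1, 1))
  expect_equal(fit$cv_accuracy, 100)
  expect_equal(predict(fit, x)$class, y)
  # shuffled labels: cross-validated accuracy near 1/2 within binomial error
  ysh <- sample(y)
  fit2 <- fit_classifier(x, ysh, c_grid = 1)
  expect_lt(abs(fit2$cv_accuracy / 100 - 0.5), 4 * sqrt(0.25 / 100) + 0.05)
  expect_error(fit_classifier(x, rep("a", 100)), "two classes")
})

test_that("irreducibly ambiguous duplicated features score about 50%", {
  x <- matrix(rep(c(0, 1), each = 40), 80, 1)
  y <- rep(c("a", "b"), 40)  # each duplicated feature value is 50/50
  fit <- fit_classifier(x, y, c_grid = 1)
  expect_lt(abs(fit$cv_accuracy - 50), 15)
})

test_that("classes with too few examples are dropped with a warning", {
  set.seed(2)
  x <- matrix(rnorm(42 * 3), 42)
  y <- c(rep("a", 20), rep("b", 20), rep("rare", 2))
  expect_warning(fit <- fit_classifier(x, y, c_grid = 1), "rare")
  expect_false("rare" %in% fit$levels)
})

test_that("per-tag accuracies are exact on a hand-built fixture and aggregate to overall", {
  pred <- c("NN", "NN", "VB", "DT", "VB", "NN")
  gold <- c("NN", "VB", "VB", "DT", "VB", "NN")
  tab <- per_tag_accuracy(pred, gold, support_min = 2)
  expect_equal(tab$tag, c("DT", "NN", "VB"))
  expect_equal(tab$support, c(1L, 2L, 3L))
  expect_equal(tab$accuracy, c(100, 100, 200 / 3), tolerance = 1e-12)
  expect_equal(tab$low_support, c(TRUE, FALSE, FALSE))
  # support-weighted aggregation equals the overall accuracy
  overall <- 100 * mean(pred == gold)
  expect_equal(sum(tab$accuracy * tab$support) / sum(tab$support), overall)
  # a tag absent from the gold labels is not reported
  expect_false("XX" %in% per_tag_accuracy(c("XX", "NN"), c("NN", "NN"))$tag)
  expect_error(per_tag_accuracy("a", c("a", "b")), "length mismatch")
})

test_that("paired comparison matches the closed-form t on a fixed difference vector", {
  d <- c(2, 4, 1, 3, 5, 2, 3, 4, 1, 5)
  b <- rep(0, 10)
  got <- paired_comparison(d, b)
  # textbook formula computed independently
  n <- length(d)
  t_want <- mean(d) / (sd(d) / sqrt(n))
  p_want <- 2 * pt(-abs(t_want), n - 1)
  ci_want <- mean(d) + c(-1, 1) * qt(0.975, n - 1) * sd(d) / sqrt(n)
  expect_equal(got$t, t_want)
  expect_equal(got$p, p_want)
  expect_equal(got$ci, ci_want)
  expect_false(got$degenerate)
})

test_that("degenerate paired comparisons are flagged", {
  same <- c(81.2, 79.5, 83.1)
  eq <- paired_comparison(same, same)
  expect_equal(eq$p, 1)
  expect_equal(eq$t, 0)
  const <- paired_comparison(same + 1, same)
  expect_true(const$degenerate)
  expect_true(is.na(const$p))
  expect_error(paired_comparison(1:3, 1:2), "equal-length")
})

test_that("Holm-Bonferroni with an explicit factor matches the step-down by hand", {
  expect_equal(holm_bonferroni(c(0.01, 0.02, 0.04), factor = 3),
               c(0.03, 0.04, 0.04))
  expect_equal(holm_bonferroni(0.2, factor = 3), 0.6)
  expect_equal(holm_bonferroni(c(1, 1, 1), factor = 3), c(1, 1, 1))
  expect_error(holm_bonferroni(c(0.1, 0.2), factor = 1), "factor")
  expect_error(holm_bonferroni(c(0.5, 1.2), factor = 3), "\\[0, 1\\]")
})

test_that("Holm adjustment is order-preserving, at least the raw p, and idempotent at n", {
  set.seed(3)
  for (rep in 1:20) {
    p <- runif(sample(2:8, 1))
    adj <- holm_bonferroni(p, factor = length(p))
    expect_true(all(adj >= p - 1e-12))
    expect_equal(order(adj[order(p)]), seq_along(p))  # monotone in rank
    # standard Holm (factor = n) agrees with stats::p.adjust
    expect_equal(adj, p.adjust(p, "holm"))
  }
})

test_that("run_experiment ties the protocol together on a small synthetic problem", {
  set.seed(4)
  mk <- function(n, shift) {
    x <- rbind(matrix(rnorm(n * 4, 0), n), matrix(rnorm(n * 4, shift), n))
    list(x = x, y = rep(c("a", "b"), each = n))
  }
  tr <- mk(30, 3)
  tests <- lapply(1:3, function(k) mk(15, 3))
  noise <- lapply(tests, function(t)
    list(x = matrix(rnorm(nrow(t$x) * 4), nrow(t$x)), y = t$y))
  feats <- list(
    good = list(train = tr$x, test = lapply(tests, `[[`, "x")),
    noise = list(train = matrix(rnorm(240), 60),
                 test = lapply(noise, `[[`, "x")))
  labels <- list(train = tr$y, test = lapply(tests, `[[`, "y"))
  rep_ <- run_experiment(feats, labels, c_grid = 1, holm_factor = 3)
  expect_gt(mean(rep_$accuracy[, "good"]), mean(rep_$accuracy[, "noise"]))
  expect_equal(dim(rep_$accuracy), c(3L, 2L))
  expect_gte(rep_$comparisons$p_adjusted[1], rep_$comparisons$p[1])
  # probability rows sum to one
  pr <- rep_$probabilities$good$prob
  expect_true(all(abs(rowSums(pr) - 1) < 1e-6))
  # identical features for both sources exercise the degenerate-t path
  feats2 <- list(a = feats$good, b = feats$good)
  rep2 <- run_experiment(feats2, labels, c_grid = 1, holm_factor = 3,
                         seed = 9)
  expect_equal(rep2$comparisons$p, 1)
  expect_equal(rep2$comparisons$t, 0)
  # train/test overlap is rejected
  feats3 <- list(a = list(train = tr$x, test = list(tr$x)))
  labels3 <- list(train = tr$y, test = list(tr$y))
  expect_error(run_experiment(feats3, labels3, c_grid = 1), "overlap")
})
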