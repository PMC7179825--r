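# Build a synapse table directly from explicit branch structure:
# branches is a list (one per branch) of data.frames with pre and w.
table_from_branches <- function(branches, est = 0.5) {
  spb <- nrow(branches[[1]])
  pre <- matrix(unlist(lapply(branches, `[[`, "pre")), nrow = 1)
  w <- matrix(unlist(lapply(branches, `[[`, "w")), nrow = 1)
  structure(list(pre = pre, w = w, spb = spb, established_threshold = est),
            class = "el_synapse_table")
}

test_that("no presynaptic drive means no prediction", {
  br <- list(data.frame(pre = 1:3, w = c(1, 1, 1)),
             data.frame(pre = 4:6, w = c(1, 1, 1)))
  tab <- table_from_branches(br)
  p <- compute_predictions(tab, integer(0), 6)
  expect_length(p$predicted, 0L)
})

test_that("branches are independent: counts never sum across branches", {
  # branch A and branch B each hold one active established synapse;
  # with branch_threshold = 2 the unit must NOT be predicted even though
  # the union holds two
  br <- list(data.frame(pre = c(1, 2, 3), w = c(0.9, 0.1, 0.1)),
             data.frame(pre = c(4, 5, 6), w = c(0.9, 0.1, 0.1)))
  tab <- table_from_branches(br)
  p <- compute_predictions(tab, c(1, 4), 6, branch_threshold = 2)
  expect_length(p$predicted, 0L)
  # both active established synapses on branch A -> predicted, overlap 2
  br2 <- list(data.frame(pre = c(1, 4, 3), w = c(0.9, 0.9, 0.1)),
              data.frame(pre = c(2, 5, 6), w = c(0.9, 0.1, 0.1)))
  tab2 <- table_from_branches(br2)
  p2 <- compute_predictions(tab2, c(1, 4), 6, branch_threshold = 2)
  expect_equal(p2$predicted, 1L)
  expect_equal(p2$overlap[1], 2L)
})

test_that("prediction agrees with the exhaustive brute-force oracle on toy instances", {
  grid_w <- c(0, 0.4, 0.6, 1)
  # exhaustive over all weight assignments for 1 post unit, 2 branches x 2
  # slots, and all activity patterns of 4 presynaptic units
  pre <- c(1L, 2L, 3L, 4L)
  weight_combos <- expand.grid(grid_w, grid_w, grid_w, grid_w)
  act_combos <- expand.grid(c(FALSE, TRUE), c(FALSE, TRUE),
                            c(FALSE, TRUE), c(FALSE, TRUE))
  for (thr in 1:2) {
    for (wi in seq_len(nrow(weight_combos))) {
      w <- as.numeric(weight_combos[wi, ])
      tab <- table_from_branches(list(
        data.frame(pre = pre[1:2], w = w[1:2]),
        data.frame(pre = pre[3:4], w = w[3:4])))
      for (ai in seq_len(nrow(act_combos))) {
        active <- pre[as.logical(act_combos[ai, ])]
        got <- compute_predictions(tab, active, 4, branch_threshold = thr)
        want <- oracle_predict(list(data.frame(pre = pre[1:2], w = w[1:2]),
                                    data.frame(pre = pre[3:4], w = w[3:4])),
                               active, 0.5, thr)
        expect_equal(got$overlap[1], want)
      }
    }
  }
})

test_that("prediction matches the oracle on random 2-post/3-branch/3-slot instances", {
  set.seed(19)
  grid_w <- c(0, 0.4, 0.6, 1)
  for (rep in 1:200) {
    n_src <- 9L
    pre <- matrix(sample(n_src, 2 * 9, replace = TRUE), 2, 9)
    w <- matrix(sample(grid_w, 18, replace = TRUE), 2, 9)
    tab <- structure(list(pre = pre, w = w, spb = 3L,
                          established_threshold = 0.5),
                     class = "el_synapse_table")
    active <- which(runif(n_src) < 0.4)
    thr <- sample(1:3, 1)
    got <- compute_predictions(tab, active, n_src, branch_threshold = thr)
    for (r in 1:2) {
      branches <- lapply(1:3, function(b)
        data.frame(pre = pre[r, ((b - 1) * 3 + 1):(b * 3)],
                   w = w[r, ((b - 1) * 3 + 1):(b * 3)]))
      expect_equal(got$overlap[r], oracle_predict(branches, active, 0.5, thr))
    }
  }
})

test_that("plasticity applies the stated potentiation and depression arithmetic", {
  pre <- matrix(c(1L, 2L), 1, 2)
  tab <- structure(list(pre = pre, w = matrix(c(0.5, 0.5), 1, 2), spb = 2L,
                        established_threshold = 0.5),
                   class = "el_synapse_table")
  # presynaptic 1 in the past set -> potentiation to 0.6;
  # presynaptic 2 simultaneous-only -> depression to 0.4
  out <- plasticity_update(tab, past_source_active = 1,
                           current_source_active = 2, post_active = 1,
                           n_source_units = 2, lr = 0.2)
  expect_equal(as.numeric(out$w), c(0.6, 0.4))
  # lr = 0: unchanged
  out0 <- plasticity_update(tab, 1, 2, 1, 2, lr = 0)
  expect_equal(out0$w, tab$w)
  # inactive post units never change
  out2 <- plasticity_update(tab, 1, 2, integer(0), 2, lr = 0.5)
  expect_equal(out2$w, tab$w)
  # past-pairing wins when a unit is in both sets
  out3 <- plasticity_update(tab, c(1, 2), c(1, 2), 1, 2, lr = 0.2)
  expect_equal(as.numeric(out3$w), c(0.6, 0.6))
  expect_error(plasticity_update(tab, 1, 2, 1, 2, lr = 1.5),
               "configuration error")
})

test_that("plasticity matches an element-wise oracle and keeps weights in [0, 1]", {
  set.seed(23)
  pre <- matrix(sample(6L, 12, replace = TRUE), 3, 4)
  w <- matrix(runif(12), 3, 4)
  tab <- structure(list(pre = pre, w = w, spb = 2L,
                        established_threshold = 0.5),
                   class = "el_synapse_table")
  for (rep in 1:1000) {
    past <- which(runif(6) < 0.4)
    curr <- which(runif(6) < 0.4)
    post <- which(runif(3) < 0.5)
    lr <- runif(1)
    want <- oracle_plasticity(tab$pre, tab$w, post, past, curr, lr)
    tab <- plasticity_update(tab, past, curr, post, 6, lr)
    expect_equal(tab$w, want)
  }
  expect_true(all(tab$w >= 0 & tab$w <= 1))
})

test_that("repeated pairing drives weights monotonically towards the fixed points", {
  pre <- matrix(c(1L, 2L), 1, 2)
  tab <- structure(list(pre = pre, w = matrix(c(0.2, 0.8), 1, 2), spb = 2L,
                        established_threshold = 0.5),
                   class = "el_synapse_table")
  w_pot <- numeric(30); w_dep <- numeric(30)
  for (k in 1:30) {
    tab <- plasticity_update(tab, past_source_active = 1,
                             current_source_active = 2, post_active = 1,
                             n_source_units = 2, lr = 0.1)
    w_pot[k] <- tab$w[1, 1]; w_dep[k] <- tab$w[1, 2]
  }
  expect_true(all(diff(w_pot) > 0))
  expect_true(all(diff(w_dep) < 0))
  expect_gt(w_pot[30], 0.95)
  expect_lt(w_dep[30], 0.05)
})

test_that("pruning zeroes sub-floor weights, reports sparseness, and is idempotent", {
  pre <- matrix(1:6, 2, 3)
  w <- matrix(c(0.05, 0.3, 0.09, 0.7, 0.5, 0.0), 2, 3)
  tab <- structure(list(pre = pre, w = w, spb = 3L,
                        established_threshold = 0.5),
                   class = "el_synapse_table")
  out <- prune_table(tab, prune_floor = 0.1)
  expect_equal(as.numeric(out$table$w), c(0, 0.3, 0, 0.7, 0.5, 0))
  expect_equal(out$sparseness, 4 / 6)
  again <- prune_table(out$table, prune_floor = 0.1)
  expect_identical(again$table$w, out$table$w)
  # all weights below the floor -> sparseness 1
  tab$w[] <- 0.01
  expect_equal(prune_table(tab, 0.1)$sparseness, 1)
  # all weights at 1 -> unchanged
  tab$w[] <- 1
  expect_identical(prune_table(tab, 0.1)$table$w, tab$w)
})
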