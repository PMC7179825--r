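# Shared fixtures and memoised heavy computations.

# Tiny configuration for fast structural tests: 2x2 columns of 2x3 units.
tiny_config <- function(...) {
  el_config(grid_rows = 2L, grid_cols = 2L, units_rows = 2L,
            units_cols = 3L, input_rows = 3L, input_cols = 4L,
            afferent_rf_rows = 3L, afferent_rf_cols = 3L,
            afferent_inputs = 4L, lateral_rf_rows = 3L,
            lateral_rf_cols = 3L, lateral_linked = 2L,
            apical_rf_rows = 3L, apical_rf_cols = 3L, apical_linked = 2L,
            synapses_per_branch = 2L, winners_per_cc = 1L,
            excited_fraction = 0.34, prune_period = 10L, ...)
}

# Brute-force toroidal window on one axis (independent oracle).
oracle_window <- function(center, rf, n) {
  offs <- seq_len(rf) - 1L - (rf %/% 2L)
  ((center + offs - 1L) %% n) + 1L
}

# Brute-force dendritic prediction over explicit branch structure:
# branches: list of data.frames with columns pre (id) and w (weight).
oracle_predict <- function(branches, active, est, thr) {
  best <- 0L
  for (b in branches) {
    cnt <- sum(b$w >= est & b$pre %in% active)
    if (cnt >= thr && cnt > best) best <- cnt
  }
  best
}

# Element-wise reimplementation of the plasticity rule.
oracle_plasticity <- function(pre, w, post_active, past, curr, lr) {
  out <- w
  for (r in post_active) {
    for (cidx in seq_len(ncol(pre))) {
      p <- pre[r, cidx]
      if (p %in% past) out[r, cidx] <- out[r, cidx] + lr * (1 - out[r, cidx])
      else if (p %in% curr) out[r, cidx] <- out[r, cidx] * (1 - lr)
    }
  }
  out
}

# Memoised expensive artifacts shared across acceptance tests.
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# The desk-scale grammar-bootstrap benchmark: 600 training sentences, 10
# held-out corpora of 150 sentences, 10 encoder seeds, full and
# stripped-lateral models. Used by several acceptance checks.
acceptance_benchmark <- function() {
  cached("benchmark", el_benchmark(config = el_config_scaled(), seed = 1L,
                                   encoder_seeds = 1:10, n_train = 600L,
                                   n_test_corpora = 10L,
                                   n_test_sentences = 150L,
                                   include_lesion = TRUE,
                                   include_embeddings = TRUE))
}
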