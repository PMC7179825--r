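#' Create a distal synapse table over a pathway's wiring
#'
#' Attaches a weight in `[0, 1]` to every (post unit, branch, slot) potential
#' synapse of one pathway. Initial weights are uniform in
#' `[0, established_threshold / 2)`: no synapse starts established, and no
#' single potentiation event can establish one, so established connections
#' always reflect repeated pre/post pairing.
#'
#' @param pre integer matrix of presynaptic unit ids, one pathway of an
#'   [wire_distal()] result.
#' @param spb synapses per branch (slot columns per branch in `pre`).
#' @param established_threshold weight at which a synapse counts as
#'   established.
#' @param seed integer seed for the initial weights.
#' @return an object of class `el_synapse_table`: list with `pre`, `w`,
#'   `spb`, `established_threshold`.
#' @export
synapse_table <- function(pre, spb, established_threshold = 0.5, seed = 1L) {
  w <- with_seed(derive_seed(seed, "weights"), {
    matrix(runif(length(pre), 0, established_threshold / 2),
           nrow(pre), ncol(pre))
  })
  structure(list(pre = pre, w = w, spb = as.integer(spb),
                 established_threshold = established_threshold),
            class = "el_synapse_table")
}

#' Dendritic predictions (partial depolarization)
#'
#' A unit enters the predictive state iff at least one of its branches holds
#' `branch_threshold` or more synapses that are simultaneously established
#' (weight at or above the table's threshold) and presynaptically active.
#' Branches are independent computing elements: counts are never summed
#' across branches.
#'
#' @param table an [synapse_table()].
#' @param active integer vector of active presynaptic unit ids in the
#'   table's source layer.
#' @param n_source_units number of units in the source layer.
#' @param branch_threshold active established synapses needed for a
#'   dendritic spike.
#' @return list with `predicted` (integer ids of predicted post units) and
#'   `overlap` (per post unit, the best spiking branch's count; 0 when not
#'   predicted).
#' @export
compute_predictions <- function(table, active, n_source_units,
                                branch_threshold = 1L) {
  active <- as.integer(active)
  if (length(active) && (min(active) < 1L || max(active) > n_source_units))
    stop("structural error: active presynaptic ids outside the source layer",
         call. = FALSE)
  best <- cpp_branch_overlap(table$pre, table$w, active, n_source_units,
                             table$established_threshold,
                             as.integer(branch_threshold), table$spb)
  list(predicted = which(best > 0L), overlap = best)
}

#' STDP-like potentiation/depression of a synapse table
#'
#' Only synapses onto currently active post units change. A synapse whose
#' presynaptic unit was active in the past source activation is potentiated
#' (`w <- w + lr * (1 - w)`); one whose presynaptic unit is only
#' simultaneously active is depressed (`w <- w * (1 - lr)`); a presynaptic
#' unit active in both sets potentiates (past-pairing wins). Weights stay in
#' `[0, 1]` by construction.
#'
#' @inheritParams compute_predictions
#' @param past_source_active,current_source_active integer id vectors of the
#'   source layer's past and simultaneous activations.
#' @param post_active integer ids of the currently active post units.
#' @param lr learning rate in `[0, 1]`.
#' @return the updated table (the input is not modified).
#' @export
plasticity_update <- function(table, past_source_active,
                              current_source_active, post_active,
                              n_source_units, lr) {
  if (!is.finite(lr) || lr < 0 || lr > 1)
    stop("configuration error: learning rate must lie in [0, 1]",
         call. = FALSE)
  w <- table$w + 0  # force a private copy; the C++ kernel updates in place
  cpp_plasticity(table$pre, w, as.integer(post_active),
                 as.integer(past_source_active),
                 as.integer(current_source_active),
                 n_source_units, lr)
  table$w <- w
  table
}

#' Homeostatic pruning of weak synapses
#'
#' Weights strictly below `prune_floor` are set to 0; the potential slot
#' persists and may relearn. Also reports the table's sparseness: the
#' fraction of potential synapses that are not established.
#'
#' @inheritParams compute_predictions
#' @param prune_floor weights below this are zeroed.
#' @return list with `table` (pruned) and `sparseness`.
#' @export
prune_table <- function(table, prune_floor) {
  w <- table$w + 0
  w[w < prune_floor] <- 0
  table$w <- w
  list(table = table, sparseness = table_sparseness(table))
}

#' @rdname prune_table
#' @export
table_sparseness <- function(table) {
  if (length(table$w) == 0L) return(NA_real_)
  mean(table$w < table$established_threshold)
}
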