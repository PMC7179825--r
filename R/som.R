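#' Afferent SOM response
#'
#' Excitation of every unit of one column's self-organizing map to a sampled
#' input vector: the negated Euclidean distance between the input and the
#' unit's weight vector (larger is more excited; an exact match scores 0).
#'
#' @param som a SOM weight matrix (`afferent_inputs` x units, units ordered
#'   row-major over the column's lattice), as stored per column in an
#'   [el_encoder()].
#' @param x numeric input vector of length `afferent_inputs`.
#' @return numeric vector of per-unit excitations.
#' @export
som_response <- function(som, x) {
  if (length(x) != nrow(som))
    stop("input error: input length ", length(x),
         " does not match the SOM's ", nrow(som), " afferent inputs",
         call. = FALSE)
  if (!all(is.finite(x)))
    stop("input error: non-finite input components", call. = FALSE)
  -sqrt(colSums((som - x)^2))
}

#' Kohonen update of one column's SOM
#'
#' Classic rule: the best-matching unit `c` is the most excited unit (ties
#' broken towards the lowest unit index), and every unit `i` moves towards
#' the input by `alpha * exp(-d(c,i)^2 / (2 sigma^2)) * (x - w_i)` where `d`
#' is the lattice distance.
#'
#' @inheritParams som_response
#' @param alpha learning rate (>= 0).
#' @param sigma Gaussian neighborhood radius in lattice units (> 0).
#' @param lattice_d2 optional precomputed units x units matrix of squared
#'   lattice distances; computed from `dims` when missing.
#' @param dims integer `c(rows, cols)` of the unit lattice (required when
#'   `lattice_d2` is missing).
#' @return the updated weight matrix.
#' @export
som_update <- function(som, x, alpha, sigma, lattice_d2 = NULL, dims = NULL) {
  if (!all(is.finite(x)))
    stop("input error: non-finite input components", call. = FALSE)
  if (is.null(lattice_d2)) {
    if (is.null(dims)) stop("supply `lattice_d2` or `dims`", call. = FALSE)
    lattice_d2 <- lattice_sqdist(dims[1L], dims[2L])
  }
  exc <- som_response(som, x)
  bmu <- which.max(exc)
  ah <- alpha * exp(-lattice_d2[, bmu] / (2 * sigma^2))
  som + (x - som) * rep(ah, each = nrow(som))
}

# squared lattice distances between units of an r x c lattice (row-major)
lattice_sqdist <- function(rows, cols) {
  n <- rows * cols
  r <- (seq_len(n) - 1L) %/% cols
  c <- (seq_len(n) - 1L) %% cols
  outer(r, r, "-")^2 + outer(c, c, "-")^2
}

#' Exponential parameter decay schedule
#'
#' Geometric interpolation between an initial and a final value:
#' `initial * (final/initial)^(step/total_steps)`. Strictly monotone between
#' the endpoints; returns `initial` when `total_steps` is 0.
#'
#' @param initial,final positive endpoint values.
#' @param step current step, `0 <= step <= total_steps`.
#' @param total_steps schedule length in steps.
#' @return the interpolated value.
#' @export
decay_schedule <- function(initial, final, step, total_steps) {
  stopifnot(initial > 0, final > 0, step >= 0, step <= max(total_steps, 0))
  if (total_steps <= 0) return(initial)
  initial * (final / initial)^(step / total_steps)
}

#' Select a column's afferently excited cluster
#'
#' Returns exactly `k = floor(excited_fraction * units)` unit ids. In
#' deterministic mode these are the top-k by excitation (ties towards the
#' lowest unit index). In stochastic mode units are drawn without
#' replacement with weights `exp(beta * (excitation - max excitation))`,
#' so excitation biases but does not fully determine membership.
#'
#' @param excitations numeric per-unit excitation vector.
#' @param k cluster size; taken from `config` when omitted.
#' @param config optional [el_config()] supplying `k`, `beta` and the mode.
#' @param mode `"stochastic"` or `"deterministic"`.
#' @param beta stochastic-mode temperature.
#' @return sorted integer vector of `k` unit ids.
#' @export
select_excited <- function(excitations, k = NULL, config = NULL,
                           mode = NULL, beta = NULL) {
  if (!is.null(config)) {
    k <- k %||% excited_size(config)
    beta <- beta %||% config$excitation_beta
    mode <- mode %||% (if (config$stochastic) "stochastic" else "deterministic")
  }
  mode <- match.arg(mode %||% "stochastic",
                    c("stochastic", "deterministic"))
  beta <- beta %||% 3
  if (!all(is.finite(excitations)))
    stop("input error: non-finite excitations", call. = FALSE)
  n <- length(excitations)
  if (is.null(k) || k < 1L)
    stop("configuration error: excited-cluster size must be at least 1",
         call. = FALSE)
  if (k > n)
    stop("configuration error: excited-cluster size exceeds the unit count",
         call. = FALSE)
  if (k == n) return(seq_len(n))
  if (mode == "deterministic") {
    sort(order(-excitations)[seq_len(k)])
  } else {
    # beta acts on standardized excitations, so its calibration (defined on
    # unit-variance profiles, where this reduces to exp(beta * (e - max)))
    # carries over unchanged to any excitation scale; the same C++ kernel
    # drives the encoder's per-column selection
    s <- sd(excitations)
    w <- if (!is.finite(s) || s == 0) rep(1, n)
         else exp(beta * (excitations - max(excitations)) / s)
    sort(cpp_weighted_sample(w, k))
  }
}

# Initialize one column's SOM weights uniformly within the observed
# per-component range of `obs` (afferent_inputs x n_observations); falls
# back to [0, 1] for degenerate or missing observations.
som_init <- function(n_inputs, upc, obs = NULL) {
  lo <- rep(0, n_inputs); hi <- rep(1, n_inputs)
  if (!is.null(obs) && ncol(obs) > 0L) {
    lo <- apply(obs, 1L, min); hi <- apply(obs, 1L, max)
    flat <- hi - lo <= 0
    lo[flat] <- lo[flat] - 0.5; hi[flat] <- hi[flat] + 0.5
  }
  matrix(runif(n_inputs * upc, lo, hi), n_inputs, upc)
}
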