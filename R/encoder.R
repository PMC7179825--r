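#' Construct an (untrained) encoder layer
#'
#' Builds the full model state: topology (column placement, afferent
#' sampling, linked columns), distal potential-synapse wiring with initial
#' weights, and one self-organizing map per column. All randomness flows
#' through sub-seeds derived from `seed` (see [derive_seed()]), so the same
#' configuration and seed always produce the identical model.
#'
#' @param config an [el_config()].
#' @param seed integer run seed.
#' @return an object of class `el_encoder`.
#' @seealso [train_encoder()], [predict.el_encoder()], [strip_lateral()],
#'   [synapse_census()].
#' @export
el_encoder <- function(config = el_config(), seed = 1L) {
  topo <- build_topology(config, seed)
  wiring <- wire_distal(config, topo, seed)
  est <- config$established_threshold
  lateral <- synapse_table(wiring$lateral, wiring$spb, est, seed)
  apical <- synapse_table(wiring$apical, wiring$spb, est,
                          derive_seed(seed, "weights"))
  upc <- units_per_column(config)
  som <- with_seed(derive_seed(seed, "som"), {
    lapply(seq_len(n_columns(config)), function(cc)
      som_init(config$afferent_inputs, upc))
  })
  structure(list(
    config = config, seed = as.integer(seed),
    topology = topo, wiring = wiring,
    lateral = lateral, apical = apical,
    som = som, som_initialized = FALSE,
    lattice_d2 = lattice_sqdist(config$units_rows, config$units_cols),
    prev_active = integer(0),
    has_lateral = TRUE,
    trained = FALSE, learn_steps = 0L,
    log = NULL
  ), class = "el_encoder")
}

#' Remove the lateral pathway (lesion variant)
#'
#' Returns the stripped-lateral encoder variant: the lateral wiring and
#' synapse table are removed so predictions come from the apical pathway
#' only; all other machinery is identical. Applicable before training to
#' obtain a separately trained lesioned instance.
#'
#' @param enc an [el_encoder()].
#' @return the lesioned encoder.
#' @export
strip_lateral <- function(enc) {
  stopifnot(inherits(enc, "el_encoder"))
  enc$has_lateral <- FALSE
  enc$lateral <- NULL
  enc$wiring$lateral <- matrix(0L, n_units(enc$config), 0L)
  enc$prev_active <- integer(0)
  enc
}

#' Clear the lateral context
#'
#' Empties the previous-activation context, so the next word receives no
#' lateral predictions (apical only). Called automatically at every sentence
#' start during training and inference; idempotent.
#'
#' @param enc an [el_encoder()].
#' @return the encoder with cleared context.
#' @export
reset_context <- function(enc) {
  enc$prev_active <- integer(0)
  enc
}

#' Flatten an activation into a sparse binary feature vector
#'
#' Global feature index = `(column - 1) * units_per_column + unit`; active
#' units map to 1, everything else to 0. Returned as the sorted index list
#' over the `columns * units_per_column`-dimensional binary vector.
#'
#' @param activation an activation record (list with an `active` integer
#'   vector of global unit ids) or the id vector itself.
#' @param config the encoder's [el_config()] (unused beyond validation of
#'   the index range).
#' @return sorted integer vector of active feature indices.
#' @export
flatten_activation <- function(activation, config) {
  ids <- if (is.list(activation)) activation$active else activation
  ids <- as.integer(ids)
  if (length(ids) && (min(ids) < 1L || max(ids) > n_units(config)))
    stop("structural error: active unit ids outside the layer", call. = FALSE)
  sort(ids)
}

# Mutable working state for the per-word loop: weight matrices are private
# copies that the C++ kernels update in place.
encoder_as_env <- function(enc) {
  cfg <- enc$config
  env <- new.env(parent = emptyenv())
  env$config <- cfg
  env$n_cols <- n_columns(cfg)
  env$upc <- units_per_column(cfg)
  env$n_units <- n_units(cfg)
  env$aff <- enc$topology$afferent
  env$has_lateral <- enc$has_lateral
  if (enc$has_lateral) {
    env$lat_pre <- enc$lateral$pre
    env$lat_w <- enc$lateral$w + 0
  }
  env$api_pre <- enc$apical$pre
  env$api_w <- enc$apical$w + 0
  # private copies: the C++ kernels update SOM weights in place
  env$som <- lapply(enc$som, function(m) m + 0)
  env$lattice_d2 <- enc$lattice_d2
  env$prev <- enc$prev_active
  env$spb <- enc$wiring$spb
  env$k_excited <- excited_size(cfg)
  env$learn_steps <- enc$learn_steps
  env
}

env_into_encoder <- function(env, enc) {
  if (enc$has_lateral) enc$lateral$w <- env$lat_w
  enc$apical$w <- env$api_w
  enc$som <- env$som
  enc$prev_active <- env$prev
  enc$learn_steps <- env$learn_steps
  enc
}

# One word event on the mutable state. Returns list(active, mfe, excited_n).
step_core <- function(env, word_vector, apical_active, learn = FALSE,
                      alpha = 0, sigma = 1, distal_lr = 0) {
  cfg <- env$config
  # (1) dendritic predictions: lateral from the previous EL activation,
  # apical from the word-category SDR; union, keeping the best overlap
  ov <- integer(env$n_units)
  if (env$has_lateral && length(env$prev))
    ov <- cpp_branch_overlap(env$lat_pre, env$lat_w, env$prev, env$n_units,
                             cfg$established_threshold, cfg$branch_threshold,
                             env$spb)
  if (length(apical_active)) {
    ov_a <- cpp_branch_overlap(env$api_pre, env$api_w,
                               as.integer(apical_active), env$n_units,
                               cfg$established_threshold,
                               cfg$branch_threshold, env$spb)
    ov <- pmax(ov, ov_a)
  }
  # (2) afferent excitation per column over the sampled components
  X <- word_vector[env$aff]
  dim(X) <- dim(env$aff)
  exc <- cpp_som_response_all(env$som, X)
  # (3) per-column inhibition: predicted-and-excited winners, else MFE
  sel <- cpp_select_active(exc, ov, env$k_excited, cfg$winners_per_cc,
                           cfg$sdr_min_predicted, cfg$stochastic,
                           cfg$excitation_beta)
  active <- sel$active
  mfe <- sel$mfe
  # (4) plasticity: SOM towards the input; lateral paired with the previous
  # EL activation (simultaneous co-activation depresses); apical paired with
  # the category SDR (no simultaneous source)
  if (learn) {
    cpp_som_update_all(env$som, X, exc, alpha, sigma, env$lattice_d2)
    if (env$has_lateral)
      cpp_plasticity(env$lat_pre, env$lat_w, active, env$prev, active,
                     env$n_units, distal_lr)
    if (length(apical_active))
      cpp_plasticity(env$api_pre, env$api_w, active,
                     as.integer(apical_active), integer(0),
                     env$n_units, distal_lr)
    env$learn_steps <- env$learn_steps + 1L
    if (cfg$prune_period > 0L &&
        env$learn_steps %% cfg$prune_period == 0L) {
      if (env$has_lateral) {
        w <- env$lat_w
        w[w < cfg$prune_floor] <- 0
        env$lat_w <- w
      }
      w <- env$api_w
      w[w < cfg$prune_floor] <- 0
      env$api_w <- w
    }
  }
  # (5) the current activation becomes the next word's lateral context
  env$prev <- active
  list(active = active, mfe = mfe)
}

som_update_fast <- function(Wt, x, exc, alpha, sigma, lattice_d2) {
  if (alpha <= 0) return(Wt)
  bmu <- which.max(exc)
  ah <- alpha * exp(-lattice_d2[, bmu] / (2 * sigma^2))
  Wt + (x - Wt) * rep(ah, each = nrow(Wt))
}

#' Single word event of the encoder
#'
#' Runs one activation step: dendritic predictions from the previous EL
#' activation (lateral) and the supplied category SDR (apical), stochastic
#' afferent excitation of each column's cluster, winner-take-all inhibition
#' (rank by best-branch overlap, then afferent excitation, then lowest unit
#' id), or a massive firing event of the whole excited cluster when fewer
#' than `sdr_min_predicted` excited units are predicted. With `learn = TRUE`
#' the SOMs, lateral and apical synapse tables are updated and pruning runs
#' on schedule.
#'
#' @param enc an [el_encoder()].
#' @param word_vector full embedding vector (length `input_rows *
#'   input_cols`).
#' @param apical_active integer ids of the active units of the word's
#'   category SDR (see [build_category_sdrs()]); may be empty.
#' @param learn logical.
#' @param alpha,sigma,distal_lr learning parameters for this step (ignored
#'   unless `learn`).
#' @return list with `enc` (updated encoder) and `activation`: a list with
#'   `active` (global unit ids) and `mfe` (per-column logical flags).
#' @export
encoder_step <- function(enc, word_vector, apical_active = integer(0),
                         learn = FALSE, alpha = 0.05, sigma = 1,
                         distal_lr = 0.05) {
  if (length(word_vector) != input_size(enc$config))
    stop("input error: word vector length ", length(word_vector),
         " does not match the ", input_size(enc$config),
         "-component input grid", call. = FALSE)
  if (length(apical_active) &&
      max(apical_active) > n_units(enc$config))
    stop("structural error: apical SDR does not conform to the foreign ",
         "layer geometry", call. = FALSE)
  env <- encoder_as_env(enc)
  act <- step_core(env, as.numeric(word_vector), apical_active, learn,
                   alpha, sigma, distal_lr)
  list(enc = env_into_encoder(env, enc), activation = act)
}

# Resolve corpus tokens to embedding rows. Case-sensitive match first, then
# lowercased fallback. Returns row indices with NA for OOV.
match_embeddings <- function(tokens, embeddings) {
  idx <- match(tokens, rownames(embeddings))
  miss <- is.na(idx)
  if (any(miss))
    idx[miss] <- match(tolower(tokens[miss]), tolower(rownames(embeddings)))
  idx
}

#' Train the encoder on a tagged corpus
#'
#' Runs the multi-stage training schedule: by default two stages of two
#' passes each with exponentially decaying SOM learning rate, neighborhood
#' radius and distal learning rate, then one pass at the fixed final values
#' (see [el_schedule()]). Lateral context is reset at every sentence start.
#' Out-of-vocabulary tokens are skipped (or presented as zero vectors with
#' `oov = "zero"`) and counted. The SOMs are initialized from the
#' per-component range of the first observed inputs on the first call.
#'
#' @param enc an [el_encoder()] (untrained or to be trained further).
#' @param corpus a [tagged_corpus()] with coarse categories.
#' @param embeddings numeric matrix of word vectors, one row per surface
#'   form (rownames), `input_rows * input_cols` columns.
#' @param sdrs an [build_category_sdrs()] result; built from the encoder's
#'   seed when omitted.
#' @param oov `"skip"` (default) or `"zero"`.
#' @param seed seed for the stochastic activations; derived from the
#'   encoder's seed when omitted.
#' @param verbose print per-pass progress.
#' @return the trained encoder; `$log` holds one row per pass with the MFE
#'   rate (fraction of column events that were massive firing events) and
#'   the schedule values at the pass boundaries.
#' @export
train_encoder <- function(enc, corpus, embeddings, sdrs = NULL,
                          oov = c("skip", "zero"), seed = NULL,
                          verbose = FALSE) {
  stopifnot(inherits(enc, "el_encoder"), inherits(corpus, "tagged_corpus"))
  oov <- match.arg(oov)
  cfg <- enc$config
  if (length(corpus$sentences) == 0L)
    stop("empty corpus", call. = FALSE)
  if (ncol(embeddings) != input_size(cfg))
    stop("configuration error: embedding dimension ", ncol(embeddings),
         " does not match the ", input_size(cfg), "-component input grid",
         call. = FALSE)
  sdrs <- sdrs %||% build_category_sdrs(cfg, enc$seed)
  tokens <- unlist(corpus$sentences)
  idx <- match_embeddings(tokens, embeddings)
  n_oov <- sum(is.na(idx))
  cat_by_word <- unlist(corpus$coarse_categories)
  sent_of_word <- rep(seq_along(corpus$sentences),
                      lengths(corpus$sentences))
  keep <- if (oov == "skip") !is.na(idx) else rep(TRUE, length(idx))
  wordvecs <- matrix(0, length(tokens), ncol(embeddings))
  wordvecs[!is.na(idx), ] <- embeddings[idx[!is.na(idx)], , drop = FALSE]

  env <- encoder_as_env(enc)
  if (!enc$som_initialized) {
    first <- which(keep)[seq_len(min(1000L, sum(keep)))]
    with_seed(derive_seed(seed %||% enc$seed, "som"), {
      for (cc in seq_len(env$n_cols)) {
        obs <- t(wordvecs[first, env$aff[, cc], drop = FALSE])
        env$som[[cc]] <- som_init(cfg$afferent_inputs, env$upc, obs)
      }
    })
    enc$som_initialized <- TRUE
  }

  schedule <- cfg$schedule
  words_by_sent <- split(seq_along(tokens), sent_of_word)
  apical_now <- cfg$apical_timing == "current"
  log <- list()
  pass_no <- 0L
  with_seed(derive_seed(seed %||% enc$seed, "activation"), {
    for (s in seq_along(schedule)) {
      st <- schedule[[s]]
      n_words_pass <- sum(keep)
      total <- st$passes * n_words_pass
      step <- 0L
      for (p in seq_len(st$passes)) {
        pass_no <- pass_no + 1L
        mfe_events <- 0; col_events <- 0
        alpha0 <- decay_schedule(st$alpha[1], st$alpha[2], step, total)
        for (ws in words_by_sent) {
          env$prev <- integer(0)
          prev_cat <- integer(0)
          for (wi in ws) {
            if (!keep[wi]) next
            alpha <- decay_schedule(st$alpha[1], st$alpha[2], step, total)
            sigma <- decay_schedule(st$sigma[1], st$sigma[2], step, total)
            dlr <- decay_schedule(st$distal_lr[1], st$distal_lr[2], step,
                                  total)
            apical <- if (apical_now) sdrs[[cat_by_word[wi]]] else prev_cat
            act <- step_core(env, wordvecs[wi, ], apical, learn = TRUE,
                             alpha = alpha, sigma = sigma, distal_lr = dlr)
            prev_cat <- sdrs[[cat_by_word[wi]]]
            mfe_events <- mfe_events + sum(act$mfe)
            col_events <- col_events + env$n_cols
            step <- step + 1L
          }
        }
        log[[pass_no]] <- data.frame(
          stage = s, pass = pass_no, mfe_rate = mfe_events / col_events,
          alpha_start = alpha0,
          alpha_end = decay_schedule(st$alpha[1], st$alpha[2], step, total),
          distal_lr_end = decay_schedule(st$distal_lr[1], st$distal_lr[2],
                                         step, total))
        if (verbose)
          message(sprintf("stage %d pass %d: MFE rate %.3f", s, pass_no,
                          log[[pass_no]]$mfe_rate))
      }
    }
  })
  enc <- env_into_encoder(env, enc)
  enc$prev_active <- integer(0)
  enc$trained <- TRUE
  enc$log <- do.call(rbind, log)
  enc$oov_skipped <- n_oov
  enc
}

#' Run the encoder in inference mode
#'
#' Processes a corpus with learning disabled: no weight changes, lateral
#' context reset at every sentence start, activations returned per word in
#' order. The model state is bitwise identical before and after.
#'
#' @param object a trained [el_encoder()].
#' @param corpus a [tagged_corpus()].
#' @param embeddings word-vector matrix as in [train_encoder()].
#' @param sdrs category SDRs as in [train_encoder()].
#' @param type `"activations"` returns the activation records;
#'   `"features"` additionally builds the sparse binary feature matrix.
#' @param seed seed for the stochastic excitation draws.
#' @param oov out-of-vocabulary policy, as in [train_encoder()].
#' @param ... unused.
#' @return an object of class `el_activations`: list with `meta` (data frame
#'   of sentence, position, word, tag, coarse category, MFE column count),
#'   `active` (list of global unit-id vectors), `n_units`, and, for
#'   `type = "features"`, a sparse `features` matrix (words x units).
#' @export
predict.el_encoder <- function(object, corpus, embeddings, sdrs = NULL,
                               type = c("activations", "features"),
                               seed = 1L, oov = c("skip", "zero"), ...) {
  type <- match.arg(type)
  oov <- match.arg(oov)
  cfg <- object$config
  stopifnot(inherits(corpus, "tagged_corpus"))
  if (length(corpus$sentences) == 0L) stop("empty corpus", call. = FALSE)
  sdrs <- sdrs %||% build_category_sdrs(cfg, object$seed)
  tokens <- unlist(corpus$sentences)
  idx <- match_embeddings(tokens, embeddings)
  keep <- if (oov == "skip") !is.na(idx) else rep(TRUE, length(idx))
  wordvecs <- matrix(0, length(tokens), ncol(embeddings))
  wordvecs[!is.na(idx), ] <- embeddings[idx[!is.na(idx)], , drop = FALSE]
  cat_by_word <- unlist(corpus$coarse_categories)
  tag_by_word <- unlist(corpus$fine_tags)
  sent_of_word <- rep(seq_along(corpus$sentences),
                      lengths(corpus$sentences))
  pos_of_word <- unlist(lapply(lengths(corpus$sentences), seq_len))

  env <- encoder_as_env(object)
  active <- vector("list", length(tokens))
  mfe_cols <- integer(length(tokens))
  words_by_sent <- split(seq_along(tokens), sent_of_word)
  apical_now <- cfg$apical_timing == "current"
  with_seed(derive_seed(seed, "activation"), {
    for (ws in words_by_sent) {
      env$prev <- integer(0)
      prev_cat <- integer(0)
      for (wi in ws) {
        if (!keep[wi]) { active[[wi]] <- integer(0); next }
        apical <- if (apical_now) sdrs[[cat_by_word[wi]]] else prev_cat
        act <- step_core(env, wordvecs[wi, ], apical, learn = FALSE)
        prev_cat <- sdrs[[cat_by_word[wi]]]
        active[[wi]] <- act$active
        mfe_cols[wi] <- sum(act$mfe)
      }
    }
  })
  out <- list(
    meta = data.frame(sentence = sent_of_word, position = pos_of_word,
                      word = tokens, tag = tag_by_word,
                      coarse = cat_by_word, mfe_columns = mfe_cols,
                      oov = !keep, stringsAsFactors = FALSE),
    active = active, n_units = n_units(cfg), config = cfg)
  class(out) <- "el_activations"
  if (type == "features") out$features <- activation_features(out)
  out
}

#' Sparse binary feature matrix of an activation sequence
#'
#' @param acts an `el_activations` object from [predict.el_encoder()].
#' @return a `dgCMatrix` (words x units) of 0/1 presence indicators.
#' @export
activation_features <- function(acts) {
  stopifnot(inherits(acts, "el_activations"))
  n <- length(acts$active)
  i <- rep.int(seq_len(n), lengths(acts$active))
  j <- unlist(acts$active)
  Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, acts$n_units))
}

#' @export
print.el_encoder <- function(x, ...) {
  cat(sprintf("Encoder layer (%s%s): %d columns x %d units\n",
              if (x$trained) "trained" else "untrained",
              if (x$has_lateral) "" else ", lateral stripped",
              n_columns(x$config), units_per_column(x$config)))
  if (!is.null(x$log))
    cat(sprintf("  final-pass MFE rate: %.3f over %d passes\n",
                x$log$mfe_rate[nrow(x$log)], nrow(x$log)))
  invisible(x)
}

#' @export
summary.el_encoder <- function(object, ...) {
  cen <- synapse_census(object)
  cat("Encoder layer summary\n")
  print(object$config)
  cat(sprintf("  units: %d, proximal synapses: %d, distal potential: %d (%d/unit)\n",
              cen$total_units, cen$proximal_synapses,
              cen$distal_potential_synapses_total, cen$distal_per_unit))
  if (object$has_lateral)
    cat(sprintf("  lateral sparseness: %.3f\n",
                table_sparseness(object$lateral)))
  cat(sprintf("  apical sparseness : %.3f\n",
              table_sparseness(object$apical)))
  if (!is.null(object$log)) {
    cat("  training passes:\n")
    print(object$log, row.names = FALSE)
  }
  invisible(object)
}

#' Distal sparseness of a trained encoder
#'
#' Fraction of distal potential synapses whose weight is below the
#' established threshold, over the requested pathways.
#'
#' @param enc an [el_encoder()].
#' @param pathway `"both"`, `"lateral"` or `"apical"`.
#' @return sparseness in `[0, 1]`.
#' @export
distal_sparseness <- function(enc, pathway = c("both", "lateral", "apical")) {
  pathway <- match.arg(pathway)
  est <- enc$config$established_threshold
  ws <- list()
  if (pathway %in% c("both", "lateral") && enc$has_lateral)
    ws <- c(ws, list(enc$lateral$w))
  if (pathway %in% c("both", "apical"))
    ws <- c(ws, list(enc$apical$w))
  total <- sum(vapply(ws, length, 1L))
  if (total == 0L) return(NA_real_)
  sum(vapply(ws, function(w) sum(w < est), 1)) / total
}

#' Save / load an encoder checkpoint
#'
#' Versioned binary container (RDS) holding the full model state, including
#' SOM weights per column and the sparse distal weight tables.
#'
#' @param enc an [el_encoder()].
#' @param path file path.
#' @return `write_encoder` returns `path` invisibly; `read_encoder` the
#'   encoder.
#' @export
write_encoder <- function(enc, path) {
  stopifnot(inherits(enc, "el_encoder"))
  saveRDS(list(format = "elgram-checkpoint", version = 1L, encoder = enc),
          path)
  invisible(path)
}

#' @rdname write_encoder
#' @export
read_encoder <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "elgram-checkpoint"))
    stop("not an encoder checkpoint: ", path, call. = FALSE)
  x$encoder
}
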