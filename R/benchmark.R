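#' End-to-end synthetic grammar-bootstrap experiment
#'
#' The desk-scale analogue of the full evaluation: generates a synthetic
#' lexicon and tagged corpora, trains one encoder per seed (optionally also
#' a separately trained stripped-lateral instance), extracts features for a
#' training corpus and a set of held-out corpora, trains linear SVMs per
#' feature source, and compares sources with paired t-tests over the
#' per-corpus accuracies (averaged over encoder seeds), Holm-Bonferroni
#' corrected with factor 3.
#'
#' Feature sources: `encoder` (flattened EL SDR/MFE activations),
#' `embeddings` (the raw word vectors) and, when `include_lesion`,
#' `stripped` (activations of the stripped-lateral instance). The C sweep
#' runs once per source on the first seed's features (on a stratified
#' subsample of the training tokens); the chosen C is reused across seeds,
#' with the final models always refit on the full training features.
#'
#' @param config an [el_config()]; the scaled configuration by default.
#' @param seed corpus/lexicon seed (one fixed data set per benchmark).
#' @param encoder_seeds integer vector; one full (and optionally one
#'   lesioned) encoder is trained per seed.
#' @param n_train training-corpus sentences.
#' @param n_test_corpora,n_test_sentences held-out corpora count and size.
#' @param include_lesion also train and evaluate the stripped-lateral
#'   variant.
#' @param include_embeddings include the raw-embedding source.
#' @param holm_factor correction factor for the source comparisons.
#' @param cv_subsample cap on sweep examples (see [fit_classifier()]).
#' @param verbose print progress.
#' @return an object of class `el_benchmark`: list with `accuracy`
#'   (seed x corpus x source array, percent), `mean_accuracy` (corpora x
#'   sources), `comparisons`, `per_tag` (averaged over seeds), `report`
#'   (the [run_experiment()] result of the last seed), `sparseness`
#'   (per-seed distal sparseness of the trained full encoders),
#'   `contract` (observed SDR/MFE activation sizes), `train_log` (first
#'   seed), `lexicon`, `config`.
#' @export
el_benchmark <- function(config = el_config_scaled(), seed = 1L,
                         encoder_seeds = 1:10, n_train = 600L,
                         n_test_corpora = 10L, n_test_sentences = 150L,
                         include_lesion = TRUE, include_embeddings = TRUE,
                         holm_factor = 3, cv_subsample = 1500L,
                         verbose = FALSE) {
  lex <- make_lexicon(dim = input_size(config), seed = seed)
  train_corpus <- make_corpus(lex, n_sentences = n_train, seed = seed)
  test_corpora <- lapply(seq_len(n_test_corpora), function(k)
    make_corpus(lex, n_sentences = n_test_sentences,
                seed = derive_seed(seed, "corpus", k)))
  sdrs <- build_category_sdrs(config, seed)
  emb <- lex$embeddings

  emb_feats <- function(corpus) {
    toks <- unlist(corpus$sentences)
    emb[match_embeddings(toks, emb), , drop = FALSE]
  }
  labels <- list(train = unlist(train_corpus$fine_tags),
                 test = lapply(test_corpora, function(cc)
                   unlist(cc$fine_tags)))

  sources <- c("encoder", if (include_lesion) "stripped",
               if (include_embeddings) "embeddings")
  n_seed <- length(encoder_seeds)
  acc <- array(NA_real_, c(n_seed, n_test_corpora, length(sources)),
               dimnames = list(NULL, NULL, sources))
  per_tag_acc <- list(); sparseness <- numeric(n_seed)
  contract <- list(max_sdr_active = 0L, mfe_sizes = integer(0))
  train_log <- NULL; report <- NULL; chosen_c <- NULL

  for (i in seq_len(n_seed)) {
    es <- encoder_seeds[i]
    if (verbose) message("encoder seed ", es)
    feats <- list()
    enc <- train_encoder(el_encoder(config, es), train_corpus, emb,
                         sdrs = sdrs, verbose = verbose)
    if (i == 1L) train_log <- enc$log
    sparseness[i] <- distal_sparseness(enc)
    models <- list(encoder = enc)
    if (include_lesion)
      models$stripped <- train_encoder(strip_lateral(el_encoder(config, es)),
                                       train_corpus, emb, sdrs = sdrs)
    for (s in names(models)) {
      tr <- predict(models[[s]], train_corpus, emb, sdrs = sdrs,
                    type = "features", seed = derive_seed(es, "activation"))
      te <- lapply(seq_along(test_corpora), function(k)
        predict(models[[s]], test_corpora[[k]], emb, sdrs = sdrs,
                type = "features",
                seed = derive_seed(es, "activation", k)))
      if (s == "encoder" && i == 1L) {
        # audit the sparsity contract on the first seed's activations:
        # per-column active counts for non-MFE (SDR) and MFE columns
        upc <- units_per_column(config)
        nc <- n_columns(config)
        k_mfe <- excited_size(config)
        for (wi in seq_along(tr$active)) {
          ids <- tr$active[[wi]]
          if (!length(ids)) next
          cnt <- tabulate((ids - 1L) %/% upc + 1L, nc)
          # SDR columns hold at most winners_per_cc active units, MFE
          # columns exactly the excited-cluster size (2 < 4 here, so the
          # count separates the two event kinds)
          contract$max_sdr_active <- max(contract$max_sdr_active,
                                         cnt[cnt != k_mfe], 0L)
          if (tr$meta$mfe_columns[wi] > 0L)
            contract$mfe_sizes <- unique(c(contract$mfe_sizes,
                                           cnt[cnt == k_mfe]))
        }
      }
      feats[[s]] <- list(train = as.matrix(tr$features),
                         test = lapply(te, function(a)
                           as.matrix(a$features)))
    }
    if (include_embeddings)
      feats$embeddings <- list(train = emb_feats(train_corpus),
                               test = lapply(test_corpora, emb_feats))
    # probability tables (and the probability-model fits they require) are
    # emitted for the last seed's report only
    rep_i <- run_experiment(feats, labels, holm_factor = holm_factor,
                            seed = derive_seed(es, "svm"),
                            cv_subsample = cv_subsample,
                            fixed_c = chosen_c,
                            prob_corpus = if (i == n_seed) 1L else NULL)
    chosen_c <- chosen_c %||% rep_i$chosen_c
    for (s in sources) acc[i, , s] <- rep_i$accuracy[, s]
    per_tag_acc[[i]] <- rep_i$per_tag
    report <- rep_i
  }

  mean_acc <- apply(acc, c(2, 3), mean)
  pairs <- utils::combn(sources, 2L)
  comparisons <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    pc <- paired_comparison(mean_acc[, a], mean_acc[, b])
    data.frame(source_a = a, source_b = b, mean_diff = pc$mean_diff,
               t = pc$t, df = pc$df, p = pc$p, degenerate = pc$degenerate,
               stringsAsFactors = FALSE)
  }))
  ok <- !is.na(comparisons$p)
  comparisons$p_adjusted <- NA_real_
  if (any(ok))
    comparisons$p_adjusted[ok] <-
      holm_bonferroni(comparisons$p[ok], max(holm_factor, sum(ok)))

  # per-tag accuracies averaged over seeds, per source
  tags <- sort(unique(labels$train))
  per_tag <- lapply(setNames(sources, sources), function(s) {
    ms <- sapply(per_tag_acc, function(pt) {
      v <- setNames(pt[[s]]$accuracy, pt[[s]]$tag)[tags]
      v
    })
    sup <- setNames(per_tag_acc[[1L]][[s]]$support,
                    per_tag_acc[[1L]][[s]]$tag)[tags]
    data.frame(tag = tags, support = as.integer(sup),
               accuracy = rowMeans(ms, na.rm = TRUE),
               row.names = NULL, stringsAsFactors = FALSE)
  })

  structure(list(accuracy = acc, mean_accuracy = mean_acc,
                 comparisons = comparisons, per_tag = per_tag,
                 report = report, sparseness = sparseness,
                 contract = contract, train_log = train_log,
                 lexicon = lex, config = config, seeds = encoder_seeds,
                 chosen_c = chosen_c),
            class = "el_benchmark")
}

#' @export
print.el_benchmark <- function(x, ...) {
  cat("Synthetic grammar-bootstrap benchmark\n")
  m <- colMeans(x$mean_accuracy)
  for (s in names(m)) cat(sprintf("  %-10s mean accuracy %6.2f%%\n", s, m[s]))
  print(x$comparisons[, c("source_a", "source_b", "mean_diff", "t", "p",
                          "p_adjusted")], row.names = FALSE)
  cat(sprintf("  distal sparseness of trained encoders: %.3f-%.3f\n",
              min(x$sparseness), max(x$sparseness)))
  invisible(x)
}

#' Massive-firing-event profile on a single repeated sentence
#'
#' Trains the encoder on a deterministic corpus consisting of one sentence
#' and reports the per-pass MFE rate (fraction of column events that were
#' massive firing events) for each seed: the signature of sequence learning
#' is a first pass at (or near) 100% and a final pass near zero.
#'
#' @param config an [el_config()].
#' @param seeds encoder seeds.
#' @param sentence_length words in the repeated sentence.
#' @param lexicon_seed seed for the synthetic lexicon/sentence.
#' @return matrix (passes x seeds) of MFE rates.
#' @export
repeated_sentence_mfe <- function(config = el_config_scaled(),
                                  seeds = 1:5, sentence_length = 8L,
                                  lexicon_seed = 1L) {
  lex <- make_lexicon(dim = input_size(config), seed = lexicon_seed)
  base <- make_corpus(lex, n_sentences = 50L, seed = lexicon_seed)
  # probe with a sentence free of repeated embeddings, so that first-pass
  # predictions cannot arise from within-sentence token recurrence
  emb_key <- lapply(base$sentences, function(s) {
    rows <- match_embeddings(s, lex$embeddings)
    apply(lex$embeddings[rows, , drop = FALSE], 1L, paste, collapse = ",")
  })
  ok <- vapply(emb_key, function(k) !anyDuplicated(k), TRUE)
  pick <- which(ok & lengths(base$sentences) >= sentence_length)[1L]
  if (is.na(pick)) pick <- which.max(lengths(base$sentences) * ok)
  corpus <- tagged_corpus(base$sentences[pick], base$fine_tags[pick],
                          base$coarse_categories[pick])
  sdrs <- build_category_sdrs(config, lexicon_seed)
  out <- sapply(seeds, function(es) {
    enc <- train_encoder(el_encoder(config, es), corpus, lex$embeddings,
                         sdrs = sdrs)
    enc$log$mfe_rate
  })
  colnames(out) <- paste0("seed", seeds)
  out
}
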