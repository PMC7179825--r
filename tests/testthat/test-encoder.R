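# Small fixture: scaled encoder + tiny synthetic corpus, built once.
enc_fixture <- function() {
  cached("enc_fixture", {
    cfg <- el_config_scaled()
    lex <- make_lexicon(dim = 30, seed = 4)
    corpus <- make_corpus(lex, n_sentences = 40, seed = 4)
    sdrs <- build_category_sdrs(cfg, 4)
    list(cfg = cfg, lex = lex, corpus = corpus, sdrs = sdrs)
  })
}

test_that("an untrained encoder fires a full massive firing event on any word", {
  fx <- enc_fixture()
  enc <- el_encoder(fx$cfg, seed = 1)
  wv <- fx$lex$embeddings[1, ]
  out <- encoder_step(enc, wv, apical_active = fx$sdrs$content)
  # every column bursts: no distal synapse starts established
  expect_true(all(out$activation$mfe))
  expect_length(out$activation$active, 25L * 4L)  # floor(0.1 * 49) per column
  expect_error(encoder_step(enc, wv[1:10]), "input error")
  expect_error(encoder_step(enc, wv, apical_active = 99999L),
               "structural error")
})

test_that("flattening emits sorted global indices with the contracted sizes", {
  cfg <- el_config()
  # an all-SDR activation: 2 winners in each of 225 columns
  ids <- as.integer(outer(c(1L, 2L), (0:224) * 225L, "+"))
  flat <- flatten_activation(ids, cfg)
  expect_length(flat, 450L)
  expect_identical(flat, sort(ids))
  expect_length(flatten_activation(integer(0), cfg), 0L)
  # full-MFE activation: 22 excited units per column
  mfe_ids <- as.integer(outer(1:22, (0:224) * 225L, "+"))
  expect_length(flatten_activation(mfe_ids, cfg), 4950L)
  expect_error(flatten_activation(1e6L, cfg), "structural error")
})

test_that("context reset clears lateral predictions and is idempotent", {
  fx <- enc_fixture()
  enc <- el_encoder(fx$cfg, seed = 2)
  out <- encoder_step(enc, fx$lex$embeddings[3, ], fx$sdrs$verb)
  expect_gt(length(out$enc$prev_active), 0L)
  r1 <- reset_context(out$enc)
  expect_length(r1$prev_active, 0L)
  expect_identical(reset_context(r1)$prev_active, r1$prev_active)
})

test_that("training requires aligned non-empty input and logs the schedule", {
  fx <- enc_fixture()
  enc <- el_encoder(fx$cfg, seed = 1)
  expect_error(tagged_corpus(list(), list()), "empty corpus")
  trained <- cached("trained_tiny", train_encoder(enc, fx$corpus,
                                                  fx$lex$embeddings,
                                                  sdrs = fx$sdrs))
  expect_true(trained$trained)
  expect_equal(nrow(trained$log), 5L)  # 2 + 2 + 1 passes
  # schedule audit: stage-1 logged starting rate equals the configured one
  expect_equal(trained$log$alpha_start[1], fx$cfg$schedule[[1]]$alpha[1])
  # learning progress: final pass has fewer MFEs than the first
  expect_lt(trained$log$mfe_rate[5], trained$log$mfe_rate[1])
  # embedding-dimension mismatch is rejected
  bad_emb <- fx$lex$embeddings[, 1:10]
  expect_error(train_encoder(el_encoder(fx$cfg, 1), fx$corpus, bad_emb),
               "configuration error")
})

test_that("inference is frozen: the checkpoint hashes identically before and after", {
  fx <- enc_fixture()
  trained <- cached("trained_tiny", train_encoder(el_encoder(fx$cfg, 1),
                                                  fx$corpus,
                                                  fx$lex$embeddings,
                                                  sdrs = fx$sdrs))
  f1 <- tempfile(); f2 <- tempfile()
  write_encoder(trained, f1)
  acts <- predict(trained, fx$corpus, fx$lex$embeddings, sdrs = fx$sdrs,
                  seed = 7)
  write_encoder(trained, f2)
  expect_identical(tools::md5sum(f1)[[1]], tools::md5sum(f2)[[1]])
  unlink(c(f1, f2))
  # same seed: identical activations; per-sentence reset means the first
  # word of every sentence has apical-only context
  acts2 <- predict(trained, fx$corpus, fx$lex$embeddings, sdrs = fx$sdrs,
                   seed = 7)
  expect_identical(acts$active, acts2$active)
})

test_that("differently seeded inference mostly agrees on SDR/MFE flags after convergent training", {
  # deterministic toy corpus: one sentence, trained to convergence
  fx <- enc_fixture()
  pick <- which(lengths(fx$corpus$sentences) >= 8)[1]
  toy <- tagged_corpus(fx$corpus$sentences[pick],
                       fx$corpus$fine_tags[pick],
                       fx$corpus$coarse_categories[pick])
  enc <- train_encoder(el_encoder(fx$cfg, 1), toy, fx$lex$embeddings,
                       sdrs = fx$sdrs)
  flags <- function(acts) {
    do.call(rbind, lapply(acts$active, function(ids)
      tabulate((ids - 1L) %/% 49L + 1L, 25L) == 4L))
  }
  a <- predict(enc, toy, fx$lex$embeddings, sdrs = fx$sdrs, seed = 1)
  b <- predict(enc, toy, fx$lex$embeddings, sdrs = fx$sdrs, seed = 2)
  expect_false(identical(a$active, b$active))
  expect_gte(mean(flags(a) == flags(b)), 0.9)
})

test_that("activation sizes respect the sparsity contract", {
  fx <- enc_fixture()
  trained <- cached("trained_tiny", train_encoder(el_encoder(fx$cfg, 1),
                                                  fx$corpus,
                                                  fx$lex$embeddings,
                                                  sdrs = fx$sdrs))
  acts <- predict(trained, fx$corpus, fx$lex$embeddings, sdrs = fx$sdrs,
                  seed = 3)
  upc <- 49L
  for (wi in seq_along(acts$active)) {
    cnt <- tabulate((acts$active[[wi]] - 1L) %/% upc + 1L, 25L)
    expect_true(all(cnt %in% c(0L, 1L, 2L, 4L)))
    expect_equal(sum(cnt == 4L), acts$meta$mfe_columns[wi])
  }
})

test_that("stripping the lateral pathway leaves an apical-only encoder", {
  fx <- enc_fixture()
  enc <- strip_lateral(el_encoder(fx$cfg, seed = 1))
  cen <- synapse_census(enc)
  expect_equal(cen$lateral_per_unit, 0L)
  expect_equal(cen$apical_per_unit, 48L)  # 8 linked columns x 6 synapses
  # stripping the full default architecture leaves the 648 apical synapses
  cen_full <- cached("stripped_full_census",
                     synapse_census(strip_lateral(el_encoder(el_config(),
                                                             seed = 1))))
  expect_equal(cen_full$distal_per_unit, 648L)
  # removing the apical drive as well reduces to a pure SOM layer: every
  # word is a massive firing event
  out <- encoder_step(enc, fx$lex$embeddings[5, ],
                      apical_active = integer(0))
  expect_true(all(out$activation$mfe))
})

test_that("out-of-vocabulary tokens are skipped and counted", {
  fx <- enc_fixture()
  corp <- tagged_corpus(list(c("n01", "unknowable", "v01s")),
                        list(c("NN", "NN", "VBZ")))
  enc <- train_encoder(el_encoder(fx$cfg, 1), corp, fx$lex$embeddings,
                       sdrs = fx$sdrs)
  expect_equal(enc$oov_skipped, 1L)
  acts <- predict(enc, corp, fx$lex$embeddings, sdrs = fx$sdrs)
  expect_true(acts$meta$oov[2])
  expect_length(acts$active[[2]], 0L)
})
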