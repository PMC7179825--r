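#' Coarse word-category SDRs of the foreign category layer
#'
#' Generates the three fixed sparse distributed representations — content,
#' function and verb — in a fictitious foreign cortical layer sharing the
#' EL's columnar and cellular configuration. For each category and each
#' column, `winners_per_cc` units are drawn uniformly without replacement;
#' the three SDRs are independent draws (no engineered orthogonality) and
#' fixed for the run.
#'
#' @param config an [el_config()].
#' @param seed integer seed; SDRs are reproducible per seed.
#' @return an object of class `el_category_sdrs`: a list with `content`,
#'   `function` and `verb` integer vectors of global active unit ids, plus
#'   `seed` and layer dimensions.
#' @export
build_category_sdrs <- function(config, seed = 1L) {
  upc <- units_per_column(config)
  nc <- n_columns(config)
  draw <- function() {
    unlist(lapply(seq_len(nc), function(cc)
      (cc - 1L) * upc + sort(sample.int(upc, config$winners_per_cc))))
  }
  with_seed(derive_seed(seed, "category"), {
    out <- list(content = draw(), "function" = draw(), verb = draw())
    if (config$winners_per_cc < upc &&
        (identical(out$content, out[["function"]]) ||
         identical(out$content, out$verb) ||
         identical(out[["function"]], out$verb)))
      warning("category SDRs collide; consider another seed")
    structure(c(out, list(seed = seed, n_units = nc * upc,
                          winners_per_cc = config$winners_per_cc)),
              class = "el_category_sdrs")
  })
}

#' Map fine grammatical tags to coarse categories
#'
#' Maps each tag to one of `content`, `function` or `verb`. Exact matches in
#' `table` win; otherwise parser-style `CLUSTER_POS` conjunction tags (e.g.
#' `N_NNS`, `V_VBD`, `P_IN`) are resolved by rule: noun, adjective and
#' adverb clusters are content words — except pronouns (`PRP`, `PRP$` POS),
#' which are function words; determiner, preposition, complementizer,
#' subordination/coordination-conjunction and particle clusters are function
#' words; verb clusters and any modal are verbs. Unknown tags raise a
#' mapping error naming the tags unless a `default` category is supplied.
#'
#' @param fine_tag character vector of tags.
#' @param table named character vector of exact-match overrides,
#'   [el_tag_table()] by default. Pronoun handling is overridable through it.
#' @param default optional fallback category for unmapped tags.
#' @return character vector of categories, same length as `fine_tag`.
#' @export
coarse_map <- function(fine_tag, table = el_tag_table(), default = NULL) {
  if (any(!nzchar(fine_tag)))
    stop("mapping error: empty tag", call. = FALSE)
  out <- unname(table[fine_tag])
  todo <- which(is.na(out))
  for (i in todo) {
    tag <- fine_tag[i]
    cluster <- sub("_.*$", "", tag)
    pos <- sub("^[^_]*_", "", tag)
    out[i] <-
      if (pos %in% c("PRP", "PRP$")) "function"
      else if (pos == "MD") "verb"
      else if (cluster %in% c("N", "ADJ", "ADV")) "content"
      else if (cluster %in% c("D", "P", "C", "SC", "CONJ", "PRT")) "function"
      else if (cluster == "V") "verb"
      else NA_character_
  }
  if (anyNA(out)) {
    if (is.null(default))
      stop("mapping error: unmapped tag(s): ",
           paste(unique(fine_tag[is.na(out)]), collapse = ", "),
           call. = FALSE)
    out[is.na(out)] <- default
  }
  out
}

#' Default fine-tag to coarse-category table
#'
#' Exact-match entries covering the bare Penn-style tag set emitted by the
#' synthetic grammar plus the pronoun overrides for parser-style tags.
#' Nouns, adjectives and adverbs are content words; determiners, pronouns,
#' prepositions, conjunctions and the infinitival marker are function words;
#' verb forms and modals are verbs.
#'
#' @return named character vector (tag -> category).
#' @export
el_tag_table <- function() {
  c(NN = "content", NNS = "content", JJ = "content", RB = "content",
    DT = "function", PRP = "function", "PRP$" = "function",
    IN = "function", CC = "function", TO = "function",
    VB = "verb", VBZ = "verb", VBP = "verb", VBD = "verb",
    VBN = "verb", VBG = "verb", MD = "verb")
}
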