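#' Synthetic lexicon with clustered embeddings and ambiguous homographs
#'
#' Generates a download-free lexicon with the statistical structure the
#' encoder exploits. Semantic classes are centroids drawn on the unit sphere
#' with pairwise distance at least four times the within-class noise
#' standard deviation; each surface form carries exactly one embedding
#' (class centroid, or sense-mixture centroid for homographs, plus Gaussian
#' noise).
#'
#' Deliberate ambiguity, mirroring what distributional vectors lose:
#' \itemize{
#'   \item noun number: the singular (`NN`) and plural (`NNS`) surface of a
#'     noun lexeme share an identical embedding, so number is observable
#'     only through the number-marked determiners and pronouns;
#'   \item verb agreement: a verb lexeme's base (`VB`/`VBP`) and 3rd-person
#'     (`VBZ`) surfaces share an identical embedding, so the tag is
#'     determined only by the left context (modal/infinitival marker versus
#'     subject number);
#'   \item homographs: a fraction of noun lexemes also act as verbs — the
#'     singular surface carries `NN` and `VB`/`VBP` senses, the plural
#'     surface `NNS` and `VBZ` senses, with a noun/verb mixture embedding —
#'     so the coarse word category is required to resolve them.
#' }
#'
#' The default lexeme counts give a token/type ratio of roughly 10-15 on
#' the default 600-sentence training corpus, matching the regime of natural
#' pre-cleaned text, with open-class lexemes spread over four noun, four
#' verb and two adjective semantic families.
#'
#' @param n_noun,n_verb,n_adj,n_adv lexeme counts per open class.
#' @param homograph_frac fraction of noun lexemes that are noun/verb
#'   homographs (at least 10% of all lexemes must end up with senses
#'   spanning different coarse categories).
#' @param dim embedding dimensionality (must equal the model's input grid
#'   size; 30 for the scaled configuration, 300 for the full one).
#' @param noise_sd within-class Gaussian noise standard deviation.
#' @param seed integer seed; generation is deterministic per seed.
#' @return an object of class `el_lexicon`: list with `words` (data frame
#'   of surface, tag, coarse, lexeme), `embeddings` (surface x dim matrix),
#'   and the generation parameters.
#' @export
make_lexicon <- function(n_noun = 60L, n_verb = 36L, n_adj = 18L,
                         n_adv = 12L, homograph_frac = 0.35, dim = 30L,
                         noise_sd = 0.2, seed = 1L) {
  with_seed(derive_seed(seed, "lexicon"), {
    noun_fams <- paste0("noun_", letters[1:4])
    verb_fams <- paste0("verb_", letters[1:4])
    adj_fams <- paste0("adj_", letters[1:2])
    fams <- c(noun_fams, verb_fams, adj_fams, "adv",
              "det_sg", "det_pl", "prp_sg", "prp_pl", "prep", "conj",
              "to", "md")
    centroids <- draw_centroids(length(fams), dim, 4 * noise_sd)
    rownames(centroids) <- fams
    emb <- function(fam, mix = NULL) {
      mu <- if (is.null(mix)) centroids[fam, ]
            else colMeans(centroids[c(fam, mix), , drop = FALSE])
      mu + rnorm(dim, 0, noise_sd)
    }
    rows <- list(); vecs <- list()
    add <- function(surface, tags, lexeme, vec) {
      rows[[length(rows) + 1L]] <<- data.frame(
        surface = surface, tag = tags, coarse = coarse_map(tags),
        lexeme = lexeme, stringsAsFactors = FALSE)
      if (is.null(vecs[[surface]])) vecs[[surface]] <<- vec
    }
    n_homo <- ceiling(homograph_frac * n_noun)
    for (i in seq_len(n_noun)) {
      fam <- noun_fams[(i - 1L) %% length(noun_fams) + 1L]
      lex <- sprintf("noun%02d", i)
      homograph <- i <= n_homo
      vfam <- verb_fams[(i - 1L) %% length(verb_fams) + 1L]
      e <- if (homograph) emb(fam, vfam) else emb(fam)
      sg <- sprintf("n%02d", i); pl <- sprintf("n%02ds", i)
      # singular and plural surfaces share one embedding: number is
      # deliberately invisible to the distributional vector
      add(sg, "NN", lex, e)
      add(pl, "NNS", lex, e)
      if (homograph) {
        add(sg, "VB", lex, e)
        add(sg, "VBP", lex, e)
        add(pl, "VBZ", lex, e)
      }
    }
    for (i in seq_len(n_verb)) {
      fam <- verb_fams[(i - 1L) %% length(verb_fams) + 1L]
      lex <- sprintf("verb%02d", i)
      e <- emb(fam)
      base <- sprintf("v%02d", i)
      add(base, "VB", lex, e)
      add(base, "VBP", lex, e)
      add(sprintf("v%02ds", i), "VBZ", lex, e)   # same embedding as base
      add(sprintf("v%02dd", i), "VBD", lex, emb(fam))  # own draw: tense is
      # recoverable from the vector, agreement is not
    }
    for (i in seq_len(n_adj))
      add(sprintf("adj%02d", i), "JJ", sprintf("adj%02d", i),
          emb(adj_fams[(i - 1L) %% length(adj_fams) + 1L]))
    for (i in seq_len(n_adv))
      add(sprintf("adv%02d", i), "RB", sprintf("adv%02d", i), emb("adv"))
    fun <- list(
      list(c("a1", "this1", "every1"), "DT", "det_sg"),
      list(c("many1", "these1", "two1"), "DT", "det_pl"),
      list(c("he1", "she1", "it1"), "PRP", "prp_sg"),
      list(c("they1", "we1"), "PRP", "prp_pl"),
      list(c("on1", "in1", "near1", "with1"), "IN", "prep"),
      list(c("and1", "but1"), "CC", "conj"),
      list("to1", "TO", "to"),
      list(c("can1", "will1", "must1"), "MD", "md"))
    for (f in fun)
      for (s in f[[1L]]) add(s, f[[2L]], s, emb(f[[3L]]))
    words <- do.call(rbind, rows)
    surfaces <- names(vecs)
    embeddings <- do.call(rbind, vecs)
    rownames(embeddings) <- surfaces
    multi <- tapply(words$coarse, words$lexeme,
                    function(x) length(unique(x)) > 1L)
    out <- list(words = words, embeddings = embeddings,
                params = list(n_noun = n_noun, n_verb = n_verb,
                              n_adj = n_adj, n_adv = n_adv,
                              homograph_frac = homograph_frac, dim = dim,
                              noise_sd = noise_sd, seed = seed),
                ambiguous_share = mean(multi))
    class(out) <- "el_lexicon"
    out
  })
}

# Centroids on the unit sphere with enforced pairwise separation.
draw_centroids <- function(n, dim, min_dist, max_tries = 200L) {
  for (try in seq_len(max_tries)) {
    x <- matrix(rnorm(n * dim), n, dim)
    x <- x / sqrt(rowSums(x^2))
    if (n < 2L || min(dist(x)) >= min_dist) return(x)
  }
  stop("generation error: cannot place ", n, " class centroids at pairwise ",
       "distance >= ", min_dist, " in ", dim, " dimensions", call. = FALSE)
}

#' Default probabilistic template grammar
#'
#' Clause structure `S -> NP VP [PP]` with optional coordination; noun
#' phrases are a number-marked determiner plus optional adjective and a
#' noun, or a pronoun; verb phrases inflect for subject number (`VBZ` after
#' singular, `VBP` after plural subjects), with past-tense, modal + base
#' form and infinitival `to` + base form alternatives, optional adverb and
#' optional object/prepositional phrase. Subject-verb number agreement is
#' enforced; determiners and pronouns are always number-marked so that every
#' tag is determined by the embedding, the coarse category and the left
#' context.
#'
#' @param p_coord,p_pp,p_adj,p_adv,p_prp_subject,p_past,p_md,p_to,p_object
#'   production probabilities.
#' @return a list of class `el_grammar`.
#' @export
make_grammar <- function(p_coord = 0.15, p_pp = 0.25, p_adj = 0.3,
                         p_adv = 0.15, p_prp_subject = 0.2, p_past = 0.25,
                         p_md = 0.15, p_to = 0.15, p_object = 0.55) {
  structure(list(p_coord = p_coord, p_pp = p_pp, p_adj = p_adj,
                 p_adv = p_adv, p_prp_subject = p_prp_subject,
                 p_past = p_past, p_md = p_md, p_to = p_to,
                 p_object = p_object),
            class = "el_grammar")
}

#' Generate a tagged corpus from the template grammar
#'
#' Draws `n_sentences` sentences from the probabilistic grammar over the
#' lexicon, emitting aligned tokens, fine tags and coarse categories.
#' Homographs are emitted in contexts that determine their tag (noun senses
#' inside noun phrases, verb senses after subjects, modals or the
#' infinitival marker).
#'
#' @param lexicon an [make_lexicon()] result.
#' @param grammar an [make_grammar()] result.
#' @param n_sentences number of sentences (> 0).
#' @param seed integer seed.
#' @return a [tagged_corpus()].
#' @export
make_corpus <- function(lexicon, grammar = make_grammar(), n_sentences,
                        seed = 1L) {
  stopifnot(inherits(lexicon, "el_lexicon"),
            inherits(grammar, "el_grammar"))
  if (is.null(n_sentences) || n_sentences < 1L)
    stop("empty corpus requested", call. = FALSE)
  w <- lexicon$words
  pool <- function(tag) w$surface[w$tag == tag]
  pools <- setNames(lapply(unique(w$tag), pool), unique(w$tag))
  if (any(lengths(pools) == 0L))
    stop("empty grammar pools", call. = FALSE)
  pick <- function(tag) sample(pools[[tag]], 1L)
  g <- grammar
  with_seed(derive_seed(seed, "corpus"), {
    sents <- vector("list", n_sentences)
    tags <- vector("list", n_sentences)
    for (si in seq_len(n_sentences)) {
      emit_np <- function(number = NULL) {
        number <- number %||% sample(c("sg", "pl"), 1L)
        if (runif(1) < g$p_prp_subject) {
          # pronouns are split by number through their surface pools
          prp_pool <- w$surface[w$tag == "PRP" &
                                  grepl(if (number == "sg") "^(he|she|it)"
                                        else "^(they|we)", w$surface)]
          s <- sample(prp_pool, 1L)
          list(tokens = s, tags = "PRP", number = number)
        } else {
          det_pool <- w$surface[w$tag == "DT" &
                                  grepl(if (number == "sg")
                                          "^(a1|this1|every1)$"
                                        else "^(many1|these1|two1)$",
                                        w$surface)]
          toks <- sample(det_pool, 1L); tgs <- "DT"
          if (runif(1) < g$p_adj) {
            toks <- c(toks, pick("JJ")); tgs <- c(tgs, "JJ")
          }
          ntag <- if (number == "sg") "NN" else "NNS"
          toks <- c(toks, pick(ntag)); tgs <- c(tgs, ntag)
          list(tokens = toks, tags = tgs, number = number)
        }
      }
      emit_vp <- function(number) {
        toks <- character(0); tgs <- character(0)
        if (runif(1) < g$p_adv) {
          toks <- c(toks, pick("RB")); tgs <- c(tgs, "RB")
        }
        r <- runif(1)
        if (r < g$p_md) {
          toks <- c(toks, pick("MD"), pick("VB"))
          tgs <- c(tgs, "MD", "VB")
        } else if (r < g$p_md + g$p_past) {
          toks <- c(toks, pick("VBD")); tgs <- c(tgs, "VBD")
        } else {
          vtag <- if (number == "sg") "VBZ" else "VBP"
          toks <- c(toks, pick(vtag)); tgs <- c(tgs, vtag)
        }
        if (runif(1) < g$p_to) {
          toks <- c(toks, pick("TO"), pick("VB")); tgs <- c(tgs, "TO", "VB")
        }
        if (runif(1) < g$p_object) {
          np <- emit_np()
          toks <- c(toks, np$tokens); tgs <- c(tgs, np$tags)
        }
        list(tokens = toks, tags = tgs)
      }
      emit_clause <- function() {
        np <- emit_np()
        vp <- emit_vp(np$number)
        toks <- c(np$tokens, vp$tokens); tgs <- c(np$tags, vp$tags)
        if (runif(1) < g$p_pp) {
          obj <- emit_np()
          toks <- c(toks, pick("IN"), obj$tokens)
          tgs <- c(tgs, "IN", obj$tags)
        }
        list(tokens = toks, tags = tgs)
      }
      cl <- emit_clause()
      if (runif(1) < g$p_coord) {
        cl2 <- emit_clause()
        cl <- list(tokens = c(cl$tokens, pick("CC"), cl2$tokens),
                   tags = c(cl$tags, "CC", cl2$tags))
      }
      sents[[si]] <- cl$tokens
      tags[[si]] <- cl$tags
    }
    tagged_corpus(sents, tags,
                  meta = list(generator = "elgram-template-grammar",
                              seed = seed, grammar = unclass(g)))
  })
}

#' @export
print.el_lexicon <- function(x, ...) {
  cat(sprintf(
    "Synthetic lexicon: %d surfaces, %d sense entries, %d-d embeddings\n",
    nrow(x$embeddings), nrow(x$words), ncol(x$embeddings)))
  cat(sprintf("  surfaces with senses across coarse categories: %.1f%%\n",
              100 * x$ambiguous_share))
  invisible(x)
}
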