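#' Aligned tagged corpus
#'
#' Bundles sentences, fine grammatical tags and coarse categories with full
#' alignment checking: per sentence the token, fine-tag and category counts
#' must agree, sentences must be non-empty and tokens whitespace-free.
#' Coarse categories are derived from the fine tags through [coarse_map()]
#' when not supplied.
#'
#' @param sentences list of character token vectors.
#' @param fine_tags list of character tag vectors, aligned.
#' @param coarse_categories optional list of category vectors, aligned.
#' @param meta optional provenance list.
#' @return an object of class `tagged_corpus`.
#' @export
tagged_corpus <- function(sentences, fine_tags, coarse_categories = NULL,
                          meta = list()) {
  if (length(sentences) == 0L) stop("empty corpus", call. = FALSE)
  if (length(fine_tags) != length(sentences))
    stop("alignment error: ", length(sentences), " sentences but ",
         length(fine_tags), " tag blocks", call. = FALSE)
  for (i in seq_along(sentences)) {
    if (length(sentences[[i]]) == 0L)
      stop("alignment error: empty sentence ", i, call. = FALSE)
    if (any(grepl("\\s", sentences[[i]])))
      stop("alignment error: whitespace inside a token of sentence ", i,
           call. = FALSE)
    if (length(fine_tags[[i]]) != length(sentences[[i]]))
      stop("alignment error: sentence ", i, " has ",
           length(sentences[[i]]), " tokens but ", length(fine_tags[[i]]),
           " tags", call. = FALSE)
  }
  if (is.null(coarse_categories)) {
    coarse_categories <- lapply(fine_tags, coarse_map)
  } else {
    for (i in seq_along(sentences))
      if (length(coarse_categories[[i]]) != length(sentences[[i]]))
        stop("alignment error: sentence ", i, " has ",
             length(sentences[[i]]), " tokens but ",
             length(coarse_categories[[i]]), " categories", call. = FALSE)
  }
  structure(list(sentences = sentences, fine_tags = fine_tags,
                 coarse_categories = coarse_categories, meta = meta),
            class = "tagged_corpus")
}

#' @export
print.tagged_corpus <- function(x, ...) {
  nt <- sum(lengths(x$sentences))
  cat(sprintf("Tagged corpus: %d sentences, %d tokens, %d fine tags\n",
              length(x$sentences), nt,
              length(unique(unlist(x$fine_tags)))))
  invisible(x)
}

#' Read a one-sentence-per-line corpus
#'
#' Each non-empty line is whitespace-split into one token list; the input is
#' assumed pre-cleaned (no punctuation filtering is applied). Trailing blank
#' lines are ignored.
#'
#' @param path file path (UTF-8).
#' @return list of character token vectors.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty corpus file: ", path, call. = FALSE)
  strsplit(trimws(lines), "\\s+")
}

#' @rdname read_corpus
#' @param sentences list of token vectors.
#' @export
write_corpus <- function(sentences, path) {
  writeLines(vapply(sentences, paste, "", collapse = " "), path,
             useBytes = TRUE)
  invisible(path)
}

#' Read a blank-line-delimited per-word annotation file
#'
#' The on-disk format for fine tags and coarse categories: one annotation
#' per line, sentences separated by one empty line. The block count must
#' match the expected sentence count.
#'
#' @param path file path.
#' @param n_expected_sentences expected number of blocks; checked when
#'   non-NULL.
#' @return list of character vectors, one per sentence.
#' @export
read_tag_file <- function(path, n_expected_sentences = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  if (length(lines) == 0L) stop("empty tag file: ", path, call. = FALSE)
  blank <- !nzchar(trimws(lines))
  block <- cumsum(c(TRUE, blank[-length(blank)])) # blank line opens a block
  blocks <- unname(split(trimws(lines[!blank]), block[!blank]))
  if (!is.null(n_expected_sentences) &&
      length(blocks) != n_expected_sentences)
    stop("alignment error: ", length(blocks), " annotation blocks but ",
         n_expected_sentences, " sentences expected", call. = FALSE)
  blocks
}

#' @rdname read_tag_file
#' @param tags list of character vectors.
#' @export
write_tag_file <- function(tags, path) {
  out <- unlist(lapply(tags, function(t) c(t, "")))
  writeLines(out[-length(out)], path, useBytes = TRUE)
  invisible(path)
}

#' Read an aligned corpus + tag (+ category) file set
#'
#' @param corpus_path,tags_path,categories_path file paths; categories are
#'   derived from the tags through [coarse_map()] when no file is given.
#' @return a [tagged_corpus()].
#' @export
read_tagged_corpus <- function(corpus_path, tags_path,
                               categories_path = NULL) {
  sentences <- read_corpus(corpus_path)
  tags <- read_tag_file(tags_path, length(sentences))
  cats <- if (!is.null(categories_path))
    read_tag_file(categories_path, length(sentences)) else NULL
  tagged_corpus(sentences, tags, cats,
                meta = list(corpus_path = corpus_path))
}

#' Read a word2vec embedding table
#'
#' Supports both the text dialect (optional `count dim` header line, then
#' one `word v1 ... vd` line per word) and the binary dialect (`count dim`
#' header line, then per word: the surface form, a space, and `dim`
#' little-endian float32 values). Duplicate words keep their first
#' occurrence with a warning.
#'
#' @param path file path.
#' @param format `"text"` or `"binary"`.
#' @param expected_dim when non-NULL, a mismatching vector length raises a
#'   configuration error.
#' @return numeric matrix, one row per word (rownames).
#' @export
read_embeddings <- function(path, format = c("text", "binary"),
                            expected_dim = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- if (format == "text") read_embeddings_text(path)
         else read_embeddings_binary(path)
  dup <- duplicated(rownames(tab))
  if (any(dup)) {
    warning("duplicate words in embedding table; first occurrence kept: ",
            paste(unique(rownames(tab)[dup]), collapse = ", "))
    tab <- tab[!dup, , drop = FALSE]
  }
  if (!is.null(expected_dim) && ncol(tab) != expected_dim)
    stop("configuration error: embedding dimension ", ncol(tab),
         " does not match the expected ", expected_dim, call. = FALSE)
  tab
}

read_embeddings_text <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty embedding file: ", path, call. = FALSE)
  first <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  has_header <- length(first) == 2L &&
    !anyNA(suppressWarnings(as.numeric(first)))
  if (has_header) lines <- lines[-1L]
  parts <- strsplit(trimws(lines), "\\s+")
  dims <- lengths(parts) - 1L
  if (length(unique(dims)) != 1L)
    stop("parse error: inconsistent vector length at line ",
         which(dims != dims[1L])[1L] + has_header, " of ", path,
         call. = FALSE)
  vals <- suppressWarnings(
    vapply(parts, function(p) as.numeric(p[-1L]), numeric(dims[1L])))
  if (anyNA(vals))
    stop("parse error: non-numeric vector component in ", path,
         call. = FALSE)
  mat <- t(matrix(vals, nrow = dims[1L]))
  rownames(mat) <- vapply(parts, `[`, "", 1L)
  mat
}

read_embeddings_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) stop("parse error: truncated header", call. = FALSE)
    if (ch == "\n") break
    header <- c(header, ch)
  }
  hd <- strsplit(trimws(paste(header, collapse = "")), "\\s+")[[1L]]
  n <- as.integer(hd[1L]); d <- as.integer(hd[2L])
  if (is.na(n) || is.na(d))
    stop("parse error: malformed binary header", call. = FALSE)
  mat <- matrix(0, n, d)
  words <- character(n)
  for (i in seq_len(n)) {
    wchars <- character(0)
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L)
        stop("parse error: truncated binary table at word ", i,
             call. = FALSE)
      if (ch == " ") break
      if (ch == "\n" && length(wchars) == 0L) next  # tolerate separators
      wchars <- c(wchars, ch)
    }
    words[i] <- paste(wchars, collapse = "")
    v <- readBin(con, "numeric", n = d, size = 4L, endian = "little")
    if (length(v) != d)
      stop("parse error: truncated vector for word ", i, call. = FALSE)
    mat[i, ] <- v
  }
  rownames(mat) <- words
  mat
}

#' @rdname read_embeddings
#' @param embeddings numeric matrix with word rownames.
#' @export
write_embeddings <- function(embeddings, path,
                             format = c("text", "binary")) {
  format <- match.arg(format)
  if (format == "text") {
    lines <- c(paste(nrow(embeddings), ncol(embeddings)),
               vapply(seq_len(nrow(embeddings)), function(i)
                 paste(rownames(embeddings)[i],
                       paste(format(embeddings[i, ], scientific = FALSE,
                                    trim = TRUE, digits = 8),
                             collapse = " ")), ""))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(paste0(nrow(embeddings), " ", ncol(embeddings), "\n"), con,
              eos = NULL)
    for (i in seq_len(nrow(embeddings))) {
      writeChar(paste0(rownames(embeddings)[i], " "), con, eos = NULL)
      writeBin(as.numeric(embeddings[i, ]), con, size = 4L,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read / write sparse features in SVMlight format
#'
#' One example per line: `label index:value ...` with 1-based, strictly
#' increasing indices.
#'
#' @param x feature matrix (dense or `dgCMatrix`).
#' @param labels numeric labels, one per row.
#' @param path file path.
#' @param n_features total feature dimension on read; inferred from the
#'   largest index when NULL.
#' @return `write_features_svmlight` returns `path`;
#'   `read_features_svmlight` a list with `x` (a `dgCMatrix`) and `labels`.
#' @export
write_features_svmlight <- function(x, labels, path) {
  stopifnot(nrow(x) == length(labels))
  xs <- methods::as(methods::as(x, "CsparseMatrix"), "generalMatrix")
  tr <- Matrix::mat2triplet(xs)
  byrow <- split(data.frame(j = tr$j, v = tr$x),
                 factor(tr$i, levels = seq_len(nrow(x))))
  lines <- vapply(seq_len(nrow(x)), function(i) {
    b <- byrow[[i]]
    if (is.null(b) || nrow(b) == 0L) return(as.character(labels[i]))
    o <- order(b$j)
    paste(labels[i],
          paste0(b$j[o], ":", format(b$v[o], scientific = FALSE,
                                     trim = TRUE),
                 collapse = " "))
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_features_svmlight
#' @export
read_features_svmlight <- function(path, n_features = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  labels <- as.numeric(vapply(parts, `[`, "", 1L))
  ij <- lapply(seq_along(parts), function(i) {
    p <- parts[[i]][-1L]
    if (length(p) == 0L) return(NULL)
    kv <- strsplit(p, ":", fixed = TRUE)
    data.frame(i = i, j = as.integer(vapply(kv, `[`, "", 1L)),
               v = as.numeric(vapply(kv, `[`, "", 2L)))
  })
  ij <- do.call(rbind, ij)
  nf <- n_features %||% (if (is.null(ij)) 0L else max(ij$j))
  x <- if (is.null(ij))
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(length(parts), nf))
  else Matrix::sparseMatrix(i = ij$i, j = ij$j, x = ij$v,
                            dims = c(length(parts), nf))
  list(x = x, labels = labels)
}

#' Write the per-word activation sidecar table
#'
#' TSV with one row per word: sentence, position, word, tag, coarse
#' category, number of columns that fired a massive firing event.
#'
#' @param acts an `el_activations` object.
#' @param path file path.
#' @export
write_sidecar_tsv <- function(acts, path) {
  write.table(acts$meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
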