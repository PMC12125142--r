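#' Corpora of token sequences
#'
#' A `corpus` is an ordered list of sentences (character vectors of tokens)
#' with provenance metadata: the experimental condition, the name of the
#' generating grammar (if any), and the seed used to produce it. Tokens are
#' non-empty, whitespace-free, case-sensitive strings.
#'
#' @param sentences list of character vectors.
#' @param condition one of `"structured"`, `"scrambled"`, `"sov"`,
#'   `"reweighted"`, `"external"`.
#' @param grammar_name name of the generating grammar, or `NULL`.
#' @param seed generating seed, or `NULL`.
#' @return an object of class `corpus`.
#' @export
corpus <- function(sentences, condition = "external", grammar_name = NULL,
                   seed = NULL) {
  condition <- match.arg(condition,
    c("structured", "scrambled", "sov", "reweighted", "external"))
  sentences <- lapply(sentences, as.character)
  toks <- unlist(sentences)
  if (length(toks) && (any(!nzchar(toks)) || any(grepl("[[:space:]]", toks))))
    stop("tokens must be non-empty strings without whitespace")
  structure(list(sentences = sentences, condition = condition,
                 grammar_name = grammar_name, seed = seed),
            class = "corpus")
}

#' @export
print.corpus <- function(x, ...) {
  n <- length(x$sentences)
  nt <- sum(lengths(x$sentences))
  cat(sprintf("<corpus> %d sentences, %d tokens, condition: %s%s\n",
              n, nt, x$condition,
              if (!is.null(x$grammar_name))
                sprintf(" (grammar '%s', seed %s)", x$grammar_name,
                        format(x$seed)) else ""))
  if (n) cat("  e.g.:", paste(x$sentences[[1]], collapse = " "), "\n")
  invisible(x)
}

#' @export
length.corpus <- function(x) length(x$sentences)

sentence_strings <- function(x) {
  vapply(x$sentences, paste, "", collapse = " ")
}

#' Scramble word order within each sentence
#'
#' Each sentence is independently replaced by a uniform random permutation of
#' its tokens (the identity permutation is allowed). This destroys sentential
#' structure while exactly preserving per-sentence token multisets, sentence
#' count and lengths, and hence all corpus-level word-frequency statistics.
#'
#' @param corpus a [corpus()].
#' @param seed integer seed.
#' @return the scrambled `corpus`, `condition = "scrambled"`.
#' @export
scramble_corpus <- function(corpus, seed = 1L) {
  if (!length(corpus$sentences)) stop("corpus has no sentences")
  scrambled <- withr::with_seed(seed, {
    lapply(corpus$sentences, function(s) s[sample.int(length(s))])
  })
  out <- corpus
  out$sentences <- scrambled
  out$condition <- "scrambled"
  out$seed <- seed
  out
}

#' Split a corpus into training and held-out test sets
#'
#' Sentences are deduplicated by their whitespace-joined string before
#' splitting, so test sentences are guaranteed not to occur in the training
#' set. A fraction `test_fraction` of the unique strings is assigned to the
#' test set (one occurrence each); the training corpus keeps every original
#' occurrence of the remaining strings, preserving training frequencies.
#'
#' @param corpus a [corpus()].
#' @param test_fraction fraction of unique sentence strings held out,
#'   in (0, 1).
#' @param seed integer seed; the split is deterministic given the seed.
#' @return `list(train = corpus, test = corpus)`.
#' @export
split_corpus <- function(corpus, test_fraction, seed = 1L) {
  if (!length(corpus$sentences)) stop("corpus has no sentences")
  stopifnot(test_fraction > 0, test_fraction < 1)
  strs <- sentence_strings(corpus)
  uniq <- unique(strs)
  n_test <- round(test_fraction * length(uniq))
  if (n_test < 1 || n_test >= length(uniq))
    stop(sprintf("test_fraction %g yields an empty train or test split (%d unique sentences)",
                 test_fraction, length(uniq)))
  test_strs <- withr::with_seed(seed, sample(uniq, n_test))
  in_test <- strs %in% test_strs
  train <- corpus; test <- corpus
  train$sentences <- corpus$sentences[!in_test]
  ## one occurrence per held-out string, in first-occurrence order
  test$sentences <- corpus$sentences[match(test_strs, strs)]
  train$seed <- test$seed <- seed
  list(train = train, test = test)
}

#' Read / write corpora as plain text
#'
#' One sentence per line, single-space-separated tokens, UTF-8. Provenance
#' (`condition`, `grammar_name`, `seed`) is stored in a JSON sidecar at
#' `paste0(path, ".json")`.
#'
#' @param corpus a [corpus()].
#' @param path text file path.
#' @return `read_corpus` returns a `corpus`; `write_corpus` invisibly returns
#'   `path`.
#' @export
write_corpus <- function(corpus, path) {
  writeLines(sentence_strings(corpus), path, useBytes = TRUE)
  meta <- list(condition = corpus$condition,
               grammar_name = corpus$grammar_name, seed = corpus$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  sentences <- strsplit(lines, " ", fixed = TRUE)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar))
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  else list(condition = "external", grammar_name = NULL, seed = NULL)
  corpus(sentences, condition = meta$condition,
         grammar_name = meta$grammar_name, seed = meta$seed)
}
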