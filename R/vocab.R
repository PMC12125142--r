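BOS <- "<s>"
EOS <- "</s>"
UNK <- "<unk>"

#' Build a language-model vocabulary from a training corpus
#'
#' Reserved tokens `<s>` (sentence start, context only), `</s>` (sentence end)
#' and `<unk>` (unknown word) come first; corpus words follow in decreasing
#' frequency. Words with training count below `min_count` are dropped and
#' mapped to `<unk>` (toy grammars are closed-vocabulary: use the default 0).
#'
#' @param corpus a [corpus()].
#' @param min_count minimum training count for a word to enter the vocabulary.
#' @return an object of class `lm_vocab`: character vector of tokens with
#'   attribute `predictable` (everything except `<s>`).
#' @export
build_vocab <- function(corpus, min_count = 0L) {
  toks <- unlist(corpus$sentences)
  if (!length(toks)) stop("corpus has no tokens")
  cnt <- sort(table(toks), decreasing = TRUE)
  keep <- names(cnt)[cnt >= min_count]
  keep <- setdiff(keep, c(BOS, EOS, UNK))
  tokens <- c(BOS, EOS, UNK, keep)
  structure(tokens, predictable = setdiff(tokens, BOS), class = "lm_vocab")
}

#' @export
print.lm_vocab <- function(x, ...) {
  cat(sprintf("<lm_vocab> %d tokens (incl. <s>, </s>, <unk>)\n", length(x)))
  invisible(x)
}

## map corpus tokens into the vocabulary (OOV -> <unk>)
map_tokens <- function(tokens, vocab) {
  ifelse(tokens %in% vocab, tokens, UNK)
}
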