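#' Next-token probability distribution given a prefix
#'
#' Returns the model's conditional distribution over its vocabulary. The
#' n-gram backend conditions on the last `order - 1` prefix tokens with `<s>`
#' padding and distributes mass over the predictable tokens (everything
#' except `<s>`); the recurrent backend conditions on the full prefix and
#' returns its raw softmax over the whole vocabulary, so the probabilities
#' agree exactly with the surprisals it emits. Entries are non-negative and
#' sum to 1 within 1e-9.
#'
#' @param model an `ngram_model` or `rnn_lm`.
#' @param prefix character vector of preceding tokens (possibly empty);
#'   unknown words are mapped to `<unk>`.
#' @return named numeric probability vector.
#' @export
next_token_distribution <- function(model, prefix = character(0)) {
  UseMethod("next_token_distribution")
}

#' @export
next_token_distribution.ngram_model <- function(model, prefix = character(0)) {
  h <- ngram_history(model, prefix)
  p <- vapply(model$predictable, function(w) ngram_prob(model, h, w), 0)
  names(p) <- model$predictable
  p
}

#' @export
next_token_distribution.rnn_lm <- function(model, prefix = character(0)) {
  pr <- cpp_lstm_next_dist(model$params, rnn_ids(model, prefix),
                           match(BOS, model$vocab) - 1L)
  ## raw softmax over the full vocabulary: <s> keeps its (untrained, tiny)
  ## mass so the distribution agrees exactly with the scored surprisals
  names(pr) <- as.character(model$vocab)
  pr
}

#' Per-token surprisal of a sentence
#'
#' Surprisal of token \eqn{w_i} is \eqn{I(w_i) = -\log_2 p(w_i \mid context)}
#' in bits, where the context is the model's conditioning window. Zero
#' probabilities (possible under unsmoothed MLE n-grams) give infinite
#' surprisal and raise a warning; they are never silently dropped.
#'
#' @param model an `ngram_model` or `rnn_lm`.
#' @param sentence non-empty character vector of tokens.
#' @param include_eos also score the end-of-sentence event as a final
#'   position. Off by default: reported per-word surprisal tables exclude
#'   `</s>`, matching the convention of reporting word surprisal only.
#' @return data.frame with columns `position` (0-based, contiguous), `token`,
#'   `surprisal` (bits).
#' @export
surprisal_sequence <- function(model, sentence, include_eos = FALSE) {
  UseMethod("surprisal_sequence")
}

#' @export
surprisal_sequence.ngram_model <- function(model, sentence, include_eos = FALSE) {
  if (!length(sentence)) stop("sentence must be non-empty")
  toks <- map_tokens(sentence, model$vocab)
  scored <- if (include_eos) c(toks, EOS) else toks
  shown <- if (include_eos) c(sentence, EOS) else sentence
  padded <- c(rep(BOS, max(model$order - 1L, 0L)), toks, EOS)
  off <- max(model$order - 1L, 0L)
  s <- vapply(seq_along(scored), function(i) {
    h <- if (model$order == 1L) character(0)
         else padded[(off + i - model$order + 1L):(off + i - 1L)]
    -log2(ngram_prob(model, h, scored[i]))
  }, 0)
  flag_infinite_surprisal(s)
  data.frame(position = seq_along(scored) - 1L, token = shown, surprisal = s,
             stringsAsFactors = FALSE)
}

#' @export
surprisal_sequence.rnn_lm <- function(model, sentence, include_eos = FALSE) {
  if (!length(sentence)) stop("sentence must be non-empty")
  targets <- c(rnn_ids(model, sentence), match(EOS, model$vocab) - 1L)
  lp <- cpp_lstm_logprobs(model$params, targets,
                          match(BOS, model$vocab) - 1L)
  s <- -lp
  shown <- c(sentence, EOS)
  if (!include_eos) { s <- s[-length(s)]; shown <- shown[-length(shown)] }
  flag_infinite_surprisal(s)
  data.frame(position = seq_along(s) - 1L, token = shown, surprisal = s,
             stringsAsFactors = FALSE)
}

flag_infinite_surprisal <- function(s) {
  n_inf <- sum(is.infinite(s))
  if (n_inf)
    warning(sprintf("%d token(s) received zero probability (infinite surprisal)",
                    n_inf), call. = FALSE)
  invisible(n_inf)
}

#' Surprisal table for a whole corpus
#'
#' Concatenates [surprisal_sequence()] over all sentences in stable order.
#' Two models scored on the same corpus yield token-aligned tables (identical
#' `sentence_id`/`position` keys), which is what [token_aligned_correlation()]
#' consumes.
#'
#' @param model an `ngram_model` or `rnn_lm`.
#' @param corpus a [corpus()].
#' @param include_eos score `</s>` as a final position per sentence.
#' @param model_id,corpus_id provenance strings stored as attributes.
#' @return data.frame with columns `sentence_id`, `position`, `token`,
#'   `surprisal`; attributes `model_id`, `corpus_id`.
#' @export
corpus_surprisal <- function(model, corpus, include_eos = FALSE,
                             model_id = NULL, corpus_id = NULL) {
  rows <- lapply(seq_along(corpus$sentences), function(i) {
    r <- surprisal_sequence(model, corpus$sentences[[i]], include_eos)
    cbind(sentence_id = i, r)
  })
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(sentence_id = integer(0), position = integer(0),
                         token = character(0), surprisal = numeric(0))
  rownames(out) <- NULL
  attr(out, "model_id") <- model_id
  attr(out, "corpus_id") <- corpus_id
  out
}

#' Entropy of the next-token distribution after a prefix
#'
#' \eqn{H = -\sum_v p(v \mid prefix)\,\log_2 p(v \mid prefix)}: the expected
#' surprisal of the continuation, in bits, bounded by \eqn{\log_2 |V|}.
#'
#' @inheritParams next_token_distribution
#' @return entropy in bits.
#' @export
prefix_entropy <- function(model, prefix = character(0)) {
  p <- next_token_distribution(model, prefix)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Per-position entropy reduction along a sentence
#'
#' \eqn{\Delta H_i = H(w_1..w_{i-1}) - H(w_1..w_i)}: the change in uncertainty
#' about the next token caused by reading word \eqn{i}. No sign clipping is
#' applied; entropy can increase.
#'
#' @param model an `ngram_model` or `rnn_lm`.
#' @param sentence non-empty character vector.
#' @return numeric vector of length `length(sentence)`.
#' @export
entropy_reduction <- function(model, sentence) {
  if (!length(sentence)) stop("sentence must be non-empty")
  H <- vapply(0:length(sentence), function(i)
    prefix_entropy(model, sentence[seq_len(i)]), 0)
  H[-length(H)] - H[-1]
}

#' Read / write surprisal tables as TSV
#'
#' Header `sentence_id  position  token  surprisal_bits`, UTF-8, `.` decimal
#' separator; values written at 6 decimals.
#'
#' @param table a surprisal table from [corpus_surprisal()].
#' @param path file path.
#' @return `read_surprisal_table` returns the data.frame;
#'   `write_surprisal_table` invisibly returns `path`.
#' @export
write_surprisal_table <- function(table, path) {
  out <- data.frame(sentence_id = table$sentence_id,
                    position = table$position, token = table$token,
                    surprisal_bits = sprintf("%.6f", table$surprisal))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_surprisal_table
#' @export
read_surprisal_table <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = c("integer", "integer", "character",
                                        "numeric"),
                         quote = "", fileEncoding = "UTF-8")
  data.frame(sentence_id = d$sentence_id, position = d$position,
             token = d$token, surprisal = d$surprisal_bits,
             stringsAsFactors = FALSE)
}
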