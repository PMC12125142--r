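#' Configuration for the recurrent language model
#'
#' Defaults suit small closed-vocabulary toy languages: a single-layer LSTM
#' with a 32-dimensional embedding and 64 hidden units, trained for 10 epochs
#' with the Adam optimizer (learning rate 1e-3), mini-batches of 64 sentences,
#' and global-norm gradient clipping at 5. All fields are recorded in the
#' model object so runs are fully described by their configuration and seed.
#'
#' @param embedding embedding dimension.
#' @param hidden hidden-state dimension.
#' @param epochs training epochs.
#' @param batch_size sentences per mini-batch.
#' @param lr Adam learning rate.
#' @param clip global gradient-norm clip (0 disables).
#' @param min_count training words rarer than this map to `<unk>`.
#' @return a list of class `rnn_config`.
#' @export
rnn_config <- function(embedding = 32L, hidden = 64L, epochs = 10L,
                       batch_size = 64L, lr = 1e-3, clip = 5, min_count = 0L) {
  structure(list(embedding = as.integer(embedding), hidden = as.integer(hidden),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, clip = clip, min_count = as.integer(min_count)),
            class = "rnn_config")
}

#' Train an LSTM next-word language model
#'
#' Minimizes mean next-token negative log-likelihood with teacher forcing.
#' Each sentence is consumed as `<s> w_1 ... w_L` predicting
#' `w_1 ... w_L </s>`, so the model learns both word transitions and sentence
#' termination. Training is reproducible: parameter initialization and batch
#' shuffling use an internal generator derived from `seed`.
#'
#' @param corpus a [corpus()].
#' @param config an [rnn_config()].
#' @param seed integer seed.
#' @return an object of class `rnn_lm` with the learned parameters, the
#'   vocabulary, the configuration, and the per-epoch training loss in
#'   bits/token.
#' @seealso [surprisal_sequence()], [corpus_surprisal()],
#'   [next_token_distribution()]
#' @export
train_recurrent <- function(corpus, config = rnn_config(), seed = 1L) {
  if (!length(corpus$sentences)) stop("corpus has no sentences")
  vocab <- build_vocab(corpus, config$min_count)
  if (length(attr(vocab, "predictable")) <= 1)
    stop("vocabulary too small to train: no token other than </s>")
  ids <- lapply(corpus$sentences, function(s)
    c(match(map_tokens(s, vocab), vocab), match(EOS, vocab)) - 1L)
  fit <- cpp_lstm_train(ids, length(vocab), match(BOS, vocab) - 1L,
                        config$embedding, config$hidden, config$epochs,
                        config$batch_size, config$lr, config$clip,
                        as.integer(seed))
  structure(list(params = fit[c("E", "W", "U", "Wy", "b", "by")],
                 epoch_loss_bits = as.numeric(fit$epoch_loss_bits),
                 vocab = vocab, config = config, seed = as.integer(seed)),
            class = "rnn_lm")
}

#' @export
print.rnn_lm <- function(x, ...) {
  cat(sprintf(
    "<rnn_lm> LSTM emb %d, hidden %d, %d epochs, seed %d; vocab %d; final loss %.3f bits/token\n",
    x$config$embedding, x$config$hidden, x$config$epochs, x$seed,
    length(x$vocab), utils::tail(x$epoch_loss_bits, 1)))
  invisible(x)
}

rnn_ids <- function(model, tokens) {
  match(map_tokens(tokens, model$vocab), model$vocab) - 1L
}
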