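test_that("surprisal is the negative base-2 log of the conditional probability", {
  # p = 1 -> 0 bits; p = 0.5 -> 1 bit, read off a hand-countable corpus
  co <- fixed_corpus(c("a b", "a c"), times = 5)
  m <- train_ngram(co, 2, smoothing = "mle")
  s <- surprisal_sequence(m, c("a", "b"))
  expect_equal(s$surprisal[1], 0)   # p(a | <s>) = 1
  expect_equal(s$surprisal[2], 1)   # p(b | a) = 0.5
  expect_equal(s$position, c(0, 1))
})

test_that("per-sentence surprisal sums obey the chain rule", {
  co <- generate_corpus(toy_grammar(), 120, seed = 5)
  m <- train_ngram(co, 3, smoothing = "katz")
  r <- train_recurrent(co, rnn_config(epochs = 2), seed = 2)
  for (model in list(m, r)) {
    sent <- co$sentences[[7]]
    s <- surprisal_sequence(model, sent, include_eos = TRUE)
    # independent oracle: joint probability as a product of conditionals
    # queried one token at a time from the model's distribution
    logp <- 0
    for (i in seq_along(sent))
      logp <- logp + log2(next_token_distribution(model,
                                                  sent[seq_len(i - 1)])[[sent[i]]])
    logp <- logp + log2(next_token_distribution(model, sent)[["</s>"]])
    expect_lt(abs(sum(s$surprisal) - (-logp)), 1e-6)
  }
})

test_that("zero-probability tokens are flagged, not dropped", {
  co <- fixed_corpus("a b", times = 3)
  m <- train_ngram(co, 2, smoothing = "mle")
  expect_warning(s <- surprisal_sequence(m, c("b", "a")), "zero probability")
  expect_equal(nrow(s), 2)
  expect_true(any(is.infinite(s$surprisal)))
})

test_that("corpus scoring aligns tables and preserves totals", {
  co <- generate_corpus(toy_grammar(), 60, seed = 6)
  m1 <- train_ngram(co, 2, smoothing = "katz")
  m2 <- train_ngram(co, 3, smoothing = "katz")
  t1 <- corpus_surprisal(m1, co)
  t2 <- corpus_surprisal(m2, co)
  expect_equal(t1$sentence_id, t2$sentence_id)
  expect_equal(t1$position, t2$position)
  expect_equal(t1$token, t2$token)
  expect_equal(nrow(t1), sum(lengths(co$sentences)))
  # mean x N == total negative log-likelihood
  expect_equal(mean(t1$surprisal) * nrow(t1), sum(t1$surprisal))
  # empty corpus -> empty table
  expect_equal(nrow(corpus_surprisal(m1, corpus(list()))), 0)
})

test_that("prefix entropy equals expected surprisal and respects its bounds", {
  co <- generate_corpus(toy_grammar(), 80, seed = 14)
  m <- train_ngram(co, 2, smoothing = "katz")
  for (pre in list(character(0), "the", c("a", "woman"))) {
    p <- next_token_distribution(m, pre)
    H <- prefix_entropy(m, pre)
    expect_lt(abs(H - sum(p[p > 0] * -log2(p[p > 0]))), 1e-9)
    expect_gte(H, 0)
    expect_lte(H, log2(length(p)))
  }
  # deterministic continuation: one-hot distribution has zero entropy
  det <- train_ngram(fixed_corpus("a b", times = 4), 2, smoothing = "mle")
  expect_equal(prefix_entropy(det, "a"), 0)
  # uniform binary continuation has exactly 1 bit
  unif <- train_ngram(fixed_corpus(c("a b", "a c"), times = 4), 2,
                      smoothing = "mle")
  expect_equal(prefix_entropy(unif, "a"), 1)
})

test_that("entropy reduction matches differenced prefix entropies", {
  co <- generate_corpus(toy_grammar(), 80, seed = 15)
  m <- train_ngram(co, 3, smoothing = "katz")
  sent <- co$sentences[[3]]
  dh <- entropy_reduction(m, sent)
  oracle <- vapply(seq_along(sent), function(i)
    prefix_entropy(m, sent[seq_len(i - 1)]) -
      prefix_entropy(m, sent[seq_len(i)]), 0)
  expect_equal(dh, oracle)
  # a unigram model has a position-independent distribution: all zero
  m1 <- train_ngram(co, 1, smoothing = "katz")
  expect_equal(entropy_reduction(m1, sent), rep(0, length(sent)))
  # a deterministic continuation collapses all prior uncertainty
  det <- train_ngram(fixed_corpus(c("a b", "c d"), times = 4), 2,
                     smoothing = "mle")
  expect_equal(entropy_reduction(det, c("a", "b"))[1],
               prefix_entropy(det, character(0)))
})

test_that("surprisal tables round-trip through TSV at 6 decimals", {
  co <- generate_corpus(toy_grammar(), 10, seed = 4)
  m <- train_ngram(co, 2, smoothing = "katz")
  tab <- corpus_surprisal(m, co)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_surprisal_table(tab, path)
  tab2 <- read_surprisal_table(path)
  expect_equal(tab2$sentence_id, tab$sentence_id)
  expect_equal(tab2$position, tab$position)
  expect_equal(tab2$token, tab$token)
  expect_equal(tab2$surprisal, tab$surprisal, tolerance = 1e-6)
})
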