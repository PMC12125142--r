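test_that("bigram MLE reproduces hand counts on a deterministic corpus", {
  co <- fixed_corpus("a b", times = 10)
  m <- train_ngram(co, 2, smoothing = "mle")
  expect_equal(surprisim:::ngram_prob(m, "a", "b"), 1)
  s <- surprisal_sequence(m, c("a", "b"))
  expect_equal(s$surprisal[2], 0)           # p(b|a) = 1 -> 0 bits
  expect_equal(s$surprisal[1], 0)           # p(a|<s>) = 1
})

test_that("an order-1 model conditions on nothing", {
  co <- fixed_corpus(c("a b", "b c", "c a"), times = 3)
  m <- train_ngram(co, 1, smoothing = "katz")
  base <- next_token_distribution(m, character(0))
  expect_equal(next_token_distribution(m, c("a")), base)
  expect_equal(next_token_distribution(m, c("c", "b", "a")), base)
})

test_that("additive smoothing matches the textbook formula", {
  # c(a, b) = 2 and c(a, .) = 2; V = predictable types {a, b, </s>, <unk>}
  co <- fixed_corpus("a b", times = 2)
  m <- train_ngram(co, 2, smoothing = "add_k", k = 1)
  V <- length(m$predictable)
  expect_equal(V, 4)
  expect_equal(surprisim:::ngram_prob(m, "a", "b"), (2 + 1) / (2 + 1 * V))
  expect_equal(surprisim:::ngram_prob(m, "a", "a"), (0 + 1) / (2 + 1 * V))
  # 'b' is only ever followed by </s>: c(b, .) = 2, c(b, a) = 0
  expect_equal(surprisim:::ngram_prob(m, "b", "a"), (0 + 1) / (2 + 1 * V))
  # an unseen history falls back to the uniform additive distribution
  expect_equal(surprisim:::ngram_prob(m, "<unk>", "a"), 1 / V)
})

test_that("conditional probabilities equal count ratios on a hand-counted corpus", {
  # tokens: a b a b a c   (one sentence)
  co <- fixed_corpus("a b a b a c")
  m <- train_ngram(co, 2, smoothing = "mle")
  # after 'a': b twice, c once
  expect_equal(surprisim:::ngram_prob(m, "a", "b"), 2 / 3)
  expect_equal(surprisim:::ngram_prob(m, "a", "c"), 1 / 3)
  # after 'b': a twice
  expect_equal(surprisim:::ngram_prob(m, "b", "a"), 1)
  # after 'c': end of sentence
  expect_equal(surprisim:::ngram_prob(m, "c", "</s>"), 1)
})

test_that("every smoothed distribution is proper, including unseen histories", {
  co <- generate_corpus(toy_grammar(), 150, seed = 44)
  for (sm in c("katz", "add_k")) {
    m <- train_ngram(co, 3, smoothing = sm)
    prefixes <- list(character(0), "the", c("the", "farmer"),
                     c("farmer", "the"),            # unseen order
                     c("zzz", "qqq"),               # unknown words
                     c("the", "farmer", "loves", "a"))
    for (pre in prefixes) {
      p <- next_token_distribution(m, pre)
      expect_true(all(p >= 0))
      expect_lt(abs(sum(p) - 1), 1e-9)
    }
  }
})

test_that("Katz backoff discounts mass toward unseen continuations", {
  co <- generate_corpus(toy_grammar(), 300, seed = 15)
  m <- train_ngram(co, 3, smoothing = "katz")
  # after a determiner-noun context every verb is grammatical; the seen
  # continuations have small counts, so discounting reserves mass and all
  # twelve verbs score positive, seen or not
  p <- next_token_distribution(m, c("the", "farmer"))
  verbs <- toy_grammar()$lexicon$word[toy_grammar()$lexicon$pos == "V"]
  expect_true(all(p[verbs] > 0))
  # and under MLE the same unseen continuations would be hard zeros
  mle <- train_ngram(co, 3, smoothing = "mle")
  p_mle <- next_token_distribution(mle, c("the", "farmer"))
  expect_gte(sum(p[verbs] > 0), sum(p_mle[verbs] > 0))
})

test_that("rare words map to <unk> under a count threshold", {
  co <- fixed_corpus(c(rep("a b", 5), "a rare"))
  m <- train_ngram(co, 2, smoothing = "katz", min_count = 2)
  expect_false("rare" %in% m$vocab)
  s <- surprisal_sequence(m, c("a", "rare"))
  expect_equal(s$token[2], "rare")  # surface token kept in the table
  expect_true(is.finite(s$surprisal[2]))
})

test_that("order must be at least 1 and corpora non-empty", {
  co <- fixed_corpus("a b")
  expect_error(train_ngram(co, 0), "order")
  expect_error(train_ngram(corpus(list()), 2), "sentences")
})
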