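# synthetic surprisal tables built directly from value vectors,
# `sent_len` tokens per sentence
value_table <- function(values, sent_len = 8) {
  n <- length(values)
  sid <- rep(seq_len(ceiling(n / sent_len)), each = sent_len)[seq_len(n)]
  pos <- unlist(lapply(split(seq_len(n), sid), seq_along)) - 1L
  data.frame(sentence_id = sid, position = pos,
             token = paste0("w", seq_len(n)), surprisal = values)
}

test_that("windows are sentence-bounded with the exact expected count", {
  tab <- data.frame(
    sentence_id = rep(1:3, times = c(5, 2, 4)),
    position = c(0:4, 0:1, 0:3),
    token = "w",
    surprisal = 1:11 / 10)
  for (n in 1:4) {
    w <- make_windows(tab, n)
    expect_equal(nrow(w), sum(pmax(0, c(5, 2, 4) - n + 1)))
    expect_equal(ncol(w), n)
  }
  # a window never mixes values from two sentences: with n = 5 only the
  # 5-token sentence contributes
  w5 <- make_windows(tab, 5)
  expect_equal(nrow(w5), 1)
  expect_equal(unname(w5[1, ]), tab$surprisal[1:5])
  expect_error(make_windows(tab, 0), ">= 1")
  expect_error(make_windows(tab, 11), "<= 10")
})

test_that("preprocessing standardizes, rounds, and never adds distinct values", {
  withr::with_seed(3, v <- rnorm(500, 4, 2))
  z <- preprocess_values(v, zscore = TRUE)
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(sd(z) - 1), 1e-9)
  expect_equal(preprocess_values(1.234, round_to = 0.1), 1.2)
  expect_equal(preprocess_values(c(1.26, -0.54), round_to = 0.1),
               c(1.3, -0.5), tolerance = 1e-9)
  r <- preprocess_values(v, zscore = TRUE, round_to = 0.1)
  expect_lte(length(unique(r)), length(unique(v)))
  expect_error(preprocess_values(rep(2, 5), zscore = TRUE), "zero standard")
})

test_that("same-source windows classify at chance", {
  withr::with_seed(11, {
    a <- value_table(rlnorm(1200, 1, 0.5))
    b <- value_table(rlnorm(1200, 1, 0.5))
  })
  rep <- run_classification(a, b, window_sizes = c(1, 4, 8),
                            preprocessings = list(list(zscore = FALSE)),
                            seed = 21)
  for (i in seq_len(nrow(rep))) {
    band <- qbinom(c(0.005, 0.995), rep$n_test[i], 0.5) / rep$n_test[i]
    expect_gte(rep$accuracy[i], band[1])
    expect_lte(rep$accuracy[i], band[2])
  }
})

test_that("disjoint-support distributions are almost perfectly separable", {
  withr::with_seed(12, {
    a <- value_table(runif(800, 0, 1))
    b <- value_table(runif(800, 10, 11))
  })
  rep <- run_classification(a, b, window_sizes = c(1, 3),
                            preprocessings = list(list(zscore = FALSE)),
                            seed = 22)
  expect_true(all(rep$accuracy >= 0.95))
})

test_that("rounding degrades uniqueness-driven separability", {
  # two languages whose surprisal values interleave on a fine grid: every
  # value is unique to its language at 0.01 grain, but collides at 0.1
  grid_a <- seq(0.01, 5.00, by = 0.02)   # odd hundredths
  grid_b <- seq(0.02, 5.00, by = 0.02)   # even hundredths
  accs <- sapply(1:5, function(s) {
    withr::with_seed(100 + s, {
      a <- value_table(sample(grid_a, 900, replace = TRUE))
      b <- value_table(sample(grid_b, 900, replace = TRUE))
    })
    rep <- run_classification(
      a, b, window_sizes = 1,
      preprocessings = list(list(zscore = FALSE),
                            list(zscore = FALSE, round_to = 0.1)),
      seed = s)
    c(raw = rep$accuracy[is.na(rep$rounded_to)],
      rounded = rep$accuracy[!is.na(rep$rounded_to)])
  })
  expect_gt(mean(accs["raw", ]), 0.9)           # uniqueness is learnable
  expect_lte(mean(accs["rounded", ]), mean(accs["raw", ]))
})

test_that("classification reports are deterministic in the seed", {
  withr::with_seed(14, {
    a <- value_table(rnorm(400, 2, 1))
    b <- value_table(rnorm(400, 2.5, 1))
  })
  r1 <- run_classification(a, b, window_sizes = c(1, 2), seed = 31)
  r2 <- run_classification(a, b, window_sizes = c(1, 2), seed = 31)
  expect_identical(r1, r2)
})

test_that("accuracy grows with window size across structurally different toy languages", {
  # two small languages over disjoint word inventories, one SVO, one SOV;
  # trigram surprisal tables feed the classifier
  g_a <- mini_grammar()
  g_b <- to_sov(mini_grammar_renamed())
  prep <- function(g, seed) {
    co <- generate_corpus(g, 2500, seed = seed)
    parts <- split_corpus(co, 0.25, seed = seed + 1)
    m <- train_ngram(parts$train, 3, smoothing = "katz")
    corpus_surprisal(m, parts$test)
  }
  ta <- prep(g_a, 301)
  tb <- prep(g_b, 401)
  # raw z-scored values are uniquely attributable to one language, so even
  # single values classify near ceiling (the uniqueness confound)
  raw <- run_classification(ta, tb, window_sizes = 1,
                            preprocessings = list(list(zscore = TRUE)),
                            seed = 5)
  expect_gt(raw$accuracy, 0.9)
  # with values coarsened, longer windows carry the sequential information
  # and accuracy rises with window size
  rep <- run_classification(
    ta, tb, window_sizes = c(1, 2, 4, 6, 8, 10),
    preprocessings = list(list(zscore = TRUE, round_to = 0.5)), seed = 5)
  lo <- mean(rep$accuracy[rep$window_size <= 2])
  hi <- mean(rep$accuracy[rep$window_size >= 6])
  expect_gte(hi, lo)
  expect_gt(max(rep$accuracy), 0.5)
})

test_that("empty classes are rejected", {
  a <- value_table(rnorm(20), sent_len = 2)   # no sentence reaches length 5
  b <- value_table(rnorm(20), sent_len = 10)
  expect_error(run_classification(a, b, window_sizes = 5, seed = 1),
               "zero windows")
})
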