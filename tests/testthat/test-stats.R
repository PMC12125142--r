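test_that("identical samples give a null comparison", {
  a <- c(1, 2, 3, 4, 5)
  rep <- compare_distributions(a, a)
  expect_equal(rep$t, 0)
  expect_equal(rep$cohens_d, 0)
  expect_equal(rep$mean_diff, 0)
  expect_equal(rep$df, 8)
  expect_equal(rep$p, 1)
})

test_that("pooled t, d and CI match textbook formulas computed by hand", {
  a <- c(1, 2, 3, 4); b <- c(3, 4, 5, 6)
  rep <- compare_distributions(a, b)
  # independent arithmetic: pooled variance and standard error
  sp2 <- (3 * var(a) + 3 * var(b)) / 6
  se <- sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(rep$t, (mean(a) - mean(b)) / se, tolerance = 1e-12)
  expect_equal(rep$cohens_d, (mean(a) - mean(b)) / sqrt(sp2),
               tolerance = 1e-12)
  expect_equal(rep$df, 6)
  tcrit <- qt(0.975, 6)
  expect_equal(rep$ci_low, (mean(a) - mean(b)) - tcrit * se,
               tolerance = 1e-12)
  expect_equal(rep$ci_high, (mean(a) - mean(b)) + tcrit * se,
               tolerance = 1e-12)
  # cross-check t and p against the base implementation
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(rep$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(rep$p, tt$p.value, tolerance = 1e-12)
  expect_true(rep$ci_low <= rep$mean_diff && rep$mean_diff <= rep$ci_high)
})

test_that("comparisons are antisymmetric and scale invariant", {
  withr::with_seed(2, {
    a <- rnorm(40, 2); b <- rnorm(35, 2.5)
  })
  ab <- compare_distributions(a, b)
  ba <- compare_distributions(b, a)
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$cohens_d, -ba$cohens_d)
  sc <- compare_distributions(3 * a + 1, 3 * b + 1)
  expect_equal(sc$cohens_d, ab$cohens_d, tolerance = 1e-12)
})

test_that("post-hoc power is monotone in effect size and sample size", {
  p_d <- sapply(c(0.1, 0.3, 0.5, 0.8), function(d)
    surprisim:::power_two_sample(d, 50, 50, 0.05, 98))
  expect_true(all(diff(p_d) > 0))
  p_n <- sapply(c(10, 30, 100, 500), function(n)
    surprisim:::power_two_sample(0.4, n, n, 0.05, 2 * n - 2))
  expect_true(all(diff(p_n) > 0))
  # huge effects at large n saturate at 1 (the reported regime)
  expect_equal(surprisim:::power_two_sample(0.98, 31428, 31428, 0.05, 62854),
               1, tolerance = 1e-12)
})

test_that("the analytic p agrees with a permutation oracle", {
  withr::with_seed(7, {
    a <- rnorm(6, 0); b <- rnorm(6, 1)
  })
  rep <- compare_distributions(a, b)
  pool <- c(a, b)
  obs <- abs(mean(a) - mean(b))
  n_perm <- 100000
  withr::with_seed(8, {
    hits <- sum(replicate(n_perm, {
      idx <- sample.int(12, 6)
      abs(mean(pool[idx]) - mean(pool[-idx])) >= obs - 1e-12
    }))
  })
  p_mc <- hits / n_perm
  ci <- binom.test(hits, n_perm)$conf.int
  # generous MC band: analytic Student p should sit near the permutation p
  expect_gt(rep$p, max(0, ci[1] - 0.02))
  expect_lt(rep$p, ci[2] + 0.02)
})

test_that("degenerate comparisons are flagged", {
  expect_error(compare_distributions(1, c(1, 2)), "at least 2")
  expect_warning(rep <- compare_distributions(c(1, 1, 1), c(2, 2, 2)),
                 "zero pooled variance")
  expect_true(is.infinite(rep$t))
})

make_table <- function(values) {
  data.frame(sentence_id = 1L, position = seq_along(values) - 1L,
             token = paste0("w", seq_along(values)), surprisal = values)
}

test_that("token-aligned correlation matches the direct formula", {
  x <- c(1.2, 3.4, 2.2, 5.0, 4.1)
  y <- c(0.9, 2.9, 2.5, 4.8, 3.6)
  rep <- token_aligned_correlation(make_table(x), make_table(y))
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(rep$r, r_hand, tolerance = 1e-12)
  expect_equal(rep$df, 3)
  expect_equal(rep$n, 5)
  # self-correlation and anti-correlation
  expect_equal(token_aligned_correlation(make_table(x), make_table(x))$r, 1)
  neg <- make_table(-x)
  expect_equal(token_aligned_correlation(make_table(x), neg)$r, -1)
})

test_that("misaligned tables are rejected with the divergent key", {
  a <- make_table(c(1, 2, 3))
  b <- make_table(c(1, 2, 3))
  b$token[2] <- "other"
  expect_error(token_aligned_correlation(a, b), "other")
  expect_warning(
    rep <- token_aligned_correlation(make_table(c(1, 1, 1)),
                                     make_table(c(1, 2, 3))),
    "zero variance")
  expect_true(is.na(rep$r))
})

test_that("reports serialize to JSON with provenance", {
  rep <- compare_distributions(c(1, 2, 3), c(2, 3, 4))
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep, path, model_a = "structured", model_b = "scrambled")
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$t, rep$t)
  expect_equal(back$cohens_d, rep$cohens_d)
  expect_equal(back$model_a, "structured")
})
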