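#' Two-sample comparison of surprisal distributions
#'
#' Computes the full readout used to contrast per-token surprisal
#' distributions between two training conditions: group means and standard
#' deviations, Student's pooled two-sample t (df = n1 + n2 - 2), the
#' two-sided p value, the 95% (or `1 - alpha`) confidence interval of the
#' mean difference from the pooled standard error, Cohen's d with pooled
#' standard deviation, and post-hoc power of the two-sided test at the
#' observed effect size via the noncentral t distribution. A Welch variant
#' is available behind `var_equal = FALSE` (df then follows
#' Welch-Satterthwaite and d uses the averaged variance).
#'
#' @param a,b numeric vectors of surprisal values (bits), length >= 2 each.
#' @param alpha significance level, default 0.05.
#' @param var_equal pooled-variance Student t (default) or Welch t.
#' @return a list of class `comparison_report` with fields `n1`, `n2`,
#'   `mean1`, `mean2`, `sd1`, `sd2`, `mean_diff` (a - b), `t`, `df`, `p`,
#'   `ci_low`, `ci_high`, `cohens_d`, `power`, `alpha`.
#' @export
compare_distributions <- function(a, b, alpha = 0.05, var_equal = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) stop("both samples need at least 2 observations")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("non-finite surprisal values in input; infinite surprisals (zero-probability tokens) must be handled before comparison")
  m1 <- mean(a); m2 <- mean(b)
  v1 <- stats::var(a); v2 <- stats::var(b)
  if (var_equal) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    d <- if (sp2 > 0) (m1 - m2) / sqrt(sp2) else if (m1 == m2) 0 else Inf
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- se^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    sp2 <- (v1 + v2) / 2
    d <- if (sp2 > 0) (m1 - m2) / sqrt(sp2) else if (m1 == m2) 0 else Inf
  }
  t_stat <- if (se > 0) (m1 - m2) / se else if (m1 == m2) 0 else {
    warning("zero pooled variance with unequal means: t is infinite")
    sign(m1 - m2) * Inf
  }
  p <- if (is.finite(t_stat)) 2 * stats::pt(-abs(t_stat), df) else 0
  tcrit <- stats::qt(1 - alpha / 2, df)
  ci <- if (is.finite(se) && se > 0)
    (m1 - m2) + c(-1, 1) * tcrit * se else c(m1 - m2, m1 - m2)
  structure(
    list(n1 = n1, n2 = n2, mean1 = m1, mean2 = m2,
         sd1 = sqrt(v1), sd2 = sqrt(v2), mean_diff = m1 - m2,
         t = t_stat, df = df, p = p, ci_low = ci[1], ci_high = ci[2],
         cohens_d = d,
         power = power_two_sample(d, n1, n2, alpha, df),
         alpha = alpha),
    class = "comparison_report")
}

## post-hoc power of the two-sided two-sample t test at observed d
power_two_sample <- function(d, n1, n2, alpha, df) {
  if (!is.finite(d)) return(1)
  ncp <- abs(d) * sqrt(n1 * n2 / (n1 + n2))
  tcrit <- stats::qt(1 - alpha / 2, df)
  1 - stats::pt(tcrit, df, ncp = ncp) + stats::pt(-tcrit, df, ncp = ncp)
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("Two-sample comparison (Student pooled t)\n"))
  cat(sprintf("  M1 = %.3f (sd %.3f, n %d);  M2 = %.3f (sd %.3f, n %d)\n",
              x$mean1, x$sd1, x$n1, x$mean2, x$sd2, x$n2))
  cat(sprintf("  diff = %.3f bits, CI[%.3f, %.3f];  t(%s) = %.2f, p = %.3g\n",
              x$mean_diff, x$ci_low, x$ci_high,
              format(x$df, big.mark = ","), x$t, x$p))
  cat(sprintf("  Cohen's d = %.3f, power = %.3g (alpha %.3g)\n",
              x$cohens_d, x$power, x$alpha))
  invisible(x)
}

#' Token-aligned Pearson correlation between two surprisal tables
#'
#' The two tables must describe the same test tokens: identical
#' `(sentence_id, position, token)` keys in the same order (as produced by
#' scoring two models on one shared corpus). Pearson's r is computed over the
#' paired values; the two-sided p comes from the t transform with
#' df = n - 2.
#'
#' @param a,b surprisal tables from [corpus_surprisal()].
#' @return a list of class `correlation_report` with fields `r`, `df`, `p`,
#'   `n`.
#' @export
token_aligned_correlation <- function(a, b) {
  key <- function(t) paste(t$sentence_id, t$position, t$token, sep = "\r")
  ka <- key(a); kb <- key(b)
  if (length(ka) != length(kb) || any(ka != kb)) {
    bad <- if (length(ka) != length(kb)) 1L else which(ka != kb)[1]
    stop(sprintf("tables are not token-aligned (first divergent key at row %d: '%s' vs '%s')",
                 bad,
                 if (bad <= length(ka)) gsub("\r", "/", ka[bad]) else "<missing>",
                 if (bad <= length(kb)) gsub("\r", "/", kb[bad]) else "<missing>"))
  }
  x <- a$surprisal; y <- b$surprisal
  n <- length(x)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance in one series: correlation undefined")
    return(structure(list(r = NA_real_, df = n - 2L, p = NA_real_, n = n),
                     class = "correlation_report"))
  }
  r <- stats::cor(x, y)
  df <- n - 2L
  t_stat <- r * sqrt(df / (1 - r^2))
  structure(list(r = r, df = df, p = 2 * stats::pt(-abs(t_stat), df), n = n),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("Token-aligned Pearson correlation: r(%s) = %.3f, p = %.3g (n = %d)\n",
              format(x$df, big.mark = ","), x$r, x$p, x$n))
  invisible(x)
}

#' Serialize a report as JSON
#'
#' Writes all fields of a `comparison_report`, `correlation_report` or
#' classification report at full double precision, plus any provenance
#' supplied in `...`.
#'
#' @param report a report object.
#' @param path file path.
#' @param ... extra named provenance fields (model ids, seeds, ...).
#' @return invisibly, `path`.
#' @export
write_report <- function(report, path, ...) {
  obj <- c(unclass(report), list(...))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
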