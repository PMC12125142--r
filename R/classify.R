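#' Sliding windows of consecutive surprisal values
#'
#' Windows of `n` consecutive values with stride 1, built within each
#' sentence; no window crosses a sentence boundary, so a sentence of length
#' `L` contributes `max(0, L - n + 1)` windows.
#'
#' @param table a surprisal table from [corpus_surprisal()].
#' @param n window size, 1 to 10.
#' @return numeric matrix with `n` columns and attribute `sentence_id`
#'   (source sentence of each window).
#' @export
make_windows <- function(table, n) {
  if (n < 1) stop("window size must be >= 1")
  if (n > 10) stop("window size must be <= 10")
  by_sent <- split(table$surprisal, table$sentence_id)
  rows <- lapply(names(by_sent), function(sid) {
    v <- by_sent[[sid]]
    L <- length(v)
    if (L < n) return(NULL)
    idx <- seq_len(L - n + 1)
    m <- vapply(seq_len(n) - 1L, function(k) v[idx + k], numeric(length(idx)))
    m <- matrix(m, nrow = length(idx))
    attr(m, "sid") <- rep(as.integer(sid), nrow(m))
    m
  })
  rows <- Filter(Negate(is.null), rows)
  out <- if (length(rows)) do.call(rbind, rows) else matrix(numeric(0), 0, n)
  attr(out, "sentence_id") <-
    if (length(rows)) unlist(lapply(rows, attr, "sid")) else integer(0)
  out
}

#' Z-score and/or round surprisal values
#'
#' Z-scoring standardizes the values of one source corpus to mean 0, sd 1
#' (applied per corpus, so each language keeps its own scale reference).
#' Rounding replaces each value by the nearest multiple of `round_to` and is
#' applied after z-scoring; it is the control that destroys value-uniqueness
#' cues while preserving the coarse distribution.
#'
#' @param values numeric vector.
#' @param zscore standardize first.
#' @param round_to rounding grain (e.g. 0.1), or `NULL` for none.
#' @return the transformed numeric vector.
#' @export
preprocess_values <- function(values, zscore = FALSE, round_to = NULL) {
  if (zscore) {
    s <- stats::sd(values)
    if (!is.finite(s) || s == 0)
      stop("cannot z-score values with zero standard deviation")
    values <- (values - mean(values)) / s
  }
  if (!is.null(round_to)) values <- round(values / round_to) * round_to
  values
}

#' Classify the source language of surprisal windows
#'
#' Implements the language-identification probe: can a classifier tell which
#' of two corpora a window of consecutive surprisal values came from? For
#' every window size and preprocessing condition, sentence-bounded sliding
#' windows are built from both tables, the larger class is downsampled to
#' balance, an 80/20 stratified train/test split is drawn, and a random
#' forest (majority vote over `n_trees` trees) reports held-out accuracy.
#' All randomness is derived from `seed`, so identical seeds give identical
#' reports.
#'
#' @param table_a,table_b surprisal tables for the two sources.
#' @param window_sizes integer vector within 1..10.
#' @param preprocessings list of `list(zscore = <bool>, round_to = <num or
#'   NULL>)` conditions.
#' @param seed integer seed.
#' @param n_trees trees in the forest.
#' @param split_by `"window"` (default) or `"sentence"`: the unit assigned to
#'   train vs test. Sentence-level splitting removes any leakage of
#'   overlapping windows across the split.
#' @param test_fraction held-out fraction, default 0.2.
#' @return data.frame of class `classifier_report`: one row per
#'   `(window_size, preprocessing)` with `accuracy`, `n_train`, `n_test`,
#'   `seed`.
#' @export
run_classification <- function(table_a, table_b, window_sizes = 1:10,
                               preprocessings = list(list(zscore = TRUE,
                                                          round_to = NULL)),
                               seed = 1L, n_trees = 100L,
                               split_by = c("window", "sentence"),
                               test_fraction = 0.2) {
  split_by <- match.arg(split_by)
  if (!nrow(table_a) || !nrow(table_b)) stop("both tables must be non-empty")
  rows <- list()
  for (pp in preprocessings) {
    zs <- isTRUE(pp$zscore)
    rt <- pp$round_to
    ta <- table_a; tb <- table_b
    ta$surprisal <- preprocess_values(ta$surprisal, zs, rt)
    tb$surprisal <- preprocess_values(tb$surprisal, zs, rt)
    for (n in window_sizes) {
      wa <- make_windows(ta, n); wb <- make_windows(tb, n)
      if (!nrow(wa) || !nrow(wb))
        stop(sprintf("a class has zero windows at window size %d", n))
      acc <- withr::with_seed(
        derive_seed(seed, sprintf("clf-%d-%d-%s", n, zs,
                                  format(if (is.null(rt)) 0 else rt))), {
        fit_rf_accuracy(wa, wb, n_trees, split_by, test_fraction)
      })
      rows[[length(rows) + 1L]] <- data.frame(
        window_size = n, zscored = zs,
        rounded_to = if (is.null(rt)) NA_real_ else rt,
        accuracy = acc$accuracy, n_train = acc$n_train, n_test = acc$n_test,
        seed = seed)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("classifier_report", class(out))
  out
}

fit_rf_accuracy <- function(wa, wb, n_trees, split_by, test_fraction) {
  sid_a <- attr(wa, "sentence_id"); sid_b <- attr(wb, "sentence_id")
  ## balance classes by downsampling the larger one before splitting
  n_keep <- min(nrow(wa), nrow(wb))
  ka <- sort(sample.int(nrow(wa), n_keep))
  kb <- sort(sample.int(nrow(wb), n_keep))
  x <- rbind(wa[ka, , drop = FALSE], wb[kb, , drop = FALSE])
  y <- factor(rep(c("a", "b"), each = n_keep))
  if (split_by == "window") {
    test_idx <- c(sample.int(n_keep, round(test_fraction * n_keep)),
                  n_keep + sample.int(n_keep, round(test_fraction * n_keep)))
  } else {
    sid <- c(paste0("a", sid_a[ka]), paste0("b", sid_b[kb]))
    test_sents <- unlist(lapply(split(unique(sid), substr(unique(sid), 1, 1)),
      function(u) sample(u, max(1, round(test_fraction * length(u))))))
    test_idx <- which(sid %in% test_sents)
  }
  train_idx <- setdiff(seq_len(2 * n_keep), test_idx)
  colnames(x) <- paste0("w", seq_len(ncol(x)))
  fit <- randomForest::randomForest(x[train_idx, , drop = FALSE],
                                    y[train_idx], ntree = n_trees)
  pred <- stats::predict(fit, x[test_idx, , drop = FALSE])
  list(accuracy = mean(pred == y[test_idx]),
       n_train = length(train_idx), n_test = length(test_idx))
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("<classifier_report> held-out accuracy by window size x preprocessing\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
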