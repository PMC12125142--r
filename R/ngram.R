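NGRAM_SEP <- "\x1f"
CTX_ROOT <- "\x01"  # environment key for the empty (unigram) context

ngram_keys <- function(s, j) {
  L <- length(s)
  if (L < j) return(character(0))
  i <- seq_len(L - j + 1L)
  if (j == 1L) return(s)
  do.call(paste, c(lapply(0:(j - 1L), function(k) s[i + k]), sep = NGRAM_SEP))
}

#' Train a smoothed n-gram language model
#'
#' Counts are collected from the corpus with `order - 1` start-of-sentence
#' (`<s>`) padding tokens and one end-of-sentence (`</s>`) token per sentence;
#' each backoff order is counted with its own padding so that context totals
#' equal the number of prediction events at that order. Three smoothing
#' schemes are available:
#'
#' * `"katz"` (default): Katz backoff with Good-Turing discounting of counts
#'   up to 7, the classic SRILM-style recipe. Whenever the count-of-counts
#'   statistics make a Good-Turing discount undefined or out of range, that
#'   count falls back to an absolute discount of 0.5.
#' * `"add_k"`: additive smoothing, `p(w|h) = (c(hw) + k) / (c(h) + k * V)`
#'   with `V` the number of predictable vocabulary types.
#' * `"mle"`: raw relative frequencies; unseen events get probability 0 and
#'   hence infinite surprisal (flagged downstream, never silently dropped).
#'
#' @param corpus a [corpus()].
#' @param order n-gram order (>= 1); a trigram model is `order = 3`.
#' @param smoothing `"katz"`, `"add_k"`, or `"mle"`.
#' @param k additive constant for `"add_k"`.
#' @param min_count words rarer than this at training time are mapped to
#'   `<unk>`; default 0 (closed vocabulary).
#' @return an object of class `ngram_model`.
#' @seealso [next_token_distribution()], [surprisal_sequence()]
#' @export
train_ngram <- function(corpus, order, smoothing = c("katz", "add_k", "mle"),
                        k = 1, min_count = 0L) {
  smoothing <- match.arg(smoothing)
  if (order < 1) stop("order must be >= 1")
  if (!length(corpus$sentences)) stop("corpus has no sentences")
  vocab <- build_vocab(corpus, min_count)
  mapped <- lapply(corpus$sentences, map_tokens, vocab)

  tab <- vector("list", order)   # j-gram counts (named numeric)
  for (j in seq_len(order)) {
    padded <- lapply(mapped, function(s) c(rep(BOS, j - 1L), s, EOS))
    grams <- unlist(lapply(padded, ngram_keys, j), use.names = FALSE)
    if (j == 1L) grams <- grams[grams != BOS]
    cnt <- table(grams)
    tab[[j]] <- as.numeric(cnt); names(tab[[j]]) <- names(cnt)
  }
  ngram_from_counts(tab, order, smoothing, k, vocab)
}

## assemble a scoring-ready model from per-order n-gram count tables
ngram_from_counts <- function(tab, order, smoothing, k, vocab) {
  ctx <- vector("list", order)   # per-context continuation tables (env)
  for (j in seq_len(order)) {
    cnt <- tab[[j]]
    e <- new.env(parent = emptyenv(), size = max(16L, length(cnt)))
    if (j == 1L) {
      assign(CTX_ROOT, list(words = names(cnt), counts = unname(cnt),
                            total = sum(cnt)), envir = e)
    } else {
      keys <- names(cnt)
      parts <- strsplit(keys, NGRAM_SEP, fixed = TRUE)
      ctxk <- vapply(parts, function(p)
        paste(p[-j], collapse = NGRAM_SEP), "")
      w <- vapply(parts, function(p) p[[j]], "")
      idx <- split(seq_along(keys), ctxk)
      for (ck in names(idx)) {
        ii <- idx[[ck]]
        assign(ck, list(words = w[ii], counts = unname(cnt[ii]),
                        total = sum(cnt[ii])), envir = e)
      }
    }
    ctx[[j]] <- e
  }

  discounts <- if (smoothing == "katz")
    lapply(tab, good_turing_discounts) else NULL

  predictable <- attr(vocab, "predictable")
  structure(
    list(order = order, smoothing = smoothing, k = k, vocab = vocab,
         predictable = predictable, tab = tab, ctx = ctx,
         discounts = discounts,
         unigram = katz_unigram(ctx[[1]], predictable),
         alpha_cache = new.env(parent = emptyenv())),
    class = "ngram_model")
}

#' @export
print.ngram_model <- function(x, ...) {
  cat(sprintf("<ngram_model> order %d, smoothing '%s', vocabulary %d tokens\n",
              x$order, x$smoothing, length(x$vocab)))
  invisible(x)
}

## Good-Turing discount factors for counts 1..k (SRILM-style Katz discounts).
## The cutoff adapts downward when the count-of-counts statistics make the
## usual k = 5 degenerate (small corpora); a count whose Good-Turing
## discount is undefined or outside (0, 1) falls back to an absolute
## discount of 0.5, so low counts always reserve some backoff mass.
good_turing_discounts <- function(counts, k_max = 7L) {
  Nr <- tabulate(pmin(counts, k_max + 1L), nbins = k_max + 1L)
  d <- (seq_len(k_max) - 0.5) / seq_len(k_max)
  if (Nr[1] == 0) return(d)
  k_cut <- 0L
  for (k in k_max:1) {
    if (Nr[k + 1] > 0 && (k + 1) * Nr[k + 1] / Nr[1] < 1) { k_cut <- k; break }
  }
  if (k_cut == 0L) return(d)
  common <- (k_cut + 1) * Nr[k_cut + 1] / Nr[1]
  for (r in seq_len(k_cut)) {
    if (Nr[r] == 0 || Nr[r + 1] == 0) next
    r_star <- (r + 1) * Nr[r + 1] / Nr[r]
    dr <- (r_star / r - common) / (1 - common)
    if (is.finite(dr) && dr > 0 && dr < 1) d[r] <- dr
  }
  d
}

## unigram base distribution over the predictable vocabulary; zero-count
## types (typically <unk>) share the Good-Turing singleton mass, so the
## distribution is proper without pseudo-counts
katz_unigram <- function(ctx1, predictable) {
  ent <- get(CTX_ROOT, envir = ctx1)
  cnt <- ent$counts[match(predictable, ent$words)]
  cnt[is.na(cnt)] <- 0
  N <- sum(cnt)
  zero <- cnt == 0
  p <- cnt / N
  if (any(zero)) {
    n1 <- sum(cnt == 1)
    p0 <- if (n1 > 0) n1 / N else 0.5 / N
    p0 <- min(p0, 0.5)
    p <- (1 - p0) * p
    p[zero] <- p0 / sum(zero)
  }
  names(p) <- predictable
  p
}

unigram_prob <- function(model, w) {
  if (missing(w)) model$unigram else unname(model$unigram[w])
}

discount_of <- function(d, count) {
  if (count > length(d)) 1 else d[count]
}

## Katz backoff probability p(w | h), h a character vector (possibly empty)
katz_prob <- function(model, h, w) {
  j <- length(h) + 1L
  if (j == 1L) return(unigram_prob(model, w))
  key <- paste(h, collapse = NGRAM_SEP)
  ent <- get0(key, envir = model$ctx[[j]])
  if (is.null(ent)) return(katz_prob(model, h[-1], w))
  i <- match(w, ent$words)
  d <- model$discounts[[j]]
  if (!is.na(i)) {
    cnt <- ent$counts[i]
    return(discount_of(d, cnt) * cnt / ent$total)
  }
  ck <- paste0(j, NGRAM_SEP, key)
  ab <- get0(ck, envir = model$alpha_cache)
  if (is.null(ab)) {
    dvals <- vapply(ent$counts, function(cc) discount_of(d, cc), 0)
    alpha_num <- 1 - sum(dvals * ent$counts) / ent$total
    p_lower_seen <- vapply(ent$words, function(ww)
      katz_prob(model, h[-1], ww), 0)
    denom <- 1 - sum(p_lower_seen)
    if (denom > 1e-12) {
      ab <- list(scale = alpha_num / denom, unif = 0)
    } else {
      ## the backoff distribution has no mass left on the unseen set:
      ## spread the reserved mass uniformly so the distribution stays proper
      n_unseen <- length(model$predictable) - length(ent$words)
      ab <- list(scale = 0,
                 unif = if (n_unseen > 0) alpha_num / n_unseen else 0)
    }
    assign(ck, ab, envir = model$alpha_cache)
  }
  ab$scale * katz_prob(model, h[-1], w) + ab$unif
}

## p(w | h) under the model's smoothing scheme; h is the full-length history
## (order - 1 tokens, BOS-padded)
ngram_prob <- function(model, h, w) {
  if (model$order == 1L) h <- character(0)
  if (length(h) > model$order - 1L)
    h <- h[(length(h) - model$order + 2L):length(h)]
  switch(model$smoothing,
    katz = katz_prob(model, h, w),
    add_k = {
      j <- length(h) + 1L
      key <- if (j == 1L) CTX_ROOT else paste(h, collapse = NGRAM_SEP)
      ent <- get0(key, envir = model$ctx[[j]])
      V <- length(model$predictable)
      cnt <- 0; tot <- 0
      if (!is.null(ent)) {
        tot <- ent$total
        i <- match(w, ent$words)
        if (!is.na(i)) cnt <- ent$counts[i]
      }
      (cnt + model$k) / (tot + model$k * V)
    },
    mle = {
      j <- length(h) + 1L
      key <- if (j == 1L) CTX_ROOT else paste(h, collapse = NGRAM_SEP)
      ent <- get0(key, envir = model$ctx[[j]])
      if (is.null(ent) || ent$total == 0) return(0)
      i <- match(w, ent$words)
      if (is.na(i)) 0 else ent$counts[i] / ent$total
    })
}

ngram_history <- function(model, prefix) {
  prefix <- map_tokens(prefix, model$vocab)
  h <- c(rep(BOS, max(model$order - 1L, 0L)), prefix)
  if (model$order == 1L) return(character(0))
  h[(length(h) - model$order + 2L):length(h)]
}
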