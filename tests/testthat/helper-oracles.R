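# Independent oracles for the grammar sampler and the language models.
# Everything here is computed from the grammar definition by enumeration /
# dynamic programming, deliberately sharing no code with the package's
# sampler or scorers.

# minimal subtree depth per nonterminal (terminal cost 0, word leaf 1)
oracle_min_depths <- function(g) {
  nts <- unique(c(sapply(g$rules, `[[`, "lhs"), g$lexicon$pos))
  m <- stats::setNames(rep(Inf, length(nts)), nts)
  m[unique(g$lexicon$pos)] <- 1
  repeat {
    old <- m
    for (r in g$rules) {
      cost <- 1 + max(c(0, sapply(r$rhs, function(s) if (s %in% nts) m[[s]] else 0)))
      if (cost < m[[r$lhs]]) m[[r$lhs]] <- cost
    }
    if (identical(old, m)) break
  }
  m
}

# expansions available at a given depth, with renormalized probabilities:
# an expansion is available iff all its nonterminals can finish in budget
oracle_expansions <- function(g, sym, depth, max_depth, md) {
  nts <- names(md)
  rules <- Filter(function(r) r$lhs == sym, g$rules)
  exps <- lapply(rules, function(r) list(rhs = r$rhs, w = r$w, word = FALSE))
  li <- which(g$lexicon$pos == sym)
  exps <- c(exps, lapply(li, function(i)
    list(rhs = g$lexicon$word[i], w = g$lexicon$w[i], word = TRUE)))
  ok <- sapply(exps, function(e) {
    if (e$word) depth + 1 <= max_depth
    else all(sapply(e$rhs, function(s)
      if (s %in% nts) depth + 1 + md[[s]] <= max_depth else TRUE))
  })
  exps <- exps[ok]
  w <- sapply(exps, `[[`, "w")
  list(exps = exps, p = w / sum(w))
}

# exact yield-length distribution of the capped sampling process
oracle_length_dist <- function(g, max_depth) {
  md <- oracle_min_depths(g)
  memo <- new.env(parent = emptyenv())
  dist <- function(sym, depth) {
    if (!(sym %in% names(md))) return(c(`1` = 1))  # bare terminal
    key <- paste(sym, depth)
    got <- get0(key, envir = memo)
    if (!is.null(got)) return(got)
    ex <- oracle_expansions(g, sym, depth, max_depth, md)
    acc <- numeric(0)
    for (i in seq_along(ex$exps)) {
      e <- ex$exps[[i]]
      d <- c(`0` = 1)
      if (e$word) d <- c(`1` = 1)
      else for (s in e$rhs) d <- convolve_dist(d, dist(s, depth + 1))
      acc <- add_dist(acc, ex$p[i] * d)
    }
    assign(key, acc, envir = memo)
    acc
  }
  dist(g$start, 0)
}

convolve_dist <- function(a, b) {
  out <- numeric(0); nm <- integer(0)
  for (i in seq_along(a)) for (j in seq_along(b)) {
    L <- as.integer(names(a)[i]) + as.integer(names(b)[j])
    k <- match(L, nm)
    if (is.na(k)) { nm <- c(nm, L); out <- c(out, a[i] * b[j]) }
    else out[k] <- out[k] + a[i] * b[j]
  }
  stats::setNames(out, nm)[order(nm)]
}

add_dist <- function(a, b) {
  for (j in seq_along(b)) {
    L <- names(b)[j]
    if (L %in% names(a)) a[[L]] <- a[[L]] + b[[j]]
    else a[L] <- b[[j]]
  }
  a[order(as.integer(names(a)))]
}

# derivation entropy (bits) and expected yield length of the capped process
oracle_entropy_length <- function(g, max_depth) {
  md <- oracle_min_depths(g)
  memo <- new.env(parent = emptyenv())
  he <- function(sym, depth) {
    if (!(sym %in% names(md))) return(c(H = 0, EL = 1))
    key <- paste(sym, depth)
    got <- get0(key, envir = memo)
    if (!is.null(got)) return(got)
    ex <- oracle_expansions(g, sym, depth, max_depth, md)
    p <- ex$p
    H <- -sum(p[p > 0] * log2(p[p > 0]))
    EL <- 0
    for (i in seq_along(ex$exps)) {
      e <- ex$exps[[i]]
      if (e$word) { EL <- EL + p[i]; next }
      for (s in e$rhs) {
        sub <- he(s, depth + 1)
        H <- H + p[i] * sub[["H"]]
        EL <- EL + p[i] * sub[["EL"]]
      }
    }
    out <- c(H = H, EL = EL)
    assign(key, out, envir = memo)
    out
  }
  he(g$start, 0)
}

# every string of the grammar's (uncapped) language with yield <= maxlen,
# as whitespace-joined strings; brute-force enumeration with length pruning
oracle_language_strings <- function(g, maxlen) {
  nts <- unique(c(sapply(g$rules, `[[`, "lhs"), g$lexicon$pos))
  minlen <- stats::setNames(rep(Inf, length(nts)), nts)
  minlen[unique(g$lexicon$pos)] <- 1
  repeat {
    old <- minlen
    for (r in g$rules) {
      v <- sum(sapply(r$rhs, function(s) if (s %in% nts) minlen[[s]] else 1))
      if (v < minlen[[r$lhs]]) minlen[[r$lhs]] <- v
    }
    if (identical(old, minlen)) break
  }
  expand <- function(sym, budget) {
    if (!(sym %in% nts)) return(if (budget >= 1) sym else character(0))
    out <- character(0)
    for (w in g$lexicon$word[g$lexicon$pos == sym])
      if (budget >= 1) out <- c(out, w)
    for (r in g$rules) {
      if (r$lhs != sym) next
      need <- sum(sapply(r$rhs, function(s)
        if (s %in% nts) minlen[[s]] else 1))
      if (need > budget) next
      parts <- list("")
      rem <- budget
      ok <- TRUE
      seqs <- list(character(0))
      for (k in seq_along(r$rhs)) {
        rest_min <- if (k < length(r$rhs))
          sum(sapply(r$rhs[(k + 1):length(r$rhs)], function(s)
            if (s %in% nts) minlen[[s]] else 1)) else 0
        new_seqs <- list()
        for (sq in seqs) {
          used <- length(sq)
          sub <- expand(r$rhs[k], budget - used - rest_min)
          for (s2 in sub)
            new_seqs[[length(new_seqs) + 1]] <- c(sq, strsplit(s2, " ")[[1]])
        }
        seqs <- new_seqs
        if (!length(seqs)) { ok <- FALSE; break }
      }
      if (ok) out <- c(out, sapply(seqs, paste, collapse = " "))
    }
    unique(out)
  }
  expand(g$start, maxlen)
}
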