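#' Boolean grammar membership by chart parsing
#'
#' Decides whether a token sequence is in a grammar's string language, ignoring
#' weights. The grammar is binarized on the fly (long right-hand sides folded
#' into fresh chain symbols, unit productions closed transitively) and
#' membership is decided with a CKY chart. Empty productions are not
#' supported, so the empty sequence is never derivable.
#'
#' This is deliberately independent of the sampler: it serves as the
#' soundness oracle for generated sentences.
#'
#' @param grammar a [grammar()].
#' @param sentence character vector of tokens.
#' @return `TRUE` iff the sentence is derivable.
#' @export
is_derivable <- function(grammar, sentence) {
  n <- length(sentence)
  if (n == 0) return(FALSE)
  b <- binarize_grammar(grammar)
  ## chart[[i]][[l]]: set of symbols deriving tokens i..(i+l-1)
  chart <- vector("list", n)
  for (i in seq_len(n)) {
    chart[[i]] <- vector("list", n - i + 1)
    cell <- unique(c(b$lex_index[[sentence[i]]], character(0)))
    chart[[i]][[1]] <- unit_close(cell, b$unit_parents)
  }
  if (n > 1) for (l in 2:n) for (i in seq_len(n - l + 1)) {
    cell <- character(0)
    for (k in seq_len(l - 1)) {
      left <- chart[[i]][[k]]
      right <- chart[[i + k]][[l - k]]
      if (!length(left) || !length(right)) next
      for (a in left) {
        partners <- b$binary_index[[a]]
        if (is.null(partners)) next
        hit <- partners$right %in% right
        if (any(hit)) cell <- c(cell, partners$parent[hit])
      }
    }
    chart[[i]][[l]] <- unit_close(unique(cell), b$unit_parents)
  }
  grammar$start %in% chart[[1]][[n]]
}

## transitive closure over unit productions: add every parent of a present
## symbol until fixpoint
unit_close <- function(cell, unit_parents) {
  if (!length(unit_parents)) return(cell)
  repeat {
    add <- unique(unlist(unit_parents[intersect(names(unit_parents), cell)]))
    add <- setdiff(add, cell)
    if (!length(add)) return(cell)
    cell <- c(cell, add)
  }
}

#' @keywords internal
binarize_grammar <- function(g) {
  nts <- nonterminals(g)
  lex <- split(g$lexicon$pos, g$lexicon$word)
  binary <- list()   # list of c(parent, left, right)
  units <- list()    # list of c(parent, child)
  fresh <- 0L
  add_terminal_wrappers <- function(rhs) {
    ## terminals appearing directly in a rhs get a dedicated preterminal
    vapply(rhs, function(s) {
      if (s %in% nts) return(s)
      wrap <- paste0(".T_", s)
      lex[[s]] <<- unique(c(lex[[s]], wrap))
      wrap
    }, "")
  }
  for (r in g$rules) {
    rhs <- add_terminal_wrappers(r$rhs)
    if (length(rhs) == 1) {
      units[[length(units) + 1L]] <- c(r$lhs, rhs)
    } else {
      lhs <- r$lhs
      while (length(rhs) > 2) {
        fresh <- fresh + 1L
        mid <- paste0(".X", fresh)
        binary[[length(binary) + 1L]] <- c(lhs, rhs[1], mid)
        lhs <- mid
        rhs <- rhs[-1]
      }
      binary[[length(binary) + 1L]] <- c(lhs, rhs[1], rhs[2])
    }
  }
  ## index binary rules by left child for the inner CKY loop
  binary_index <- list()
  for (bi in binary) {
    e <- binary_index[[bi[2]]]
    binary_index[[bi[2]]] <- list(parent = c(e$parent, bi[1]),
                                  right = c(e$right, bi[3]))
  }
  unit_parents <- list()
  for (u in units)
    unit_parents[[u[2]]] <- c(unit_parents[[u[2]]], u[1])
  list(lex_index = lex, binary_index = binary_index,
       unit_parents = unit_parents)
}
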