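#' Sample a derivation tree from a weighted grammar
#'
#' Expansion choices are drawn with probability proportional to rule/lexicon
#' weights. Recursion is controlled by a depth cap: at each node the available
#' expansions are those whose every right-hand-side nonterminal can still
#' terminate within the remaining depth budget (minimal completion depth,
#' precomputed by fixpoint); weights are renormalized over the available set.
#' This guarantees termination and gives the sampler a well-defined analytic
#' distribution. If a nonterminal has no completable expansion at the cap, a
#' depth-exhaustion error naming it is raised.
#'
#' @param grammar a [grammar()].
#' @param max_depth maximum depth of any leaf (root at depth 0); must be at
#'   least the grammar's minimal derivation depth.
#' @param seed optional integer; when given, sampling runs in a local RNG state
#'   seeded with it.
#' @return a derivation tree: nested lists with fields `symbol`, `children`
#'   (absent for word leaves), and `rule_choice` (index into the canonical
#'   expansion list of the node's category).
#' @seealso [derivation_yield()], [generate_corpus()], [transform_derivation()]
#' @export
sample_sentence <- function(grammar, max_depth = 8L, seed = NULL) {
  md <- min_depths(grammar)
  if (max_depth < md[[grammar$start]])
    stop(sprintf("max_depth %d below minimal derivation depth %d",
                 max_depth, md[[grammar$start]]))
  sampler <- function() sample_node(grammar, grammar$start, 0L, max_depth, md)
  if (is.null(seed)) sampler() else withr::with_seed(seed, sampler())
}

sample_node <- function(g, sym, depth, max_depth, md) {
  exps <- expansions_of(g, sym)
  ok <- vapply(exps, function(e) {
    if (e$kind == "word") return(depth + 1L <= max_depth)
    all(vapply(e$rhs, function(s)
      if (s %in% names(md)) depth + 1L + md[[s]] <= max_depth else TRUE, TRUE))
  }, TRUE)
  if (!any(ok))
    stop(sprintf("depth exhausted: no completable expansion for '%s' at depth %d",
                 sym, depth))
  w <- vapply(exps, `[[`, 0, "w") * ok
  choice <- sample.int(length(exps), 1L, prob = w)
  e <- exps[[choice]]
  if (e$kind == "word")
    return(list(symbol = sym, rule_choice = choice,
                children = list(list(symbol = e$rhs))))
  children <- lapply(e$rhs, function(s) {
    if (s %in% names(md)) sample_node(g, s, depth + 1L, max_depth, md)
    else list(symbol = s)  # terminal used directly in a rhs
  })
  list(symbol = sym, rule_choice = choice, children = children)
}

#' Left-to-right terminal yield of a derivation tree
#'
#' @param tree a derivation tree from [sample_sentence()].
#' @return character vector of words.
#' @export
derivation_yield <- function(tree) {
  if (is.null(tree$children)) return(tree$symbol)
  unlist(lapply(tree$children, derivation_yield))
}

#' Replay a derivation's choices under a related grammar
#'
#' Maps a derivation sampled from one grammar onto another grammar with the
#' same rule inventory up to within-rule reordering (as produced by
#' [to_sov()]): each node keeps its expansion choice, and children are permuted
#' to follow the target rule's right-hand-side order. Matched derivations
#' therefore have identical token multisets under both grammars.
#'
#' @param tree derivation tree sampled from `from`.
#' @param from,to two `grammar` objects whose rule lists correspond
#'   index-by-index with right-hand sides equal up to permutation.
#' @return the transformed derivation tree (a derivation of `to`).
#' @export
transform_derivation <- function(tree, from, to) {
  if (is.null(tree$children)) return(tree)
  exps_from <- expansions_of(from, tree$symbol)
  e_from <- exps_from[[tree$rule_choice]]
  if (e_from$kind == "word") return(tree)
  e_to <- expansions_of(to, tree$symbol)[[tree$rule_choice]]
  if (length(e_to$rhs) != length(e_from$rhs) ||
      !identical(sort(e_to$rhs), sort(e_from$rhs)))
    stop(sprintf("rule %d of '%s' is not a permutation of its counterpart",
                 tree$rule_choice, tree$symbol))
  ## stable mapping of each target rhs position to a distinct source position
  used <- logical(length(e_from$rhs))
  perm <- vapply(e_to$rhs, function(s) {
    j <- which(e_from$rhs == s & !used)[1]
    used[j] <<- TRUE
    j
  }, 0L)
  out <- tree
  out$children <- lapply(tree$children[perm], transform_derivation, from, to)
  out
}

#' Sample a corpus of sentences from a grammar
#'
#' @param grammar a [grammar()].
#' @param n_sentences number of sentences (>= 0).
#' @param seed integer seed; generation is reproducible for a fixed seed.
#' @param max_depth depth cap passed to [sample_sentence()].
#' @return a [corpus()] with `condition = "structured"`.
#' @export
generate_corpus <- function(grammar, n_sentences, seed = 1L, max_depth = 8L) {
  stopifnot(n_sentences >= 0)
  md <- min_depths(grammar)
  if (max_depth < md[[grammar$start]])
    stop(sprintf("max_depth %d below minimal derivation depth %d",
                 max_depth, md[[grammar$start]]))
  sentences <- withr::with_seed(seed, {
    lapply(seq_len(n_sentences), function(i)
      derivation_yield(sample_node(grammar, grammar$start, 0L, max_depth, md)))
  })
  corpus(sentences, condition = "structured", grammar_name = grammar$name,
         seed = seed)
}
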