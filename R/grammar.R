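#' Weighted phrase-structure grammars
#'
#' A `grammar` object is a weighted context-free rewrite system together with a
#' lexicon. Phrasal rules expand nonterminal categories into sequences of
#' symbols; lexicon entries expand part-of-speech (preterminal) categories into
#' single words. Expansion probabilities are the rule/entry weights normalized
#' within each left-hand-side category, so weights need only be positive, not
#' sum to one.
#'
#' Nonterminals are identified by a declared list (the union of rule left-hand
#' sides and lexicon categories), not by casing; any other symbol appearing in
#' a right-hand side is a terminal word.
#'
#' @param rules list of phrasal rules, each `list(lhs = <chr>, rhs = <chr
#'   vector>, w = <positive weight>)`.
#' @param lexicon data.frame with columns `pos` (preterminal category), `word`,
#'   `w` (positive weight).
#' @param start start symbol, default `"S"`.
#' @param name grammar name used for corpus provenance.
#' @param verb_categories character vector of preterminal categories treated as
#'   verbs by [to_sov()].
#' @return an object of class `grammar`.
#' @seealso [toy_grammar()], [sample_sentence()], [to_sov()],
#'   [reweight_lexicon()], [is_derivable()]
#' @export
grammar <- function(rules, lexicon, start = "S", name = "grammar",
                    verb_categories = "V") {
  stopifnot(is.list(rules), is.data.frame(lexicon))
  lexicon <- data.frame(pos = as.character(lexicon$pos),
                        word = as.character(lexicon$word),
                        w = as.numeric(lexicon$w),
                        stringsAsFactors = FALSE)
  rules <- lapply(rules, function(r) {
    list(lhs = as.character(r$lhs), rhs = as.character(r$rhs),
         w = as.numeric(if (!is.null(r$w)) r$w else r$weight))
  })
  g <- structure(
    list(name = name, start = start, rules = rules, lexicon = lexicon,
         verb_categories = verb_categories),
    class = "grammar")
  validate_grammar(g)
  g
}

#' @export
print.grammar <- function(x, ...) {
  cat(sprintf("<grammar '%s'>  start: %s\n", x$name, x$start))
  cat(sprintf("  %d phrasal rules, %d lexicon entries, %d words, %d categories\n",
              length(x$rules), nrow(x$lexicon),
              length(unique(x$lexicon$word)), length(unique(x$lexicon$pos))))
  for (r in x$rules)
    cat(sprintf("  %s -> %s  [%g]\n", r$lhs, paste(r$rhs, collapse = " "), r$w))
  invisible(x)
}

nonterminals <- function(g) {
  unique(c(vapply(g$rules, `[[`, "", "lhs"), g$lexicon$pos))
}

#' @keywords internal
validate_grammar <- function(g) {
  ws <- c(vapply(g$rules, `[[`, 0, "w"), g$lexicon$w)
  if (any(!is.finite(ws)) || any(ws <= 0))
    stop("all rule and lexicon weights must be positive and finite")
  nts <- nonterminals(g)
  if (!g$start %in% nts)
    stop(sprintf("start symbol '%s' has no expansion", g$start))
  ## rhs symbols outside the declared nonterminals are bare terminals
  md <- min_depths(g)
  if (any(!is.finite(md)))
    stop(sprintf("unproductive nonterminal(s): %s",
                 paste(names(md)[!is.finite(md)], collapse = ", ")))
  invisible(TRUE)
}

#' Minimal derivation depth of every nonterminal
#'
#' Computed by fixpoint iteration: a preterminal with lexicon entries has depth
#' 1 (its word is a leaf one level below); a phrasal category has depth one
#' more than the cheapest rule, whose cost is the maximum over its right-hand
#' side. Terminals cost 0. `Inf` marks an unproductive category.
#' @keywords internal
min_depths <- function(g) {
  nts <- nonterminals(g)
  m <- rep(Inf, length(nts)); names(m) <- nts
  lex_pos <- unique(g$lexicon$pos)
  m[lex_pos] <- 1
  repeat {
    changed <- FALSE
    for (r in g$rules) {
      costs <- vapply(r$rhs, function(s) if (s %in% nts) m[[s]] else 0, 0)
      cand <- 1 + max(costs, 0)
      if (cand < m[[r$lhs]]) { m[[r$lhs]] <- cand; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

#' The default toy language
#'
#' A weighted phrase-structure grammar over 27 words in 4 part-of-speech
#' categories (2 determiners, 12 nouns, 12 verbs, 1 complementizer), with
#' relative-clause recursion: `S -> NP VP`, `NP -> Det N | Det N RC`,
#' `RC -> Comp VP`, `VP -> V NP`. Lexicon weights are uniform within category;
#' the recursive NP expansion has probability 0.25, which keeps the expected
#' sentence length finite well below any practical depth cap. The language
#' contains sentences such as "the farmer that finds a toddler loves a
#' scientist".
#'
#' @return a `grammar` object named `"toy"`.
#' @examples
#' g <- toy_grammar()
#' sentence <- derivation_yield(sample_sentence(g, seed = 1))
#' is_derivable(g, sentence)
#' @export
toy_grammar <- function() {
  nouns <- c("farmer", "toddler", "scientist", "mother", "bird", "woman",
             "child", "dog", "king", "queen", "teacher", "doctor")
  verbs <- c("finds", "loves", "hears", "discovers", "sees", "likes",
             "follows", "helps", "knows", "calls", "chases", "watches")
  lexicon <- rbind(
    data.frame(pos = "Det",  word = c("the", "a"), w = 1),
    data.frame(pos = "N",    word = nouns,         w = 1),
    data.frame(pos = "V",    word = verbs,         w = 1),
    data.frame(pos = "Comp", word = "that",        w = 1))
  rules <- list(
    list(lhs = "S",  rhs = c("NP", "VP"),        w = 1),
    list(lhs = "NP", rhs = c("Det", "N"),        w = 0.75),
    list(lhs = "NP", rhs = c("Det", "N", "RC"),  w = 0.25),
    list(lhs = "RC", rhs = c("Comp", "VP"),      w = 1),
    list(lhs = "VP", rhs = c("V", "NP"),         w = 1))
  grammar(rules, lexicon, start = "S", name = "toy", verb_categories = "V")
}

expansions_of <- function(g, sym) {
  ## canonical expansion order: phrasal rules first (grammar order), then
  ## lexicon entries (lexicon order); choice indices refer to this list
  idx <- which(vapply(g$rules, function(r) r$lhs == sym, TRUE))
  exps <- lapply(idx, function(i) {
    r <- g$rules[[i]]
    list(kind = "rule", rhs = r$rhs, w = r$w, rule_index = i)
  })
  li <- which(g$lexicon$pos == sym)
  c(exps, lapply(li, function(i) {
    list(kind = "word", rhs = g$lexicon$word[i], w = g$lexicon$w[i],
         rule_index = NA_integer_)
  }))
}

#' Transform a grammar from SVO to SOV constituent order
#'
#' Every phrasal rule whose right-hand side starts with a verb category
#' followed by a complement (e.g. `VP -> V NP`) is reordered so the complement
#' precedes the verb (`VP -> NP V`). Weights and all other rules are unchanged,
#' so the transformed grammar generates the same token multisets per matched
#' derivation, in a different order. Grammars without verb-complement rules are
#' returned unchanged.
#'
#' @param grammar a `grammar`.
#' @param verb_categories preterminal categories counted as verbs; defaults to
#'   the grammar's own declaration.
#' @return the reordered `grammar`, with `"-sov"` appended to its name when any
#'   rule changed.
#' @export
to_sov <- function(grammar, verb_categories = grammar$verb_categories) {
  changed <- FALSE
  rules <- lapply(grammar$rules, function(r) {
    if (length(r$rhs) >= 2 && r$rhs[1] %in% verb_categories) {
      r$rhs <- c(r$rhs[-1], r$rhs[1])
      changed <<- TRUE
    }
    r
  })
  if (!changed) return(grammar)
  g <- grammar
  g$rules <- rules
  g$name <- paste0(grammar$name, "-sov")
  validate_grammar(g)
  g
}

#' Multiply the lexicon weights of selected words
#'
#' Reweighting changes word frequencies without touching phrase structure:
#' a word with factor 2 becomes twice as probable as each of its unchanged
#' within-category peers.
#'
#' @param grammar a `grammar`.
#' @param factors named numeric vector or list, `word = factor`, factors > 0.
#' @return the reweighted `grammar`, `"-reweighted"` appended to its name.
#' @examples
#' g <- reweight_lexicon(toy_grammar(), c(woman = 2, discovers = 2, a = 2))
#' @export
reweight_lexicon <- function(grammar, factors) {
  factors <- unlist(factors)
  unknown <- setdiff(names(factors), grammar$lexicon$word)
  if (length(unknown))
    stop(sprintf("word(s) not in lexicon: %s", paste(unknown, collapse = ", ")))
  if (any(factors <= 0)) stop("reweighting factors must be positive")
  g <- grammar
  idx <- match(names(factors), g$lexicon$word)
  g$lexicon$w[idx] <- g$lexicon$w[idx] * factors
  g$name <- paste0(grammar$name, "-reweighted")
  g
}

#' Read / write grammars as JSON
#'
#' The file format has keys `name`, `start`, `verb_categories`,
#' `rules` (`lhs`, `rhs`, `w`) and `lexicon` (`pos`, `word`, `w`).
#'
#' @param grammar a `grammar`.
#' @param path file path.
#' @return `read_grammar` returns a `grammar`; `write_grammar` invisibly
#'   returns `path`.
#' @export
write_grammar <- function(grammar, path) {
  obj <- list(name = grammar$name, start = grammar$start,
              verb_categories = as.list(grammar$verb_categories),
              rules = lapply(grammar$rules, function(r)
                list(lhs = r$lhs, rhs = as.list(r$rhs), w = r$w)),
              lexicon = grammar$lexicon)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_grammar
#' @export
read_grammar <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  rules <- lapply(obj$rules, function(r)
    list(lhs = r$lhs, rhs = unlist(r$rhs), w = r$w))
  lex <- do.call(rbind, lapply(obj$lexicon, function(e)
    data.frame(pos = e$pos, word = e$word, w = e$w)))
  grammar(rules, lex, start = obj$start, name = obj$name,
          verb_categories = unlist(obj$verb_categories))
}
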