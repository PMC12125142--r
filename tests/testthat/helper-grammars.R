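# Small fixture grammars built in code.

# single-word language: S expands to the one lexicon entry
single_word_grammar <- function() {
  grammar(rules = list(), lexicon = data.frame(pos = "S", word = "w", w = 1),
          start = "S", name = "single")
}

# tiny two-noun / two-verb version of the toy language, handy when a test
# needs exhaustive enumeration to stay small
mini_grammar <- function(np_rc_weight = 0.25) {
  lexicon <- rbind(
    data.frame(pos = "Det", word = c("the", "a"), w = 1),
    data.frame(pos = "N", word = c("cat", "dog"), w = 1),
    data.frame(pos = "V", word = c("sees", "hears"), w = 1),
    data.frame(pos = "Comp", word = "that", w = 1))
  rules <- list(
    list(lhs = "S", rhs = c("NP", "VP"), w = 1),
    list(lhs = "NP", rhs = c("Det", "N"), w = 1 - np_rc_weight),
    list(lhs = "NP", rhs = c("Det", "N", "RC"), w = np_rc_weight),
    list(lhs = "RC", rhs = c("Comp", "VP"), w = 1),
    list(lhs = "VP", rhs = c("V", "NP"), w = 1))
  grammar(rules, lexicon, start = "S", name = "mini", verb_categories = "V")
}

# the mini language with every word renamed, giving a disjoint inventory
mini_grammar_renamed <- function(prefix = "x") {
  g <- mini_grammar()
  g$lexicon$word <- paste0(prefix, g$lexicon$word)
  g$name <- paste0("mini-", prefix)
  g
}

# build a derivation tree by hand; `choice` indexes the canonical expansion
# list (phrasal rules in grammar order, then lexicon entries)
dnode <- function(symbol, choice, ...) {
  kids <- list(...)
  if (!length(kids)) stop("leaf nodes are built by dword()")
  list(symbol = symbol, rule_choice = choice, children = kids)
}
dword <- function(pos, choice, word) {
  list(symbol = pos, rule_choice = choice,
       children = list(list(symbol = word)))
}

# corpus of fixed sentences (each a whitespace string), repeated `times`
fixed_corpus <- function(strings, times = 1) {
  corpus(rep(lapply(strings, function(s) strsplit(s, " ")[[1]]), times))
}
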