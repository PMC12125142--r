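---
title: "Simulating what lexical surprisal does and does not encode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating what lexical surprisal does and does not encode}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surprisim)
```

## The question the simulation answers

Lexical surprisal — the Shannon information of a word given its context,
$I(w_i) = -\log_2 p(w_i \mid w_1 \dots w_{i-1})$ in bits — is among the most
robust predictors of reading times and neural responses to language. Because
it is computed from surface word sequences alone, it is
*representation-agnostic*: any latent factor that shapes word order or word
frequency leaks into the estimates, but the estimate itself does not say
which factor. `surprisim` packages a controlled simulation of that
situation. We build a toy language whose latent structure we fully control,
manipulate exactly one property at a time, and measure what happens to the
surprisal estimates a language model assigns.

The accompanying estimator of uncertainty is prefix entropy,
$H = -\sum_v p(v \mid \text{prefix}) \log_2 p(v \mid \text{prefix})$, the
expected surprisal of the next token (`prefix_entropy()`,
`entropy_reduction()`).

## The toy language

`toy_grammar()` is a weighted phrase-structure grammar over 27 words in 4
part-of-speech categories — 2 determiners, 12 nouns, 12 verbs, and the
complementizer *that* — with the rules

```
S  -> NP VP          NP -> Det N      (w = 0.75)
VP -> V NP           NP -> Det N RC   (w = 0.25)
RC -> Comp VP
```

Relative clauses make the language recursive: it contains sentences such as
*the farmer that finds a toddler loves a scientist*. The 27-word / 4-category
inventory and the example sentences pin down the grammar's shape, but the
production weights are a design choice of this package — uniform within
each lexical category — and the JSON grammar format
(`read_grammar()`/`write_grammar()`) lets any other inventory or weighting
be dropped in verbatim. The
recursion weight 0.25 keeps the expected sentence length finite and short
(analytically, 7.0 words at the default depth cap); absolute surprisal
levels reported by the pipeline are a property of *this* grammar's entropy
and will differ under a different inventory, whereas the contrasts between
training conditions are the object of study and are far less sensitive to
it.

### Sampling and the depth cap

`sample_sentence()` expands nonterminals top-down, choosing each expansion
with probability proportional to its weight. Unbounded recursion is
controlled by a depth cap (default 8): at each node, expansions whose
right-hand-side categories cannot all terminate within the remaining depth
budget are masked and the weights renormalized over the survivors. We chose
masking-with-renormalization over rejection sampling because it guarantees
termination and gives the sampler an exactly computable distribution — the
test suite derives sentence-length distributions and the language's entropy
rate by dynamic programming over (category, depth) pairs and checks the
sampler against them. The cost is a small truncation bias relative to the
uncapped grammar (deep right-branching chains are redistributed onto
shallower structures); both the cap and its consequences are fixed study
conditions, identical across every training condition.

A deliberately independent chart parser (`is_derivable()`, CKY over a
binarized grammar with unit-production closure) provides the membership
oracle: every generated sentence must parse.

## The four training conditions

* **structured** — sentences as generated.
* **scrambled** — `scramble_corpus()` permutes each sentence's tokens
  uniformly at random. Per-sentence token multisets, sentence lengths, and
  all corpus-level frequency statistics are exactly preserved (tested
  bit-identically); only syntax is destroyed. The identity permutation is
  allowed — excluding it would distort the uniform distribution over
  permutations.
* **sov** — `to_sov()` reorders every rule whose right-hand side begins
  with a verb category so the complement precedes the verb
  (`VP -> V NP` becomes `VP -> NP V`), turning the SVO language into an SOV
  language with identical word frequencies. Matched derivations yield
  identical token multisets (`transform_derivation()` replays one
  derivation under the other grammar, and the documented example maps
  *the mother hears the scientist that discovers the bird* onto
  *the mother the scientist that the bird discovers hears*).
* **reweighted** — `reweight_lexicon()` doubles the lexicon weights of
  *woman*, *discovers* and *a*, changing word frequencies without touching
  structure.

`split_corpus()` deduplicates sentences by their string before splitting, so
held-out test sentences never occur in any training corpus. Unique strings
are assigned to the two sides; the training side keeps every original
occurrence (training frequencies matter), the test side keeps one occurrence
per string. Because the SOV and reweighted corpora are regenerated from
their transformed grammars rather than derived from the training corpus,
the pipeline additionally filters them against the shared test strings —
the reweighted grammar in particular can regenerate test sentences
verbatim, which would quietly break the held-out property.

## Language models

Two backends satisfy one scoring contract (`next_token_distribution()`,
`surprisal_sequence()`, `corpus_surprisal()`), and shared contract tests
exercise both.

**n-gram** (`train_ngram()`): counts with `order - 1` start padding and one
end token per sentence; smoothing by Katz backoff with Good–Turing
discounting of counts up to 7 (the classic SRILM recipe; the discount
cutoff adapts downward when count-of-counts statistics are too sparse for
the usual formula, counts whose Good–Turing discount is undefined fall
back to an absolute discount of 0.5, and when a context's backoff
distribution has no mass
left on the unseen set the reserved mass is spread uniformly so every
emitted distribution still sums to one). Additive and raw-MLE smoothing are
available; MLE zeros yield infinite surprisal and a warning, never silent
drops.

**LSTM** (`train_recurrent()`): a single-layer LSTM implemented in
C++/Armadillo inside the package — forward pass, backpropagation through
time over whole sentences, Adam, global-norm gradient clipping. Defaults:
embedding 32, hidden 64, 10 epochs, batch 64, learning rate 1e-3, clip 5.
These are deliberately modest: the toy vocabulary has ~30 types and the
training loss approaches the language's analytic entropy rate within a few
epochs (with 10,000 training sentences the mean test cross-entropy lands
within ~0.01 bits of the 2.308 bits/token rate). A different architecture
or size will shift absolute surprisal values; the configuration object is
recorded in every model and manifest for that reason. All randomness —
initialization, batch shuffling — comes from an internal generator seeded
explicitly, so a (seed, config, corpus) triple reproduces a model
bit-identically on a fixed BLAS.

Surprisal is reported in bits, base 2, throughout. The end-of-sentence
event is trained always but *excluded* from reported per-word tables by
default (reported distributions are over words; `include_eos = TRUE` is
used where chain-rule identities or cross-entropy bounds need the full
joint probability).

## Statistical readouts

`compare_distributions()` implements the pooled two-sample Student t
(df = n1 + n2 − 2, which is what reported degrees of freedom of the form
2n − 2 identify; Welch is available behind a flag), Cohen's d with pooled
standard deviation, the confidence interval of the mean difference from the
pooled standard error, and post-hoc power at the observed effect size via
the noncentral t distribution. Power is post-hoc because it is reported
alongside observed statistics. `token_aligned_correlation()` joins two
surprisal tables on identical (sentence, position, token) keys — the only
construction under which df = n − 2 equals the shared test-set token count
minus two — and is exact about misalignment: any divergent key is an error,
not a silent inner join.

## The classification probe

`run_classification()` asks whether windows of consecutive surprisal values
betray which language they came from. Windows are sliding, stride 1, and
never cross a sentence boundary (the sentence is the scoring unit; windows
of size n from a sentence of length L number max(0, L − n + 1)). Values can
be z-scored per source corpus and/or rounded to the nearest multiple of a
grain (rounding applied after z-scoring); rounding is the control that
removes value-uniqueness as a cue. The classifier is a 100-tree random
forest; classes are balanced by downsampling before an 80/20 stratified
split. The split unit defaults to the window; a sentence-level split flag
exists because overlapping windows share tokens across a window-level
split, and leakage-sensitive analyses should use it.

In our toy replication the uniqueness confound is vivid: two structurally
different toy languages over disjoint word inventories classify near
ceiling from single z-scored values, because almost every value occurs in
only one language. After coarse rounding the ceiling collapses and accuracy
instead *grows* with window size — the sequential pattern, not the
individual value, carries what remains.

## Study conditions and test-scale choices

The full study condition — run by `scripts/acceptance.R` and reproduced by
`run_toy_experiment()` defaults — uses 10,000 training sentences and a
held-out test set of ~5,000 unique sentences (~30-38k word tokens,
depending on the seed), 10 training epochs,
and all four conditions. The test suite exercises the same claims at
reduced sizes chosen so each effect is still clearly resolved: the 20-seed
directional contrast runs at 600 training sentences with a faster learning
rate (5e-3, 10 epochs; median structured-vs-scrambled difference ~1.4 bits,
far from the decision boundary), the shared moderate run uses 2,500/1,200
sentences, and the entropy-rate recovery ladder uses 800 → 2,500 → 7,000
sentences at 5 epochs. These sizes are package choices documented here so
that anyone scaling them up knows the defaults were not tuned per effect.

## Numerical choices and degenerate inputs

* All distributions must sum to 1 within 1e-9; the n-gram backend achieves
  this analytically (leftover backoff mass accounted in closed form), the
  LSTM by construction of the softmax.
* Zero pooled variance with unequal means yields an infinite t and a
  warning; zero variance in a correlation yields NA with a warning.
* Z-scoring a constant vector is an error (no silent division by zero).
* Ties in rounding follow R's round-half-to-even; the rounding grain is a
  parameter, so tests avoid exact half-ties.
* Depth-exhaustion during sampling is impossible when the cap is at least
  the grammar's minimal derivation depth (checked up front); the sampler
  still carries a defensive error naming the blocked category.

## Known limitations

The toy language has no ambiguity, no intransitives, no morphology, and a
closed 27-word vocabulary; passing tests show that the pipeline's contrasts
behave as designed under these conditions, not that the magnitudes transfer
to natural corpora. The plain-text corpus path (`read_corpus()` on
one-sentence-per-line text) supports running the identical pipeline on real
corpora, but no external data ships with the package. Absolute surprisal
levels depend on the default grammar's weights (uniform here); a grammar
with a different weighting will shift every mean while leaving the
between-condition contrasts qualitatively intact.
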