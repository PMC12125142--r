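# surprisim

Simulation tools for asking what lexical **surprisal** — the Shannon
information of a word in context,

$$I(w_i) = -\log_2 p(w_i \mid w_1 \dots w_{i-1}) \quad \text{[bits]}$$

— does and does not encode about the latent structure of a language.
Surprisal and its companion, prefix entropy
$H = -\sum_v p(v \mid \text{prefix})\,\log_2 p(v \mid \text{prefix})$, are
the workhorse predictors of computational psycholinguistics and the
cognitive neuroscience of language. They are also *representation-agnostic*:
syntax, word frequency and word order all leak into the same scalar. This
package is for researchers who want to take that confound apart under
controlled conditions.

`surprisim` builds a toy language from a weighted phrase-structure grammar
(27 words, 4 parts of speech, relative-clause recursion), manipulates
exactly one property of the training data at a time, and measures the
consequences for model-derived surprisal:

* **scrambling** — permute words within each sentence: destroys syntax,
  exactly preserves word frequencies and sentence lengths;
* **SOV transform** — move verb complements before the verb: same word
  frequencies, different constituent order;
* **lexicon reweighting** — double the frequency of a few words: same
  syntax, different word frequencies.

Per-token surprisal is estimated with two interchangeable language-model
backends — Katz/Good–Turing-smoothed n-grams and a single-layer LSTM
(implemented in C++ inside the package) — and the consequences are
quantified with pooled two-sample *t* tests, Cohen's *d*, post-hoc power,
token-aligned Pearson correlations, and a random-forest classifier that
tries to identify a language from windows of 1–10 consecutive surprisal
values (with z-scoring and a nearest-0.1 rounding control).

## A worked example

Train one LSTM on structured toy-language sentences and a second on the
same sentences scrambled, score both on a shared held-out structured test
set, and compare:

```r
library(surprisim)

cfg <- experiment_config(train_sentences = 2000, test_sentences = 1000,
                         conditions = "scrambled",
                         lm_config = rnn_config(epochs = 8), seed = 42)
res <- run_toy_experiment(cfg, quiet = TRUE)

res$comparisons$scrambled
#> Two-sample comparison (Student pooled t)
#>   M1 = 4.217 (sd 1.358, n 6621);  M2 = 2.764 (sd 1.354, n 6621)
#>   diff = 1.453 bits, CI[1.406, 1.499];  t(13,240) = 61.64, p = 0
#>   Cohen's d = 1.071, power = 1 (alpha 0.05)

res$correlations$scrambled
#> Token-aligned Pearson correlation: r(6,619) = 0.954, p = 0 (n = 6621)
```

Reading: the scrambled-trained model (M1) is on average ~1.45 bits more
surprised by grammatical test sentences than the structured-trained model
(M2) — syntactic structure in the training input lowers surprisal. Yet the
two models' per-token values correlate at r ≈ 0.95: most of the variance in
surprisal comes from word frequency, which scrambling preserves, not from
syntax.

Individual words can be scored against any trained model, here a Katz
trigram:

```r
m <- train_ngram(res$train, 3, smoothing = "katz")
sent <- strsplit("the farmer that finds a toddler loves a scientist", " ")[[1]]
cbind(token = sent, bits = round(surprisal_sequence(m, sent)$surprisal, 2))
#>       token       bits
#>  [1,] "the"       "1.03"
#>  [2,] "farmer"    "3.98"
#>  [3,] "that"      "2.64"
#>  [4,] "finds"     "5.17"
#>  [5,] "a"         "1"
#>  [6,] "toddler"   "3.81"
#>  [7,] "loves"     "3.77"
#>  [8,] "a"         "0.87"
#>  [9,] "scientist" "3.8"
```

Determiners are cheap (~1 bit: two choices), nouns cost ~log2(12) ≈ 3.6
bits, and the relative-clause verb *finds* is dearest — the grammar makes
it rare in that position.

The whole pipeline (four conditions, comparisons, correlations, optional
window classification) is also runnable from a shell:

```sh
Rscript inst/scripts/toy-experiment.R --seed 1 --out runs/toy --train 10000 --test 5000
```

## Package tour

| area | functions |
|---|---|
| grammars | `grammar()`, `toy_grammar()`, `to_sov()`, `reweight_lexicon()`, `read_grammar()`/`write_grammar()` |
| generation | `sample_sentence()`, `generate_corpus()`, `derivation_yield()`, `transform_derivation()`, `is_derivable()` |
| corpora | `corpus()`, `scramble_corpus()`, `split_corpus()`, `read_corpus()`/`write_corpus()` |
| language models | `train_ngram()`, `train_recurrent()`, `rnn_config()`, `next_token_distribution()` |
| surprisal / entropy | `surprisal_sequence()`, `corpus_surprisal()`, `prefix_entropy()`, `entropy_reduction()`, TSV I/O |
| statistics | `compare_distributions()`, `token_aligned_correlation()`, `write_report()` |
| classification | `make_windows()`, `preprocess_values()`, `run_classification()` |
| orchestration | `experiment_config()`, `run_toy_experiment()`, `derive_seed()` |

The methods vignette (`vignettes/surprisal-simulation.Rmd`) documents the
model assumptions, the depth-capped sampling scheme and its analytic
oracles, every default that matters, and known limitations.
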