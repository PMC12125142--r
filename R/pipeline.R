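#' Derive a stage seed from a master seed
#'
#' Deterministic keyed fan-out: the stage name is hashed (FNV-1a, 32-bit) and
#' folded with the master seed into a positive integer below 2^31, so every
#' pipeline stage gets an independent, reproducible, loggable seed.
#'
#' @param master integer master seed.
#' @param stage character stage key.
#' @return integer seed in `[1, 2^31 - 1]`.
#' @export
derive_seed <- function(master, stage) {
  h <- fnv1a(stage)
  as.integer((as.numeric(master) * 2654435761 + h) %% 2147483646) + 1L
}

fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  h
}

## small content hash for manifests (hex string)
content_hash <- function(x) {
  s <- paste(unlist(x), collapse = "\x1f")
  h1 <- fnv1a(s)
  h2 <- fnv1a(paste0("#", s))
  sprintf("%08x%08x", as.integer(h1 %% 2^31), as.integer(h2 %% 2^31))
}

#' Configuration of a toy surprisal experiment
#'
#' Defaults reproduce the toy study conditions: 10,000 training sentences
#' plus a held-out test set of about 5,000 unique sentences (roughly 31k-38k
#' word tokens) from [toy_grammar()]; one identically configured LSTM per
#' condition; the words `woman`, `discovers` and `a` doubled in the
#' reweighted condition; alpha 0.05.
#'
#' @param grammar a [grammar()].
#' @param train_sentences,test_sentences target corpus sizes (sentences).
#' @param conditions subset of `c("scrambled", "sov", "reweighted")` to train
#'   besides the always-present structured condition.
#' @param lm_config an [rnn_config()].
#' @param reweight_factors named factors for the reweighted condition.
#' @param alpha significance level for comparisons.
#' @param max_depth derivation depth cap.
#' @param classify also run the window classifier on
#'   structured-vs-scrambled surprisal tables.
#' @param seed master seed; all stage seeds are derived from it.
#' @return a list of class `experiment_config`.
#' @export
experiment_config <- function(grammar = toy_grammar(),
                              train_sentences = 10000L,
                              test_sentences = 5000L,
                              conditions = c("scrambled", "sov", "reweighted"),
                              lm_config = rnn_config(),
                              reweight_factors = c(woman = 2, discovers = 2,
                                                   a = 2),
                              alpha = 0.05, max_depth = 8L,
                              classify = FALSE, seed = 1L) {
  conditions <- match.arg(conditions, several.ok = TRUE)
  structure(list(grammar = grammar, train_sentences = train_sentences,
                 test_sentences = test_sentences, conditions = conditions,
                 lm_config = lm_config, reweight_factors = reweight_factors,
                 alpha = alpha, max_depth = max_depth, classify = classify,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run the toy surprisal experiment end to end
#'
#' Executes the whole pipeline: generate a structured corpus, deduplicate and
#' split it into train and held-out test sets, derive the configured
#' condition corpora (per-sentence scrambling of the same training sentences;
#' matched-size corpora regenerated from the SOV-transformed and
#' lexicon-reweighted grammars, filtered against the test strings), train one
#' LSTM per condition, score every model on the single shared structured test
#' set, and compare each condition against the structured baseline
#' ([compare_distributions()] and [token_aligned_correlation()]). The test
#' set is constructed once; its content hash is recorded in the manifest and
#' every artifact is traceable to the stage seeds derived from the master
#' seed.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional directory; when given, corpora, surprisal tables,
#'   reports and the manifest are written there.
#' @param quiet suppress per-stage progress messages.
#' @return a list with elements `manifest`, `models`, `tables` (one surprisal
#'   table per condition), `comparisons`, `correlations`, and optionally
#'   `classification`.
#' @export
run_toy_experiment <- function(config = experiment_config(), out_dir = NULL,
                               quiet = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  g <- config$grammar
  seeds <- list(
    generate = derive_seed(config$seed, "generate"),
    split = derive_seed(config$seed, "split"),
    scramble = derive_seed(config$seed, "scramble"),
    sov = derive_seed(config$seed, "sov-generate"),
    reweighted = derive_seed(config$seed, "reweighted-generate"),
    train = derive_seed(config$seed, "train"),
    classify = derive_seed(config$seed, "classify"))

  n_total <- config$train_sentences + config$test_sentences
  say("generate: %d sentences from grammar '%s'", n_total, g$name)
  full <- generate_corpus(g, n_total, seed = seeds$generate,
                          max_depth = config$max_depth)
  say("split: holding out ~%d unique test sentences", config$test_sentences)
  parts <- split_corpus(full, config$test_sentences / n_total,
                        seed = seeds$split)
  train <- parts$train; test <- parts$test
  test_strings <- sentence_strings(test)

  corpora <- list(structured = train)
  if ("scrambled" %in% config$conditions)
    corpora$scrambled <- scramble_corpus(train, seed = seeds$scramble)
  if ("sov" %in% config$conditions) {
    gs <- to_sov(g)
    corpora$sov <- filter_test_overlap(
      generate_corpus(gs, length(train), seed = seeds$sov,
                      max_depth = config$max_depth), test_strings, "sov")
  }
  if ("reweighted" %in% config$conditions) {
    gr <- reweight_lexicon(g, config$reweight_factors)
    corpora$reweighted <- filter_test_overlap(
      generate_corpus(gr, length(train), seed = seeds$reweighted,
                      max_depth = config$max_depth), test_strings,
      "reweighted")
  }

  models <- list(); tables <- list()
  for (cond in names(corpora)) {
    say("train: %s LSTM on %d sentences", cond, length(corpora[[cond]]))
    models[[cond]] <- train_recurrent(
      corpora[[cond]], config$lm_config,
      seed = derive_seed(seeds$train, cond))
    tables[[cond]] <- corpus_surprisal(models[[cond]], test,
                                       model_id = cond,
                                       corpus_id = "structured-test")
  }

  comparisons <- list(); correlations <- list()
  for (cond in setdiff(names(tables), "structured")) {
    comparisons[[cond]] <- compare_distributions(
      tables[[cond]]$surprisal, tables$structured$surprisal,
      alpha = config$alpha)
    correlations[[cond]] <- token_aligned_correlation(
      tables$structured, tables[[cond]])
  }

  classification <- NULL
  if (isTRUE(config$classify) && "scrambled" %in% names(tables)) {
    say("classify: structured vs scrambled surprisal windows")
    classification <- run_classification(
      tables$structured, tables$scrambled, seed = seeds$classify)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("surprisim")),
    grammar = g$name, master_seed = config$seed, stage_seeds = seeds,
    train_sentences = length(train),
    test_sentences = length(test),
    test_tokens = sum(lengths(test$sentences)),
    test_set_hash = content_hash(test_strings),
    conditions = names(corpora),
    lm_config = unclass(config$lm_config),
    condition_sentences = vapply(corpora, length, 0L))

  result <- list(manifest = manifest, models = models, tables = tables,
                 comparisons = comparisons, correlations = correlations,
                 classification = classification,
                 train = train, test = test)
  if (!is.null(out_dir)) write_experiment(result, out_dir)
  result
}

## drop condition training sentences whose string coincides with a held-out
## test sentence, preserving the held-out property across grammars
filter_test_overlap <- function(corp, test_strings, label) {
  keep <- !(sentence_strings(corp) %in% test_strings)
  corp$sentences <- corp$sentences[keep]
  corp$condition <- label
  corp
}

write_experiment <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_corpus(result$train, file.path(out_dir, "train.txt"))
  write_corpus(result$test, file.path(out_dir, "test.txt"))
  for (cond in names(result$tables))
    write_surprisal_table(result$tables[[cond]],
                          file.path(out_dir, paste0("surprisal-", cond, ".tsv")))
  for (cond in names(result$comparisons)) {
    write_report(result$comparisons[[cond]],
                 file.path(out_dir, paste0("comparison-", cond, ".json")),
                 contrast = paste0(cond, " vs structured"))
    write_report(result$correlations[[cond]],
                 file.path(out_dir, paste0("correlation-", cond, ".json")),
                 contrast = paste0("structured vs ", cond))
  }
  if (!is.null(result$classification))
    jsonlite::write_json(result$classification,
                         file.path(out_dir, "classification.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
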