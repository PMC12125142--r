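Package: surprisim
Title: Simulating What Lexical Surprisal Does and Does Not Encode
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the information content of lexical surprisal by
    simulation. Generates corpora from weighted phrase-structure grammars with
    relative-clause recursion, manipulates them (within-sentence scrambling,
    SVO-to-SOV constituent reordering, lexicon frequency reweighting), trains
    next-word language models (Katz/Good-Turing smoothed n-grams and an LSTM
    implemented in C++), extracts per-token surprisal and prefix entropy in bits,
    and quantifies the consequences with two-sample effect-size statistics,
    token-aligned correlations, and a random-forest classifier over windows of
    surprisal values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    randomForest,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
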