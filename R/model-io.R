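#' Save and load trained language models
#'
#' Both backends serialize to plain JSON. An n-gram model stores its
#' per-order count tables plus the smoothing configuration and vocabulary;
#' the scoring structures (context tables, discounts, base distribution)
#' are rebuilt on load, so a round-tripped model scores identically. A
#' recurrent model stores its weight matrices at full double precision
#' together with a manifest (architecture configuration, training seed,
#' vocabulary, per-epoch loss).
#'
#' @param model an `ngram_model` or `rnn_lm`.
#' @param path JSON file path.
#' @return `read_language_model` returns the model;
#'   `write_language_model` invisibly returns `path`.
#' @export
write_language_model <- function(model, path) {
  obj <- if (inherits(model, "ngram_model")) {
    list(backend = "ngram", order = model$order, smoothing = model$smoothing,
         k = model$k, vocab = as.character(model$vocab),
         counts = lapply(model$tab, function(t)
           list(keys = names(t), values = unname(t))))
  } else if (inherits(model, "rnn_lm")) {
    list(backend = "recurrent",
         config = unclass(model$config), seed = model$seed,
         vocab = as.character(model$vocab),
         epoch_loss_bits = model$epoch_loss_bits,
         params = lapply(model$params, function(m) {
           if (is.matrix(m)) list(dim = dim(m), data = as.numeric(m))
           else list(dim = length(m), data = as.numeric(m))
         }))
  } else stop("not a language model")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_language_model
#' @export
read_language_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  voc <- unlist(obj$vocab)
  vocab <- structure(voc, predictable = setdiff(voc, BOS),
                     class = "lm_vocab")
  if (obj$backend == "ngram") {
    tab <- lapply(obj$counts, function(t)
      stats::setNames(as.numeric(unlist(t$values)),
                      as.character(unlist(t$keys))))
    ngram_from_counts(tab, obj$order, obj$smoothing, obj$k, vocab)
  } else if (obj$backend == "recurrent") {
    params <- lapply(obj$params, function(p) {
      d <- unlist(p$dim)
      v <- as.numeric(unlist(p$data))
      if (length(d) == 2) matrix(v, d[1], d[2]) else v
    })
    cfg <- do.call(rnn_config, lapply(obj$config, unlist))
    structure(list(params = params[c("E", "W", "U", "Wy", "b", "by")],
                   epoch_loss_bits = as.numeric(unlist(obj$epoch_loss_bits)),
                   vocab = vocab, config = cfg, seed = as.integer(obj$seed)),
              class = "rnn_lm")
  } else stop(sprintf("unknown model backend '%s'", obj$backend))
}
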