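# R surface of the gap-filling generator: config, training, decoding,
# perplexity, the no-model copy baseline, and checkpoint save/load.

GENERATOR_FORMAT <- "synthnotes-gapfill-v1"

#' Generator configuration
#'
#' The generator is a single-layer attention encoder-decoder with tied token
#' embeddings: encoder states are position-tagged input embeddings, and each
#' decoder step attends over them with a learned query built from the previous
#' target token and the decoder position, then emits a softmax over the
#' vocabulary. `embedding_dim` is the model's scale knob; all gradients are
#' explicit, so training is deterministic given `seed`.
#'
#' @param architecture `"attention_ed"` (the trained model) or
#'   `"copy_baseline"` (no parameters; reproduces its key-phrase input).
#' @param embedding_dim embedding and state width.
#' @param max_input_len,max_output_len positional-embedding capacity; inputs
#'   beyond `max_input_len` are truncated, decoding stops at
#'   `max_output_len`.
#' @param epochs,learning_rate Adam training schedule (one update per pair).
#' @param decoding `"greedy"` (deterministic, the default) or `"beam"`.
#' @param beam_width beam size when `decoding = "beam"`.
#' @param seed integer seed for initialisation and example shuffling.
#' @return a validated config list, classed `generator_config`.
#' @export
generator_config <- function(architecture = c("attention_ed", "copy_baseline"),
                             embedding_dim = 32L, max_input_len = 40L,
                             max_output_len = 30L, epochs = 12L,
                             learning_rate = 0.01,
                             decoding = c("greedy", "beam"), beam_width = 1L,
                             seed = 1L) {
  cfg <- list(
    architecture = match.arg(architecture),
    embedding_dim = as.integer(embedding_dim),
    max_input_len = as.integer(max_input_len),
    max_output_len = as.integer(max_output_len),
    epochs = as.integer(epochs),
    learning_rate = learning_rate,
    decoding = match.arg(decoding),
    beam_width = as.integer(beam_width),
    seed = as.integer(seed)
  )
  stopifnot(cfg$embedding_dim >= 2L, cfg$max_input_len >= 1L,
            cfg$max_output_len >= 1L, cfg$epochs >= 1L,
            cfg$learning_rate > 0, cfg$beam_width >= 1L)
  class(cfg) <- "generator_config"
  cfg
}

encode_pairs <- function(pairs, vocab) {
  list(
    inputs = lapply(strsplit(pairs$input, " ", fixed = TRUE),
                    function(t) encode_tokens(t[nzchar(t)], vocab)),
    targets = lapply(strsplit(pairs$target, " ", fixed = TRUE),
                     function(t) encode_tokens(t[nzchar(t)], vocab))
  )
}

#' Train the gap-filling generator
#'
#' Fits the attention encoder-decoder by maximising target-sequence
#' likelihood given the conditioned input, with one Adam update per pair.
#' The vocabulary is built from the training pairs only; passing a vocabulary
#' containing tokens never seen in the training pairs is rejected as leakage.
#'
#' @param pairs training [conditioned_pairs()].
#' @param val_pairs optional validation pairs (loss tracked per epoch).
#' @param config a [generator_config()].
#' @param vocab optional prebuilt [build_vocabulary()] result.
#' @return a fitted model, classed `gapfill_generator`, holding the learned
#'   parameters, vocabulary, config, conditioning setup, and per-epoch
#'   training/validation loss traces (mean per-token negative log-likelihood).
#' @export
train_generator <- function(pairs, val_pairs = NULL, config = generator_config(),
                            vocab = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(pairs) || nrow(pairs) == 0L) stop("training pair set is empty")
  if (config$architecture == "copy_baseline") {
    stop("the copy baseline has no parameters to train; use run_copy_baseline()")
  }
  if (is.null(vocab)) {
    vocab <- build_vocabulary(pairs)
  } else {
    train_toks <- unique(c(unlist(strsplit(pairs$input, " ", fixed = TRUE)),
                           unlist(strsplit(pairs$target, " ", fixed = TRUE))))
    specials <- c("<pad>", "<unk>", "<s>", "</s>")
    leaked <- setdiff(setdiff(names(vocab$index), specials), train_toks)
    if (length(leaked)) {
      stop("vocabulary leakage: tokens absent from the training pairs: ",
           paste(utils::head(leaked, 5), collapse = ", "))
    }
  }
  enc <- encode_pairs(pairs, vocab)
  vl <- if (!is.null(val_pairs) && nrow(val_pairs) > 0L) {
    encode_pairs(val_pairs, vocab)
  } else list(inputs = list(), targets = list())
  V <- length(vocab$index)
  params <- cpp_seq2seq_init(V, config$embedding_dim, config$max_input_len,
                             config$max_output_len, config$seed)
  fit <- cpp_seq2seq_train(params, enc$inputs, enc$targets, vl$inputs,
                           vl$targets, config$epochs, config$learning_rate,
                           config$seed)
  model <- list(
    params = fit$params, vocab = vocab, config = config,
    setup = attr(pairs, "setup"),
    train_loss = as.numeric(fit$train_loss),
    val_loss = as.numeric(fit$val_loss),
    format = GENERATOR_FORMAT
  )
  class(model) <- "gapfill_generator"
  model
}

# parameter-free model skeleton (uniform output distribution); used for
# closed-form perplexity checks and as an "untrained" reference
zero_generator <- function(vocab, config = generator_config()) {
  V <- length(vocab$index)
  params <- cpp_seq2seq_init(V, config$embedding_dim, config$max_input_len,
                             config$max_output_len, config$seed)
  for (nm in names(params)) params[[nm]][] <- 0
  model <- list(params = params, vocab = vocab, config = config,
                setup = NULL, train_loss = numeric(0), val_loss = numeric(0),
                format = GENERATOR_FORMAT)
  class(model) <- "gapfill_generator"
  model
}

#' @export
print.gapfill_generator <- function(x, ...) {
  cat(sprintf("<gapfill_generator> %s, %d-dim, vocab %d, setup %s\n",
              x$config$architecture, x$config$embedding_dim,
              length(x$vocab$index),
              if (is.null(x$setup)) "<none>" else x$setup))
  if (length(x$train_loss)) {
    cat(sprintf("  %d epochs; train NLL %.4f -> %.4f\n", length(x$train_loss),
                x$train_loss[1], x$train_loss[length(x$train_loss)]))
  }
  invisible(x)
}

#' @export
summary.gapfill_generator <- function(object, ...) {
  print(object)
  if (length(object$val_loss) && !all(is.na(object$val_loss))) {
    cat(sprintf("  validation NLL %.4f -> %.4f\n", object$val_loss[1],
                object$val_loss[length(object$val_loss)]))
  }
  invisible(object)
}

#' Generate sentences from conditioned inputs
#'
#' Greedy decoding is deterministic; beam search returns the highest-scoring
#' completed hypothesis. One output per pair, in pair order, so paragraph
#' reassembly preserves sentence order.
#'
#' @param model a trained `gapfill_generator`.
#' @param pairs [conditioned_pairs()] whose inputs to condition on.
#' @param beam_width overrides the config's decoding width (1 = greedy).
#' @return data frame classed `generation_output` with the pair keys, `output`
#'   (space-joined generated tokens) and `score` (mean token log-likelihood).
#' @export
generate_text <- function(model, pairs, beam_width = NULL) {
  stopifnot(inherits(model, "gapfill_generator"))
  if (is.null(model$params)) stop("model is untrained")
  if (is.null(beam_width)) {
    beam_width <- if (model$config$decoding == "beam") model$config$beam_width else 1L
  }
  enc <- encode_pairs(pairs, model$vocab)
  dec <- cpp_seq2seq_decode(model$params, enc$inputs,
                            model$config$max_output_len, as.integer(beam_width))
  out <- pairs[, c("document_id", "paragraph_index", "sentence_index")]
  out$output <- vapply(dec$tokens, function(ids) {
    detokenize(decode_tokens(ids, model$vocab))
  }, character(1))
  out$score <- as.numeric(dec$score)
  class(out) <- c("generation_output", "data.frame")
  out
}

#' Copy baseline: reproduce the key-phrase input verbatim
#'
#' The no-model baseline of the evaluation: its "generated" sentence is the
#' concatenation of the selected key phrases, with no context filled in.
#'
#' @param pairs [conditioned_pairs()] built with `setup = "key"`.
#' @return a `generation_output` frame (scores are `NA`: there is no model).
#' @export
run_copy_baseline <- function(pairs) {
  if (!identical(attr(pairs, "setup"), "key")) {
    stop("the copy baseline expects pairs built with setup = 'key'")
  }
  out <- pairs[, c("document_id", "paragraph_index", "sentence_index")]
  out$output <- pairs$input
  out$score <- NA_real_
  class(out) <- c("generation_output", "data.frame")
  out
}

#' Perplexity under forced decoding
#'
#' `exp` of the mean per-token negative log-likelihood of the target tokens
#' given the inputs, pooled over all pairs, including the end-of-sequence
#' symbol of each target.
#'
#' @param model a `gapfill_generator`.
#' @param pairs [conditioned_pairs()] with non-empty targets.
#' @return a single positive number (>= 1 for any proper model).
#' @export
perplexity <- function(model, pairs) {
  stopifnot(inherits(model, "gapfill_generator"))
  if (nrow(pairs) == 0L) stop("no targets to score")
  enc <- encode_pairs(pairs, model$vocab)
  lp <- cpp_seq2seq_logprob(model$params, enc$inputs, enc$targets)
  exp(-sum(lp$logprob) / sum(lp$n_tokens))
}

#' Save or load a generator checkpoint
#'
#' The checkpoint is a single archive holding parameters, vocabulary and
#' config under a versioned format tag; a reloaded model produces
#' token-identical greedy outputs.
#'
#' @param model a `gapfill_generator`.
#' @param path checkpoint path.
#' @export
save_generator <- function(model, path) {
  stopifnot(inherits(model, "gapfill_generator"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_generator
#' @export
load_generator <- function(path) {
  model <- readRDS(path)
  if (!identical(model$format, GENERATOR_FORMAT)) {
    stop("not a ", GENERATOR_FORMAT, " checkpoint: ", path)
  }
  class(model) <- "gapfill_generator"
  model
}

#' Reassemble a generated corpus aligned with its genuine source
#'
#' Replaces each sentence's text with the generated output matched on
#' (document, paragraph, sentence), keeping all metadata, so the result can be
#' fed to the intrinsic metrics and the extrinsic classifiers.
#'
#' @param corpus the genuine [ehr_corpus()] the pairs were built from.
#' @param output a `generation_output` frame.
#' @return an `ehr_corpus` with generated text.
#' @export
generated_corpus <- function(corpus, output) {
  key <- function(df) paste(df$document_id, df$paragraph_index, df$sentence_index)
  idx <- match(key(corpus), key(output))
  if (anyNA(idx)) {
    stop("no generated output for document ",
         corpus$document_id[which(is.na(idx))[1]])
  }
  corpus$text <- output$output[idx]
  corpus
}
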