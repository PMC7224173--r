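# Shared fixture builders.

# small corpus whose planted 2-grams are exactly the lower-quartile ones
# (the filler pool is duplicated, so every non-planted 2-gram repeats and the
# nearest-rank lower quartile lands on frequency 1)
audit_fixture <- function(seed) {
  synth_config(n_patients = 12L, docs_per_patient = 2L,
               sentences_per_doc = c(5L, 7L), vocab_size = 150L,
               n_planted_rare = 50L, reuse_templates = TRUE, seed = seed)
}

# hand-built conditioned pairs from raw space-joined strings
make_pairs <- function(inputs, targets, setup = "all") {
  p <- data.frame(
    document_id = "doc1", paragraph_index = 0L,
    sentence_index = seq_along(inputs) - 1L,
    input = inputs, target = targets, stringsAsFactors = FALSE
  )
  p$phrases <- lapply(strsplit(inputs, " ", fixed = TRUE), list)
  attr(p, "setup") <- setup
  class(p) <- c("conditioned_pairs", "data.frame")
  p
}

# vocabulary over explicit tokens (plus the four specials)
vocab_of <- function(tokens) {
  pairs <- make_pairs(rep("x y", 2), rep(paste(tokens, collapse = " "), 2))
  build_vocabulary(pairs, min_frequency = 2L)
}
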