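one_sentence_corpus <- function(text) {
  df <- data.frame(
    document_id = "d1", patient_id = "p1", paragraph_index = 0L,
    sentence_index = 0L, text = text, diagnosis_code = "F20",
    diagnosis_description = "x", gender = "male", age = 30L,
    death_flag = FALSE, relative_timestamp = 0L, section_label = "summary",
    sentence_ordinal = 1L, stringsAsFactors = FALSE
  )
  ehr_corpus(df)
}

test_that("n-gram index counts within sentences with nearest-rank quartiles", {
  idx <- build_ngram_index(one_sentence_corpus("a b a b"), 2L)
  expect_identical(idx[["2"]]$freq[["a b"]], 2L)
  expect_identical(idx[["2"]]$freq[["b a"]], 1L)
  # n-grams never cross sentence boundaries
  two <- one_sentence_corpus("a b c")
  two <- rbind(two, two)
  two$sentence_index <- 0:1
  two$sentence_ordinal <- 1:2
  class(two) <- c("ehr_corpus", "data.frame")
  idx2 <- build_ngram_index(two, 2L)
  expect_identical(sum(idx2[["2"]]$freq), 4L)
  expect_error(build_ngram_index(one_sentence_corpus("x")[0, ], 2L), "empty")
})

test_that("quartile thresholds are nearest-rank percentiles", {
  # distinct frequencies {1,1,2,3,5,8,13,21}: 25th -> rank 2 (1), 75th -> rank 6 (8)
  f <- c(1L, 1L, 2L, 3L, 5L, 8L, 13L, 21L)
  expect_identical(f[ceiling(0.25 * length(f))], 1L)
  idx <- list("2" = list(freq = stats::setNames(f, paste("g", 1:8)),
                         lower = f[ceiling(0.25 * 8)],
                         upper = f[ceiling(0.75 * 8)]))
  expect_identical(idx[["2"]]$lower, 1L)
  expect_identical(idx[["2"]]$upper, 8L)
  # and the index computes the same rule
  texts <- unlist(mapply(function(g, n) rep(g, n), paste0("w", 1:8, " v", 1:8),
                         f))
  corpus <- one_sentence_corpus("x y")
  corpus <- corpus[rep(1, length(texts)), ]
  corpus$text <- texts
  corpus$sentence_index <- seq_along(texts) - 1L
  corpus$sentence_ordinal <- seq_along(texts)
  class(corpus) <- c("ehr_corpus", "data.frame")
  got <- build_ngram_index(corpus, 2L)[["2"]]
  expect_identical(sort(as.integer(got$freq)), sort(f))
  expect_identical(got$lower, 1L)
  expect_identical(got$upper, 8L)
})

test_that("quartile sampling finds the planted sentences via the answer key", {
  syn <- generate_corpus(audit_fixture(7L))
  idx <- build_ngram_index(syn$corpus, c(2L, 3L))
  expect_identical(idx[["2"]]$lower, 1L)
  smp <- sample_sentences_by_quartile(syn$corpus, idx, 2L, "low", k = 50L,
                                      seed = 1L)
  ak <- syn$answer_key$planted
  expect_identical(attr(smp, "shortfall"), 0L)
  expect_setequal(paste(smp$document_id, smp$paragraph_index, smp$sentence_index),
                  paste(ak$document_id, ak$paragraph_index, ak$sentence_index))
  expect_setequal(smp$target, ak$ngram)
  expect_true(all(smp$target_freq == 1L))
  # determinism and shortfall flagging
  smp2 <- sample_sentences_by_quartile(syn$corpus, idx, 2L, "low", k = 50L,
                                       seed = 1L)
  expect_identical(smp, smp2)
  big <- sample_sentences_by_quartile(syn$corpus, idx, 2L, "low", k = 500L,
                                      seed = 1L)
  expect_identical(attr(big, "shortfall"), 500L - nrow(big))
  expect_error(sample_sentences_by_quartile(syn$corpus, idx, 4L, "low"),
               "not in the index")
  # low and high target sets are disjoint when the thresholds differ
  hi <- sample_sentences_by_quartile(syn$corpus, idx, 2L, "high", k = 50L,
                                     seed = 1L)
  expect_length(intersect(hi$target, smp$target), 0L)
})

test_that("copy baseline audits to pct_out == pct_in for every cell", {
  syn <- generate_corpus(audit_fixture(8L))
  idx <- build_ngram_index(syn$corpus, c(2L, 3L))
  for (n in c(2L, 3L)) {
    for (q in c("low", "high")) {
      smp <- sample_sentences_by_quartile(syn$corpus, idx, n, q, k = 30L,
                                          seed = 2L)
      row <- audit_memorisation("copy_baseline", syn$corpus, smp)
      expect_identical(row$pct_out, row$pct_in)
      expect_identical(row$beyond_input_rate, 0)
    }
  }
})

test_that("composition of leaked n-grams is a token-level tally", {
  sw <- load_stopwords()
  comp <- composition_of_leaks("the press", sw)
  expect_equal(unname(comp["stopword"]), 0.5)
  expect_equal(unname(comp["other"]), 0.5)
  comp2 <- composition_of_leaks("12 .", sw)
  expect_equal(unname(comp2["numeric"]), 0.5)
  expect_equal(unname(comp2["punctuation"]), 0.5)
  expect_equal(unname(composition_of_leaks(character(0), sw)),
               c(0, 0, 0, 0))
  expect_equal(sum(composition_of_leaks(c("the 12", "press ."), sw)), 1)
})

test_that("audit rejects a setup mismatch with the trained model", {
  syn <- generate_corpus(audit_fixture(9L))
  idx <- build_ngram_index(syn$corpus, 2L)
  smp <- sample_sentences_by_quartile(syn$corpus, idx, 2L, "low", k = 10L,
                                      seed = 3L)
  pairs <- conditioned_pairs(syn$corpus, "one_meta")
  model <- train_generator(pairs[1:30, ],
                           config = generator_config(epochs = 1L))
  expect_error(audit_memorisation(model, syn$corpus, smp, setup = "top_meta"),
               "setup mismatch")
})
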