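test_that("tokenisation lowercases, detaches punctuation, and is idempotent", {
  expect_identical(tokenize("He has no allergies."),
                   c("he", "has", "no", "allergies", "."))
  expect_identical(tokenize("F20, schizophrenia"),
                   c("f20", ",", "schizophrenia"))
  expect_identical(tokenize(""), character(0))
  expect_identical(tokenize("   "), character(0))
  # property: re-tokenising the space-joined tokens is the identity
  set.seed(42)
  pieces <- c("He", "was", "re-admitted", "on", "12/03,", "(today)", "F20.",
              "mood...", "ok")
  for (i in 1:50) {
    s <- paste(sample(pieces, sample(1:8, 1), replace = TRUE), collapse = " ")
    toks <- tokenize(s)
    expect_identical(tokenize(detokenize(toks)), toks)
  }
})

test_that("corpus exchange format round-trips exactly", {
  syn <- generate_corpus(synth_config(n_patients = 10L, seed = 2L))
  path <- tempfile(fileext = ".tsv")
  write_corpus(syn$corpus, path)
  back <- read_corpus(path)
  expect_identical(as.data.frame(syn$corpus), as.data.frame(back))
  # file is grouped by document in input order
  lines <- readLines(path)
  ids <- vapply(strsplit(lines[-1], "\t"), `[[`, character(1), 1L)
  expect_identical(ids, syn$corpus$document_id)
})

test_that("degenerate corpora survive the round trip", {
  df <- data.frame(
    document_id = "d1", patient_id = "p1", paragraph_index = 0L,
    sentence_index = 0L, text = "", diagnosis_code = "F20",
    diagnosis_description = "schizophrenia", gender = "female", age = 34L,
    death_flag = FALSE, relative_timestamp = -3L, section_label = "summary",
    sentence_ordinal = 1L, stringsAsFactors = FALSE
  )
  corpus <- ehr_corpus(df)
  path <- tempfile(fileext = ".tsv")
  write_corpus(corpus, path)
  expect_identical(as.data.frame(read_corpus(path)), as.data.frame(corpus))
  # empty corpus
  empty <- corpus[0, ]
  class(empty) <- c("ehr_corpus", "data.frame")
  write_corpus(empty, path)
  expect_identical(nrow(read_corpus(path)), 0L)
})

test_that("malformed records are rejected with the line number or value", {
  syn <- generate_corpus(synth_config(n_patients = 5L, seed = 3L))
  path <- tempfile(fileext = ".tsv")
  write_corpus(syn$corpus, path)
  lines <- readLines(path)
  bad <- lines
  bad[3] <- paste(bad[3], "extra", sep = "\t")
  writeLines(bad, path)
  expect_error(read_corpus(path), "line 3")
  bad <- lines
  bad[5] <- sub("\tsummary\t", "\tward_round\t", bad[5])
  writeLines(bad, path)
  expect_error(read_corpus(path), "ward_round")
  bad <- lines
  f <- strsplit(bad[4], "\t")[[1]]
  f[9] <- "forty"  # age
  bad[4] <- paste(f, collapse = "\t")
  writeLines(bad, path)
  expect_error(read_corpus(path), "line 4")
  expect_error(read_corpus(tempfile()), "no such corpus file")
})

test_that("patient split respects fractions, determinism and disjointness", {
  syn <- generate_corpus(synth_config(n_patients = 10L, docs_per_patient = 1L,
                                      seed = 4L))
  sp <- split_by_patient(syn$corpus, c(0.8, 0.1, 0.1), seed = 7L)
  counts <- vapply(sp, function(x) length(unique(x$patient_id)), integer(1))
  expect_identical(unname(counts), c(8L, 1L, 1L))
  sp2 <- split_by_patient(syn$corpus, c(0.8, 0.1, 0.1), seed = 7L)
  expect_identical(lapply(sp, as.data.frame), lapply(sp2, as.data.frame))
  expect_error(split_by_patient(syn$corpus, c(0.5, 0.5, 0.1)), "summing to 1")
  two <- syn$corpus[syn$corpus$patient_id %in% unique(syn$corpus$patient_id)[1:2], ]
  class(two) <- c("ehr_corpus", "data.frame")
  expect_error(split_by_patient(two, c(0.8, 0.1, 0.1)), "at least 3")
})

test_that("patient disjointness holds for any seed (exhaustive scan)", {
  syn <- generate_corpus(synth_config(n_patients = 100L, docs_per_patient = 1L,
                                      sentences_per_doc = c(2L, 3L),
                                      n_planted_rare = 10L, seed = 5L))
  for (seed in c(1L, 2L, 99L)) {
    sp <- split_by_patient(syn$corpus, c(0.9, 0.05, 0.05), seed)
    pats <- lapply(sp, function(x) unique(x$patient_id))
    expect_length(intersect(pats$train, pats$validation), 0L)
    expect_length(intersect(pats$train, pats$test), 0L)
    expect_length(intersect(pats$validation, pats$test), 0L)
    expect_identical(sort(unname(unlist(pats))), sort(unique(syn$corpus$patient_id)))
  }
})

test_that("corpus statistics are exact counts", {
  df <- data.frame(
    document_id = "d1", patient_id = "p1", paragraph_index = 0L,
    sentence_index = 0:1, text = c("a b c d e", "f g h i j"),
    diagnosis_code = "F20", diagnosis_description = "x", gender = "male",
    age = 30L, death_flag = FALSE, relative_timestamp = 0L,
    section_label = "summary", sentence_ordinal = 1:2,
    stringsAsFactors = FALSE
  )
  st <- corpus_statistics(ehr_corpus(df))
  expect_identical(st$n_tokens, 10L)
  expect_identical(st$n_sentences, 2L)
  expect_equal(st$mean_sentence_length, 5)
  spectrum <- st$frequency_spectrum
  expect_true(all(diff(unname(spectrum)) <= 0))
  empty <- df[0, ]
  expect_error(corpus_statistics(ehr_corpus(empty)), "empty")
})
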