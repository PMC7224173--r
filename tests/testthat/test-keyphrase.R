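sw <- load_stopwords()

test_that("RAKE scores follow the deg/freq rule on worked examples", {
  p <- list(tokenize("patient reports low mood and poor sleep"))
  kp <- rake_extract(p, c("reports", "and"))
  expect_identical(kp$phrase, c("patient", "low mood", "poor sleep"))
  expect_equal(kp$score, c(1, 4, 4))
  # paragraph of pure stopwords
  expect_identical(nrow(rake_extract(list(c("and", "the")), c("and", "the"))), 0L)
  # duplicated candidate doubles freq and deg
  p2 <- list(tokenize("low mood and low mood"))
  kp2 <- rake_extract(p2, "and")
  expect_identical(kp2$phrase, c("low mood", "low mood"))
  expect_equal(kp2$score, c(4, 4))  # word score 4/2 = 2 each, phrase 4
})

test_that("RAKE equals an independent brute-force implementation", {
  set.seed(31)
  content <- c("mood", "sleep", "risk", "dose", "team", "clinic", "harm")
  stops <- c("the", "and", "was", "of", "he")
  for (rep in 1:40) {
    par <- lapply(seq_len(sample(1:3, 1)), function(i) {
      sample(c(content, stops, "."), sample(4:12, 1), replace = TRUE)
    })
    kp <- rake_extract(par, stops)
    want <- oracle_rake(par, stops)
    expect_identical(nrow(kp), length(want))
    if (nrow(kp)) {
      # same multiset of (phrase, score)
      got <- kp$score[order(kp$phrase, kp$score)]
      ref <- unname(want[order(names(want), want)])
      expect_equal(got, ref)
    }
  }
})

test_that("phrase selection honours setup semantics and tie-breaks", {
  p <- list(tokenize("severe chest pain and mild cough today and fever"))
  kp <- rake_extract(p, c("and", "today"))
  expect_identical(select_phrases(kp, "all"), kp)
  one <- select_phrases(kp, "one_meta")
  expect_identical(nrow(one), 1L)
  expect_identical(one$phrase, "severe chest pain")
  # argmax per sentence over five phrases
  kp5 <- rake_extract(list(tokenize("a1 x b2 x c3 x d4 x e5"),
                           tokenize("f6 x g7")), "x")
  one5 <- select_phrases(kp5, "one_meta")
  expect_identical(nrow(one5), 2L)  # one per sentence
  # quantile keeping the top scores, positional order on ties
  kp3 <- data.frame(phrase = c("p1", "p2", "p3"), score = c(4, 4, 1),
                    sentence_index = c(0L, 0L, 0L), start = c(1L, 4L, 7L))
  class(kp3) <- c("keyphrases", "data.frame")
  top <- select_phrases(kp3, "top_meta", keep_fraction = 2 / 3)
  expect_identical(top$phrase, c("p1", "p2"))
  expect_error(select_phrases(kp3, "two_meta"))
})

test_that("phrase-token counts are monotone one_meta <= top_meta <= all", {
  syn <- generate_corpus(synth_config(n_patients = 8L, seed = 16L))
  counts <- lapply(c("one_meta", "top_meta", "all"), function(s) {
    p <- conditioned_pairs(syn$corpus, s, sw)
    vapply(p$phrases, function(runs) length(unlist(runs)), integer(1))
  })
  expect_true(all(counts[[1]] <= counts[[2]]))
  expect_true(all(counts[[2]] <= counts[[3]]))
})

test_that("class markers are extracted on full-signal fixtures", {
  syn <- generate_corpus(synth_config(n_patients = 6L, n_classes = 3L,
                                      class_signal_strength = 1, seed = 17L))
  markers <- vapply(syn$answer_key$markers, paste, character(1), collapse = " ")
  pairs <- conditioned_pairs(syn$corpus, "all", sw)
  phrases <- unique(unlist(lapply(pairs$phrases, function(r) {
    vapply(r, paste, character(1), collapse = " ")
  })))
  expect_true(all(markers %in% phrases))
})

test_that("conditioned pairs carry the metadata block and are deterministic", {
  df <- data.frame(
    document_id = "d1", patient_id = "p1", paragraph_index = 0L,
    sentence_index = 0:1,
    text = c("she has severe allergies today .", "and was but of ."),
    diagnosis_code = "F20", diagnosis_description = "schizophrenia",
    gender = "female", age = 23L, death_flag = FALSE,
    relative_timestamp = 2L, section_label = "summary",
    sentence_ordinal = 1:2, stringsAsFactors = FALSE
  )
  corpus <- ehr_corpus(df)
  tm <- conditioned_pairs(corpus, "top_meta", sw)
  expect_identical(tokenize(tm$input[1])[1:7],
                   c("f20", "female", "age_20s", "death_no", "ts_week1",
                     "sec_summary", "ord_1"))
  expect_match(tm$input[1], "severe allergies$")
  # sentence with no extracted phrase: metadata block only
  expect_identical(tokenize(tm$input[2]),
                   c("f20", "female", "age_20s", "death_no", "ts_week1",
                     "sec_summary", "ord_2"))
  # all-setup input has no metadata block
  al <- conditioned_pairs(corpus, "all", sw)
  expect_identical(al$input[1], "severe allergies")
  # key setup: target is the concatenated phrases themselves
  ky <- conditioned_pairs(corpus, "key", sw)
  expect_identical(ky$target[1], "severe allergies")
  expect_identical(ky$target[2], "")
  # determinism
  expect_identical(conditioned_pairs(corpus, "top_meta", sw), tm)
})

test_that("vocabulary prunes singletons and orders deterministically", {
  pairs <- make_pairs(c("a b", "a b"), c("a a a b b zzq", "c c"))
  v <- build_vocabulary(pairs, min_frequency = 2L)
  expect_false("zzq" %in% names(v$index))
  expect_identical(synthnotes:::encode_tokens("zzq", v), v$unk)
  expect_identical(names(v$index)[1:4], c("<pad>", "<unk>", "<s>", "</s>"))
  # counts a:5, b:5 (x2 via inputs), c:2 -> a before b lexicographically
  nm <- names(v$index)[-(1:4)]
  expect_identical(nm[order(match(nm, nm))][1:2], c("a", "b"))
  expect_true(which(names(v$index) == "a") < which(names(v$index) == "b"))
  expect_error(build_vocabulary(pairs[0, ]), "zero pairs")
  expect_error(build_vocabulary(pairs, min_frequency = 1L), ">= 2")
  # full coverage when everything repeats
  pairs2 <- make_pairs(c("a b", "a b"), c("c d", "c d"))
  v2 <- build_vocabulary(pairs2)
  expect_identical(sort(setdiff(names(v2$index), c("<pad>", "<unk>", "<s>", "</s>"))),
                   c("a", "b", "c", "d"))
})

test_that("stripping key phrases deletes runs and drops emptied sentences", {
  mk <- function(texts) {
    df <- data.frame(
      document_id = "d1", patient_id = "p1", paragraph_index = 0L,
      sentence_index = seq_along(texts) - 1L, text = texts,
      diagnosis_code = "F20", diagnosis_description = "x", gender = "male",
      age = 40L, death_flag = FALSE, relative_timestamp = 0L,
      section_label = "summary", sentence_ordinal = seq_along(texts),
      stringsAsFactors = FALSE
    )
    ehr_corpus(df)
  }
  genuine <- mk(c("he has low mood today", "low mood", "stable on review"))
  artificial <- mk(c("low mood today", "low mood low mood", "stable"))
  out <- strip_common_keyphrases(genuine, artificial, "low mood")
  expect_identical(out$genuine$text, c("he has today", "stable on review"))
  expect_identical(out$artificial$text, c("today", "stable"))
})
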