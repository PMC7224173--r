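# two disjoint fixtures: a training corpus and a patient-disjoint test corpus
# carved from one separable fixture (class signal 1)
separable_split <- function(seed = 23L, n_classes = 3L) {
  syn <- generate_corpus(synth_config(
    n_patients = 24L, docs_per_patient = 1L, sentences_per_doc = c(4L, 6L),
    n_classes = n_classes, class_signal_strength = 1, n_planted_rare = 0L,
    seed = seed))
  sp <- split_by_patient(syn$corpus, c(0.7, 0, 0.3), seed = seed)
  list(train = labelled_documents(sp$train),
       test = labelled_documents(sp$test),
       train_corpus = sp$train, corpus = syn$corpus)
}

test_that("bag-of-n-grams features enumerate within-sentence n-grams", {
  docs <- data.frame(document_id = "d1", patient_id = "p1", label = "F20",
                     stringsAsFactors = FALSE)
  docs$sentences <- list(list(c("a", "b")))
  class(docs) <- c("labelled_docs", "data.frame")
  f <- featurize_bow(docs, max_n = 2L, min_df = 1L)
  expect_setequal(f$features, c("a", "b", "a b"))
  expect_true(all(f$matrix == 1L))
  # identical documents give identical rows
  docs2 <- rbind(docs, docs)
  docs2$document_id <- c("d1", "d2")
  docs2$sentences <- list(list(c("a", "b")), list(c("a", "b")))
  class(docs2) <- c("labelled_docs", "data.frame")
  f2 <- featurize_bow(docs2, max_n = 2L, min_df = 1L)
  expect_identical(f2$matrix[1, ], f2$matrix[2, ])
  expect_error(featurize_bow(docs[0, ]), "no documents")
})

test_that("bow feature count equals a brute-force n-gram enumeration", {
  fx <- separable_split(29L)
  f <- featurize_bow(fx$train, max_n = 3L, min_df = 1L)
  want <- unique(unlist(lapply(fx$train$sentences, function(sents) {
    unlist(lapply(sents, function(toks) {
      out <- character(0)
      for (n in 1:3) {
        if (length(toks) >= n) {
          for (i in seq_len(length(toks) - n + 1L)) {
            out <- c(out, paste(toks[i:(i + n - 1L)], collapse = " "))
          }
        }
      }
      out
    }))
  })))
  expect_identical(length(f$features), length(want))
  expect_setequal(f$features, want)
})

test_that("LDA topic proportions are simplex rows, reproducible by seed", {
  fx <- separable_split(31L)
  model <- lda_fit(fx$train_corpus, n_topics = 3L, seed = 5L, iters = 60L)
  th <- featurize_lda(model, fx$test, seed = 9L)
  expect_true(all(abs(rowSums(th) - 1) < 1e-6))
  th2 <- featurize_lda(model, fx$test, seed = 9L)
  expect_identical(th, th2)
  model2 <- lda_fit(fx$train_corpus, n_topics = 3L, seed = 5L, iters = 60L)
  expect_identical(model$phi, model2$phi)
  expect_error(lda_fit(fx$train_corpus, n_topics = 1L), ">= 2")
  # marker vocabularies separate: same-class topic vectors more similar
  th_tr <- featurize_lda(model, fx$train, seed = 9L)
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  same <- c(); cross <- c()
  for (i in seq_len(nrow(fx$train) - 1L)) {
    for (j in (i + 1L):nrow(fx$train)) {
      cs <- cosine(th_tr[i, ], th_tr[j, ])
      if (fx$train$label[i] == fx$train$label[j]) same <- c(same, cs)
      else cross <- c(cross, cs)
    }
  }
  expect_gt(mean(same), mean(cross))
})

test_that("F1 matches the hand formula and degenerate cases", {
  truth <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  pred <- c(TRUE, FALSE, TRUE, FALSE, TRUE)
  p <- 2 / 3
  r <- 2 / 3
  expect_equal(f1_score(truth, pred), 2 * p * r / (p + r))
  expect_equal(f1_score(truth, rep(FALSE, 5)), 0)
  expect_equal(f1_score(truth, truth), 1)
})

test_that("all three classifier families are perfect on a separable fixture", {
  fx <- separable_split(37L)
  classes <- sort(unique(fx$test$label))
  # bow + RF
  tr <- featurize_bow(fx$train)
  fit <- train_classifier(tr$matrix, fx$train$label, classes, "bow", seed = 1L)
  prob <- predict(fit, featurize_bow(fx$test, features = tr$features)$matrix)
  for (cl in classes) {
    expect_equal(f1_score(fx$test$label == cl, prob[, cl] >= 0.5), 1)
  }
  # lda + RF
  lm <- lda_fit(fx$train_corpus, n_topics = 3L, seed = 2L, iters = 80L)
  xtr <- featurize_lda(lm, fx$train, seed = 3L)
  xte <- featurize_lda(lm, fx$test, seed = 4L)
  fit2 <- train_classifier(xtr, fx$train$label, classes, "lda", seed = 1L)
  prob2 <- predict(fit2, xte)
  for (cl in classes) {
    expect_equal(f1_score(fx$test$label == cl, prob2[, cl] >= 0.5), 1)
  }
  # cnn
  cnn_encode <- synthnotes:::cnn_encode
  xtr3 <- cnn_encode(fx$train)
  xte3 <- cnn_encode(fx$test, words = attr(xtr3, "words"))
  fit3 <- train_classifier(xtr3, fx$train$label, classes, "cnn",
                           config = list(epochs = 25L), seed = 1L)
  prob3 <- predict(fit3, xte3)
  for (cl in classes) {
    expect_equal(f1_score(fx$test$label == cl, prob3[, cl] >= 0.5), 1)
  }
  # determinism of refits
  fit3b <- train_classifier(xtr3, fx$train$label, classes, "cnn",
                            config = list(epochs = 25L), seed = 1L)
  expect_identical(predict(fit3b, xte3), prob3)
})

test_that("shuffled labels collapse mean F1 towards the base rate", {
  fx <- separable_split(41L)
  classes <- sort(unique(fx$test$label))
  tr <- featurize_bow(fx$train)
  xte <- featurize_bow(fx$test, features = tr$features)$matrix
  f1s <- c()
  set.seed(11)
  for (s in 1:5) {
    yshuf <- sample(fx$train$label)
    fit <- train_classifier(tr$matrix, yshuf, classes, "bow", seed = s)
    prob <- predict(fit, xte)
    f1s <- c(f1s, vapply(classes, function(cl) {
      f1_score(fx$test$label == cl, prob[, cl] >= 0.5)
    }, numeric(1)))
  }
  expect_lt(mean(f1s), 0.55)  # far below the separable 1.0
})

test_that("a class with no positive training example is flagged and skipped", {
  fx <- separable_split(43L)
  keep <- fx$train$label != "F60"
  sub <- fx$train[keep, ]
  class(sub) <- class(fx$train)
  tr <- featurize_bow(sub)
  fit <- train_classifier(tr$matrix, sub$label, c("F20", "F32", "F60"),
                          "bow", seed = 1L)
  expect_identical(fit$skipped, "F60")
  prob <- predict(fit, tr$matrix)
  expect_true(all(is.na(prob[, "F60"])))
})

test_that("KS comparison equals brute force, is symmetric, matches ks.test", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(ks_two_sample(c(0, 0, 0), c(1, 1, 1))$statistic, 1)
  set.seed(13)
  for (i in 1:20) {
    a <- round(runif(sample(5:40, 1)), 2)  # rounded -> ties likely
    b <- round(runif(sample(5:40, 1)), 2)
    ks <- ks_two_sample(a, b)
    expect_equal(ks$statistic, oracle_ks_d(a, b))
    ks_rev <- ks_two_sample(b, a)
    expect_equal(ks$statistic, ks_rev$statistic)
    expect_equal(ks$p_value, ks_rev$p_value)
  }
  # tie-free samples: D agrees with stats::ks.test
  a <- rnorm(25)
  b <- rnorm(30, 0.5)
  expect_equal(ks_two_sample(a, b)$statistic,
               unname(stats::ks.test(a, b)$statistic))
  expect_error(ks_two_sample(numeric(0), 1), "empty")
})

test_that("protocol sample sizes follow the printed construction", {
  # 6 classes x 5 runs with CV folds -> 30 points per (regime, classifier)
  syn <- generate_corpus(synth_config(
    n_patients = 30L, docs_per_patient = 1L, sentences_per_doc = c(3L, 4L),
    n_classes = 6L, class_signal_strength = 1, n_planted_rare = 0L,
    seed = 47L))
  docs <- labelled_documents(syn$corpus)
  res <- run_protocol(list(genuine = docs), docs, classifiers = "bow",
                      n_runs = 5L, cv_folds = 3L, seed = 1L,
                      config = list(bow = list(max_n = 1L)))
  expect_identical(nrow(res$samples), 30L)
  # 13 classes x 5 runs, fixed test set -> 65 points
  syn13 <- generate_corpus(synth_config(
    n_patients = 39L, docs_per_patient = 1L, sentences_per_doc = c(3L, 4L),
    n_classes = 13L, class_signal_strength = 1, n_planted_rare = 0L,
    seed = 49L))
  sp <- split_by_patient(syn13$corpus, c(0.7, 0, 0.3), seed = 3L)
  all_classes <- sort(unique(syn13$corpus$diagnosis_code))
  res13 <- run_protocol(list(genuine = labelled_documents(sp$train)),
                        labelled_documents(sp$test), classifiers = "bow",
                        n_runs = 5L, seed = 1L, classes = all_classes,
                        config = list(bow = list(max_n = 1L)))
  expect_identical(nrow(res13$samples), 65L)
  # identical regimes and seeds give identical samples (KS D = 0)
  res_b <- run_protocol(list(genuine = labelled_documents(sp$train)),
                        labelled_documents(sp$test), classifiers = "bow",
                        n_runs = 5L, seed = 1L, classes = all_classes,
                        config = list(bow = list(max_n = 1L)))
  expect_identical(res13$samples$f1, res_b$samples$f1)
  expect_equal(ks_two_sample(res13$samples$f1, res_b$samples$f1)$statistic, 0)
})

test_that("patient overlap between training regime and test set is an error", {
  fx <- separable_split(53L)
  expect_error(run_protocol(list(genuine = fx$train), fx$train,
                            classifiers = "bow", n_runs = 1L, seed = 1L),
               "patient overlap")
})

test_that("error analysis counts high-confidence mistakes and their overlap", {
  pred_a <- data.frame(
    document_id = c("d1", "d2", "d3", "d4"), class = "F20",
    truth = c(TRUE, FALSE, FALSE, TRUE),
    pred = c(FALSE, TRUE, FALSE, TRUE),
    confidence = c(0.95, 0.99, 0.80, 0.97), stringsAsFactors = FALSE
  )
  pred_b <- pred_a
  pred_b$pred <- c(FALSE, FALSE, FALSE, TRUE)  # only the FN remains
  ea <- error_analysis(list(genuine = pred_a, artificial = pred_b), 0.9)
  expect_identical(ea$counts$fp, c(1, 0))
  expect_identical(ea$counts$fn, c(1, 1))
  expect_equal(ea$overlap, 0.5)  # d1 FN shared; d2 FP not
  # perfect predictions: nothing to count
  perfect <- pred_a
  perfect$pred <- perfect$truth
  ea2 <- error_analysis(list(a = perfect, b = perfect), 0.9)
  expect_identical(sum(ea2$counts$fp, ea2$counts$fn), 0)
  # identical prediction vectors overlap fully
  ea3 <- error_analysis(list(a = pred_a, b = pred_a), 0.9)
  expect_equal(ea3$overlap, 1)
  expect_error(error_analysis(list(a = pred_a, b = pred_b), 0.5), "threshold")
  expect_error(error_analysis(list(a = pred_a, b = pred_b), 1.1), "threshold")
})
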