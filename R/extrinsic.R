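# Extrinsic utility evaluation: train BoW+RF, LDA+RF and CNN classifiers on
# genuine versus artificial data, test on genuine data, and compare per-class
# F1 distributions with the two-sample Kolmogorov-Smirnov test.

#' Labelled documents for classification
#'
#' Collapses a sentence-level corpus to one row per document with its
#' diagnosis-code label and patient id; token sequences keep sentence
#' boundaries (a list of token vectors per document) since bag-of-words
#' n-grams never cross sentences.
#'
#' @param corpus an [ehr_corpus()].
#' @return data frame classed `labelled_docs` with `document_id`,
#'   `patient_id`, `label` and list column `sentences`.
#' @export
labelled_documents <- function(corpus) {
  docs <- corpus_documents(corpus)
  out <- data.frame(
    document_id = vapply(docs, function(d) d$document_id[1], character(1)),
    patient_id = vapply(docs, function(d) d$patient_id[1], character(1)),
    label = vapply(docs, function(d) d$diagnosis_code[1], character(1)),
    stringsAsFactors = FALSE
  )
  out$sentences <- lapply(docs, function(d) lapply(d$text, tokenize_one))
  rownames(out) <- NULL
  class(out) <- c("labelled_docs", "data.frame")
  out
}

#' Bag-of-n-grams features
#'
#' Counts all within-sentence n-grams for `n = 1..max_n` kept in at least
#' `min_df` training documents, with deterministic (lexicographic) feature
#' ordering. Passing an existing feature vector projects new documents onto
#' it (the test-set path).
#'
#' @param docs a `labelled_docs` frame.
#' @param max_n largest n-gram order (default 5).
#' @param min_df minimum document frequency for a feature (default 2).
#' @param features optional feature vector from a previous call.
#' @return list with `matrix` (documents x features) and `features`.
#' @export
featurize_bow <- function(docs, max_n = 5L, min_df = 2L, features = NULL) {
  if (nrow(docs) == 0L) stop("no documents to featurise")
  gram_tables <- lapply(docs$sentences, function(sents) {
    grams <- unlist(lapply(sents, function(toks) {
      unlist(lapply(seq_len(max_n), function(n) sent_ngrams(toks, n)))
    }))
    if (is.null(grams)) grams <- character(0)
    table(grams)
  })
  if (is.null(features)) {
    df_count <- table(unlist(lapply(gram_tables, names)))
    features <- sort(names(df_count[df_count >= min_df]))
  }
  m <- matrix(0L, nrow(docs), length(features),
              dimnames = list(docs$document_id, NULL))
  for (i in seq_len(nrow(docs))) {
    tt <- gram_tables[[i]]
    hit <- names(tt)[names(tt) %in% features]
    m[i, match(hit, features)] <- as.integer(tt[hit])
  }
  list(matrix = m, features = features)
}

#' Fit an LDA topic model on a reference corpus
#'
#' The topic model is fitted (collapsed Gibbs) on the generation-training
#' corpus, not on the classification training set; classification documents
#' are folded in against the fixed topic-word distribution.
#'
#' @param reference_corpus the [ehr_corpus()] the topics are learned from.
#' @param n_topics number of topics (>= 2).
#' @param seed sampling seed.
#' @param iters Gibbs sweeps.
#' @param alpha,beta Dirichlet hyperparameters.
#' @return list classed `lda_model` with `phi`, the word index and settings.
#' @export
lda_fit <- function(reference_corpus, n_topics = 150L, seed = 1L, iters = 150L,
                    alpha = 0.1, beta = 0.1) {
  if (n_topics < 2L) stop("n_topics must be >= 2")
  docs <- corpus_documents(reference_corpus)
  token_lists <- lapply(docs, function(d) unlist(lapply(d$text, tokenize_one)))
  words <- sort(unique(unlist(token_lists)))
  enc <- lapply(token_lists, function(t) match(t, words))
  fit <- cpp_lda_fit(enc, length(words), as.integer(n_topics), alpha, beta,
                     as.integer(iters), as.integer(seed))
  out <- list(phi = fit$phi, words = words, n_topics = as.integer(n_topics),
              alpha = alpha, seed = as.integer(seed), iters = as.integer(iters))
  class(out) <- "lda_model"
  out
}

#' Topic-proportion features for labelled documents
#'
#' @param model an [lda_fit()] result.
#' @param docs a `labelled_docs` frame.
#' @param seed fold-in seed.
#' @return matrix (documents x topics); each row sums to 1.
#' @export
featurize_lda <- function(model, docs, seed = 1L) {
  stopifnot(inherits(model, "lda_model"))
  enc <- lapply(docs$sentences, function(sents) {
    idx <- match(unlist(sents), model$words)
    idx <- idx[!is.na(idx)]
    if (!length(idx)) 1L else idx  # degenerate all-unknown doc
  })
  theta <- cpp_lda_infer(enc, model$phi, model$alpha, model$iters %/% 2L,
                         as.integer(seed))
  rownames(theta) <- docs$document_id
  theta
}

#' Per-class F1 score
#'
#' `2PR/(P+R)` from the confusion counts; 0 when there are no true positives.
#'
#' @param truth,pred logical (or 0/1) vectors.
#' @return a number in `[0, 1]`.
#' @export
f1_score <- function(truth, pred) {
  truth <- as.logical(truth)
  pred <- as.logical(pred)
  tp <- sum(truth & pred)
  if (tp == 0L) return(0)
  p <- tp / sum(pred)
  r <- tp / sum(truth)
  2 * p * r / (p + r)
}

# ---- convolutional sentence classifier (width-{3,4,5} filters, max-over-time
# pooling, logistic output), trained with per-example Adam ----------------

cnn_defaults <- function() {
  list(embedding_dim = 16L, widths = c(3L, 4L, 5L), n_filters = 16L,
       epochs = 30L, learning_rate = 0.02, dropout = 0.5)
}

cnn_init <- function(V, cfg) {
  d <- cfg$embedding_dim
  p <- list(E = matrix(stats::rnorm(V * d, 0, 0.08), V, d))
  p$W <- lapply(cfg$widths, function(w) {
    matrix(stats::rnorm(cfg$n_filters * w * d, 0, 0.08), cfg$n_filters, w * d)
  })
  p$b <- lapply(cfg$widths, function(w) numeric(cfg$n_filters))
  p$wout <- stats::rnorm(cfg$n_filters * length(cfg$widths), 0, 0.08)
  p$bout <- 0
  p
}

cnn_forward <- function(p, cfg, seq) {
  wmax <- max(cfg$widths)
  if (length(seq) < wmax) seq <- c(seq, rep(1L, wmax - length(seq)))
  X <- p$E[seq, , drop = FALSE]
  d <- cfg$embedding_dim
  cache <- list(seq = seq, X = X, per_w = vector("list", length(cfg$widths)))
  f <- numeric(0)
  for (wi in seq_along(cfg$widths)) {
    w <- cfg$widths[wi]
    nw <- length(seq) - w + 1L
    M <- do.call(cbind, lapply(0:(w - 1L), function(o) {
      X[(1L + o):(nw + o), , drop = FALSE]
    }))
    A <- pmax(M %*% t(p$W[[wi]]) + rep(p$b[[wi]], each = nw), 0)
    amax <- apply(A, 2L, which.max)
    fmax <- A[cbind(amax, seq_len(ncol(A)))]
    cache$per_w[[wi]] <- list(M = M, amax = amax, fmax = fmax, nw = nw)
    f <- c(f, fmax)
  }
  cache$f <- f
  cache
}

cnn_fit <- function(seqs, y, V, cfg = cnn_defaults(), seed = 1L) {
  with_seed(seed, {
    p <- cnn_init(V, cfg)
    adam_m <- rapply(p, function(x) x * 0, how = "replace")
    adam_v <- adam_m
    t_step <- 0
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(length(seqs))
      for (i in ord) {
        cache <- cnn_forward(p, cfg, seqs[[i]])
        mask <- stats::runif(length(cache$f)) >= cfg$dropout
        fd <- cache$f * mask / (1 - cfg$dropout)
        logit <- sum(p$wout * fd) + p$bout
        prob <- 1 / (1 + exp(-logit))
        dlogit <- prob - y[i]
        g <- list(E = matrix(0, nrow(p$E), ncol(p$E)),
                  W = lapply(p$W, function(W) W * 0),
                  b = lapply(p$b, function(b) b * 0),
                  wout = dlogit * fd, bout = dlogit)
        df <- dlogit * p$wout * mask / (1 - cfg$dropout)
        dX <- cache$X * 0
        off <- 0L
        d <- cfg$embedding_dim
        for (wi in seq_along(cfg$widths)) {
          w <- cfg$widths[wi]
          pw <- cache$per_w[[wi]]
          dfw <- df[(off + 1L):(off + cfg$n_filters)]
          off <- off + cfg$n_filters
          active <- pw$fmax > 0
          if (any(active & dfw != 0)) {
            dA <- matrix(0, pw$nw, cfg$n_filters)
            sel <- which(active & dfw != 0)
            dA[cbind(pw$amax[sel], sel)] <- dfw[sel]
            g$W[[wi]] <- t(dA) %*% pw$M
            g$b[[wi]] <- colSums(dA)
            dM <- dA %*% p$W[[wi]]
            for (o in 0:(w - 1L)) {
              rows <- (1L + o):(pw$nw + o)
              dX[rows, ] <- dX[rows, ] + dM[, (o * d + 1L):((o + 1L) * d)]
            }
          }
        }
        agg <- rowsum(dX, cache$seq)
        g$E[as.integer(rownames(agg)), ] <- agg
        # Adam over the flat parameter list
        t_step <- t_step + 1
        bc1 <- 1 - 0.9^t_step
        bc2 <- 1 - 0.999^t_step
        adam_one <- function(pv, gv, mv, vv) {
          mv <- 0.9 * mv + 0.1 * gv
          vv <- 0.999 * vv + 0.001 * gv * gv
          pv <- pv - cfg$learning_rate * (mv / bc1) / (sqrt(vv / bc2) + 1e-8)
          list(p = pv, m = mv, v = vv)
        }
        s <- adam_one(p$E, g$E, adam_m$E, adam_v$E)
        p$E <- s$p; adam_m$E <- s$m; adam_v$E <- s$v
        for (wi in seq_along(p$W)) {
          s <- adam_one(p$W[[wi]], g$W[[wi]], adam_m$W[[wi]], adam_v$W[[wi]])
          p$W[[wi]] <- s$p; adam_m$W[[wi]] <- s$m; adam_v$W[[wi]] <- s$v
          s <- adam_one(p$b[[wi]], g$b[[wi]], adam_m$b[[wi]], adam_v$b[[wi]])
          p$b[[wi]] <- s$p; adam_m$b[[wi]] <- s$m; adam_v$b[[wi]] <- s$v
        }
        s <- adam_one(p$wout, g$wout, adam_m$wout, adam_v$wout)
        p$wout <- s$p; adam_m$wout <- s$m; adam_v$wout <- s$v
        s <- adam_one(p$bout, g$bout, adam_m$bout, adam_v$bout)
        p$bout <- s$p; adam_m$bout <- s$m; adam_v$bout <- s$v
      }
    }
    list(params = p, config = cfg)
  })
}

cnn_predict <- function(fit, seqs) {
  vapply(seqs, function(s) {
    cache <- cnn_forward(fit$params, fit$config, s)
    1 / (1 + exp(-(sum(fit$params$wout * cache$f) + fit$params$bout)))
  }, numeric(1))
}

#' Train one binary classifier per class
#'
#' `bow` and `lda` fit a random forest (100 trees) on the supplied feature
#' matrix; `cnn` fits the convolutional sentence classifier on raw token
#' sequences with learned embeddings, parallel filter widths, max-over-time
#' pooling and a logistic output. A class with no positive training example
#' is flagged and skipped.
#'
#' @param x feature matrix (`bow`/`lda`) or list of integer token sequences
#'   plus vocabulary size as `attr(x, "V")` (`cnn`).
#' @param labels character vector of document labels.
#' @param classes classes to fit (default: all observed).
#' @param classifier `"bow"`, `"lda"` or `"cnn"`.
#' @param config optional overrides (CNN: `embedding_dim`, `widths`,
#'   `n_filters`, `epochs`, `learning_rate`, `dropout`; RF: `ntree`).
#' @param seed training seed (deterministic refits).
#' @return list classed `class_models`: per class either a fitted model or
#'   `NULL` (skipped), plus `skipped`.
#' @export
train_classifier <- function(x, labels, classes = sort(unique(labels)),
                             classifier = c("bow", "lda", "cnn"),
                             config = list(), seed = 1L) {
  classifier <- match.arg(classifier)
  models <- list()
  skipped <- character(0)
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    y <- as.integer(labels == cl)
    if (!any(y == 1L)) {
      models[[cl]] <- NULL
      skipped <- c(skipped, cl)
      next
    }
    cseed <- as.integer(seed) + 7919L * ci
    if (classifier == "cnn") {
      cfg <- utils::modifyList(cnn_defaults(), config)
      models[[cl]] <- cnn_fit(x, y, attr(x, "V"), cfg, cseed)
    } else {
      ntree <- if (!is.null(config$ntree)) config$ntree else 100L
      xm <- x
      colnames(xm) <- paste0("f", seq_len(ncol(xm)))
      models[[cl]] <- with_seed(cseed, {
        randomForest::randomForest(xm, factor(y, levels = c(0L, 1L)),
                                   ntree = ntree)
      })
    }
  }
  out <- list(models = models, classes = classes, classifier = classifier,
              skipped = skipped)
  class(out) <- "class_models"
  out
}

#' Per-class positive probabilities on new documents
#'
#' @param object a `class_models` fit.
#' @param newdata feature matrix or token-sequence list matching the training
#'   representation.
#' @param ... unused.
#' @return matrix (documents x classes) of positive-class probabilities (`NA`
#'   columns for skipped classes).
#' @export
predict.class_models <- function(object, newdata, ...) {
  n <- if (is.matrix(newdata)) nrow(newdata) else length(newdata)
  out <- matrix(NA_real_, n, length(object$classes),
                dimnames = list(NULL, object$classes))
  for (cl in object$classes) {
    m <- object$models[[cl]]
    if (is.null(m)) next
    out[, cl] <- if (object$classifier == "cnn") {
      cnn_predict(m, newdata)
    } else {
      xm <- newdata
      colnames(xm) <- paste0("f", seq_len(ncol(xm)))
      stats::predict(m, xm, type = "prob")[, "1"]
    }
  }
  out
}

# encode labelled docs as flat integer sequences over a training vocabulary
cnn_encode <- function(docs, words = NULL) {
  token_lists <- lapply(docs$sentences, unlist)
  if (is.null(words)) words <- sort(unique(unlist(token_lists)))
  seqs <- lapply(token_lists, function(t) {
    idx <- match(t, words)
    idx[is.na(idx)] <- length(words) + 1L  # shared unknown row
    as.integer(idx)
  })
  attr(seqs, "V") <- length(words) + 1L
  attr(seqs, "words") <- words
  seqs
}

#' Run the extrinsic classification protocol
#'
#' Trains each classifier family on each training regime and evaluates on
#' genuine test data, repeated `n_runs` times with fresh seeds. With
#' `cv_folds`, patient-disjoint folds of the genuine classification set are
#' used: per run and class the fold F1 values are averaged, giving one data
#' point per (class, run) either way - 6 classes x 5 runs = 30 points, 13 x 5
#' = 65. Without folds, training regimes must be patient-disjoint from the
#' test set.
#'
#' @param regimes named list of `labelled_docs` training sets (e.g. `genuine`,
#'   `top_meta`, ...). Artificial regimes carry the same patients as their
#'   genuine counterparts, which is what the fold exclusion keys on.
#' @param test_docs genuine `labelled_docs` used for evaluation.
#' @param classifiers subset of `c("bow", "lda", "cnn")`.
#' @param n_runs retraining repeats (default 5).
#' @param cv_folds number of patient-disjoint folds, or `NULL` for a fixed
#'   test set.
#' @param seed master seed.
#' @param lda_reference corpus for [lda_fit()] (required for `"lda"`).
#' @param n_topics topics for the LDA family.
#' @param config per-family config overrides, e.g. `list(cnn = list(epochs = 20))`.
#' @param classes class labels to evaluate (default: those observed in the
#'   test set).
#' @return list classed `extrinsic_result`: `samples` (long data frame of
#'   per-class per-run F1 with regime/classifier tags), `predictions` (per
#'   regime and classifier, last run's per-document predictions for error
#'   analysis), `classes`, `skipped`.
#' @export
run_protocol <- function(regimes, test_docs, classifiers = c("bow", "lda", "cnn"),
                         n_runs = 5L, cv_folds = NULL, seed = 1L,
                         lda_reference = NULL, n_topics = 10L,
                         config = list(), classes = NULL) {
  stopifnot(is.list(regimes), length(names(regimes)) == length(regimes))
  classifiers <- match.arg(classifiers, c("bow", "lda", "cnn"), several.ok = TRUE)
  if (is.null(classes)) classes <- sort(unique(test_docs$label))
  if (is.null(cv_folds)) {
    for (nm in names(regimes)) {
      overlap <- intersect(regimes[[nm]]$patient_id, test_docs$patient_id)
      if (length(overlap)) {
        stop("patient overlap between training regime '", nm,
             "' and the test set (e.g. ", overlap[1], ")")
      }
    }
  }
  lda_model <- if ("lda" %in% classifiers) {
    if (is.null(lda_reference)) stop("lda_reference corpus required for the lda family")
    lda_fit(lda_reference, n_topics = n_topics, seed = seed)
  }
  folds <- if (!is.null(cv_folds)) {
    pats <- unique(test_docs$patient_id)
    perm <- with_seed(seed, sample(pats))
    split(perm, rep_len(seq_len(cv_folds), length(perm)))
  }
  samples <- list()
  predictions <- list()
  skipped <- character(0)
  for (regime in names(regimes)) {
    for (clf in classifiers) {
      for (run in seq_len(n_runs)) {
        run_seed <- as.integer(seed) + 1000L * run
        if (is.null(cv_folds)) {
          res <- fit_eval_once(regimes[[regime]], test_docs, clf, classes,
                               run_seed, lda_model, config)
          f1 <- res$f1
          predictions[[paste(regime, clf, sep = ".")]] <- res$pred
          skipped <- union(skipped, res$skipped)
        } else {
          per_fold <- matrix(NA_real_, length(folds), length(classes))
          for (fi in seq_along(folds)) {
            hold <- folds[[fi]]
            train <- regimes[[regime]][!regimes[[regime]]$patient_id %in% hold, ]
            class(train) <- class(regimes[[regime]])
            test <- test_docs[test_docs$patient_id %in% hold, ]
            class(test) <- class(test_docs)
            res <- fit_eval_once(train, test, clf, classes,
                                 run_seed + fi, lda_model, config)
            per_fold[fi, ] <- res$f1
            skipped <- union(skipped, res$skipped)
          }
          f1 <- colMeans(per_fold, na.rm = TRUE)
        }
        samples[[length(samples) + 1L]] <- data.frame(
          regime = regime, classifier = clf, class = classes, run = run,
          f1 = as.numeric(f1), stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- list(samples = do.call(rbind, samples), predictions = predictions,
              classes = classes, skipped = skipped)
  class(out) <- "extrinsic_result"
  out
}

fit_eval_once <- function(train_docs, test_docs, clf, classes, seed,
                          lda_model, config) {
  cfg <- if (!is.null(config[[clf]])) config[[clf]] else list()
  if (clf == "bow") {
    tr <- featurize_bow(train_docs,
                        max_n = if (!is.null(cfg$max_n)) cfg$max_n else 5L,
                        min_df = if (!is.null(cfg$min_df)) cfg$min_df else 2L)
    xtr <- tr$matrix
    xte <- featurize_bow(test_docs, features = tr$features)$matrix
  } else if (clf == "lda") {
    xtr <- featurize_lda(lda_model, train_docs, seed = seed)
    xte <- featurize_lda(lda_model, test_docs, seed = seed + 1L)
  } else {
    xtr <- cnn_encode(train_docs)
    xte <- cnn_encode(test_docs, words = attr(xtr, "words"))
  }
  fit <- train_classifier(xtr, train_docs$label, classes,
                          classifier = clf, config = cfg, seed = seed)
  prob <- predict(fit, xte)
  f1 <- vapply(classes, function(cl) {
    if (is.null(fit$models[[cl]])) return(NA_real_)
    f1_score(test_docs$label == cl, prob[, cl] >= 0.5)
  }, numeric(1))
  pred <- do.call(rbind, lapply(classes, function(cl) {
    data.frame(document_id = test_docs$document_id, class = cl,
               truth = test_docs$label == cl, pred = prob[, cl] >= 0.5,
               confidence = pmax(prob[, cl], 1 - prob[, cl]),
               stringsAsFactors = FALSE)
  }))
  list(f1 = f1, pred = pred, skipped = fit$skipped)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' `D` is the supremum absolute difference of the two empirical CDFs
#' (evaluated at every pooled sample point); the p-value uses the asymptotic
#' two-sided Kolmogorov distribution at `sqrt(n1*n2/(n1+n2)) * D`, which is
#' well-defined under ties (common in F1 samples). Symmetric in its
#' arguments.
#'
#' @param sample_a,sample_b non-empty numeric vectors.
#' @return list classed `ks_comparison` with `statistic`, `p_value`, `n1`,
#'   `n2`.
#' @export
ks_two_sample <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b)) stop("empty sample")
  pts <- sort(unique(c(sample_a, sample_b)))
  ea <- vapply(pts, function(x) mean(sample_a <= x), numeric(1))
  eb <- vapply(pts, function(x) mean(sample_b <= x), numeric(1))
  d <- max(abs(ea - eb))
  n1 <- length(sample_a)
  n2 <- length(sample_b)
  lambda <- sqrt(n1 * n2 / (n1 + n2)) * d
  p <- if (lambda < 1e-8) {
    1  # identical ECDFs: the alternating series is degenerate at 0
  } else {
    k <- 1:100
    2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  }
  out <- list(statistic = d, p_value = min(1, max(0, p)), n1 = n1, n2 = n2)
  class(out) <- "ks_comparison"
  out
}

#' @export
print.ks_comparison <- function(x, ...) {
  cat(sprintf("2S-KS: D = %.4f, p = %.4g (n1 = %d, n2 = %d)\n",
              x$statistic, x$p_value, x$n1, x$n2))
  invisible(x)
}

#' High-confidence error analysis
#'
#' Counts "bad errors" - false positives and false negatives where the model
#' is confident and wrong - for two prediction sets (typically genuine- and
#' artificial-trained models of the same family), and the fraction of the
#' first regime's bad errors also made by the second.
#'
#' @param predictions named list of exactly two prediction frames as returned
#'   in `run_protocol()$predictions` (columns `document_id`, `class`, `truth`,
#'   `pred`, `confidence`).
#' @param threshold confidence threshold in `(0.5, 1]`.
#' @return list with per-regime `fp` and `fn` counts and `overlap`.
#' @export
error_analysis <- function(predictions, threshold = 0.9) {
  if (threshold <= 0.5 || threshold > 1) stop("threshold must be in (0.5, 1]")
  stopifnot(is.list(predictions), length(predictions) == 2L)
  bad <- lapply(predictions, function(p) {
    wrong <- p$pred != p$truth & p$confidence >= threshold
    list(fp = sum(wrong & p$pred), fn = sum(wrong & !p$pred),
         keys = paste(p$document_id, p$class)[wrong])
  })
  overlap <- if (length(bad[[1]]$keys)) {
    mean(bad[[1]]$keys %in% bad[[2]]$keys)
  } else NA_real_
  list(
    counts = data.frame(regime = names(predictions),
                        fp = vapply(bad, `[[`, numeric(1), "fp"),
                        fn = vapply(bad, `[[`, numeric(1), "fn"),
                        stringsAsFactors = FALSE),
    overlap = overlap
  )
}
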