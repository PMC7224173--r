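# Memorisation audit: how often rare versus frequent training n-grams appear
# in the conditioning inputs (%in) and in the regenerated outputs (%out),
# with forced-decoding perplexity and the token composition of leaks.

#' Within-sentence n-gram frequency index
#'
#' Counts n-grams inside sentences (never across sentence boundaries) and
#' computes the lower/upper frequency-quartile thresholds by nearest-rank
#' 25th/75th percentile over the distinct-n-gram frequency distribution.
#'
#' @param corpus a non-empty [ehr_corpus()] (the generation training set).
#' @param ns integer vector of n-gram orders (default `c(2, 3, 5)`).
#' @return list classed `ngram_index`, one element per n with `freq` (named
#'   integer vector), `lower` and `upper` thresholds.
#' @export
build_ngram_index <- function(corpus, ns = c(2L, 3L, 5L)) {
  validate_corpus(corpus)
  if (nrow(corpus) == 0L) stop("corpus is empty")
  toks <- corpus_token_list(corpus)
  out <- list()
  for (n in ns) {
    grams <- unlist(lapply(toks, function(t) {
      if (length(t) >= n) sent_ngrams(t, n) else character(0)
    }))
    if (!length(grams)) {
      out[[as.character(n)]] <- list(freq = integer(0), lower = NA_integer_,
                                     upper = NA_integer_)
      next
    }
    freq <- table(grams)
    f <- sort(as.integer(freq))
    out[[as.character(n)]] <- list(
      freq = stats::setNames(as.integer(freq), names(freq)),
      lower = f[max(1L, ceiling(0.25 * length(f)))],
      upper = f[max(1L, ceiling(0.75 * length(f)))]
    )
  }
  class(out) <- "ngram_index"
  out
}

# space-joined n-grams of one sentence
sent_ngrams <- function(tokens, n) {
  L <- length(tokens)
  if (L < n) return(character(0))
  vapply(seq_len(L - n + 1L), function(i) {
    paste(tokens[i:(i + n - 1L)], collapse = " ")
  }, character(1))
}

#' Sample sentences carrying quartile-class n-grams
#'
#' Randomly selects up to `k` unique sentences that contain at least one
#' n-gram in the requested frequency-quartile class (`low`: frequency at or
#' below the lower threshold; `high`: at or above the upper threshold). For
#' each sampled sentence one target n-gram is chosen: the lowest-frequency
#' (`low`) or highest-frequency (`high`) eligible n-gram, earliest sentence
#' position first on ties.
#'
#' @param corpus the training [ehr_corpus()].
#' @param index a matching [build_ngram_index()].
#' @param n n-gram order (must be present in the index).
#' @param quartile `"low"` or `"high"`.
#' @param k sample size; when fewer sentences are eligible all of them are
#'   returned and the shortfall is recorded.
#' @param seed sampling seed.
#' @return data frame classed `audit_sample` with the sentence keys, `target`
#'   (space-joined n-gram) and `target_freq`; attributes `n`, `quartile`,
#'   `shortfall`.
#' @export
sample_sentences_by_quartile <- function(corpus, index, n, quartile = c("low", "high"),
                                         k = 1000L, seed = 1L) {
  quartile <- match.arg(quartile)
  entry <- index[[as.character(n)]]
  if (is.null(entry)) stop("n = ", n, " is not in the index")
  toks <- corpus_token_list(corpus)
  eligible <- integer(0)
  targets <- character(0)
  tfreq <- integer(0)
  for (i in seq_along(toks)) {
    grams <- sent_ngrams(toks[[i]], n)
    if (!length(grams)) next
    f <- entry$freq[grams]
    ok <- if (quartile == "low") f <= entry$lower else f >= entry$upper
    if (!any(ok)) next
    pos <- which(ok)
    pick <- if (quartile == "low") {
      pos[order(f[pos], pos)][1]
    } else {
      pos[order(-f[pos], pos)][1]
    }
    eligible <- c(eligible, i)
    targets <- c(targets, grams[pick])
    tfreq <- c(tfreq, as.integer(f[pick]))
  }
  shortfall <- max(0L, k - length(eligible))
  take <- if (length(eligible) > k) {
    with_seed(seed, sort(sample.int(length(eligible), k)))
  } else seq_along(eligible)
  out <- data.frame(
    document_id = corpus$document_id[eligible[take]],
    paragraph_index = corpus$paragraph_index[eligible[take]],
    sentence_index = corpus$sentence_index[eligible[take]],
    target = targets[take], target_freq = tfreq[take],
    stringsAsFactors = FALSE
  )
  attr(out, "n") <- as.integer(n)
  attr(out, "quartile") <- quartile
  attr(out, "shortfall") <- shortfall
  class(out) <- c("audit_sample", "data.frame")
  out
}

# is `gram` (token vector) contiguous inside `tokens`?
contains_run <- function(tokens, gram) {
  k <- length(gram)
  L <- length(tokens)
  if (k == 0L || L < k) return(FALSE)
  for (i in seq_len(L - k + 1L)) {
    if (all(tokens[i:(i + k - 1L)] == gram)) return(TRUE)
  }
  FALSE
}

#' Audit one (n, quartile) sample for memorisation
#'
#' For each sampled sentence, the conditioning input is rebuilt with the
#' model's setup and the sentence regenerated. `pct_in` is the percentage of
#' target n-grams occurring contiguously inside a single selected key phrase;
#' `pct_out` the percentage occurring contiguously in the regenerated output;
#' `beyond_input_rate` is `pct_out` restricted to targets absent from the
#' input (true memorisation); `mean_ppl` is the forced-decoding perplexity of
#' the original sentences; `composition` gives the stopword / punctuation /
#' numeric / other token fractions of the leaked (restored) targets. For the
#' copy baseline the output is its key-phrase input, so `pct_out == pct_in`
#' exactly.
#'
#' @param model a trained [train_generator()] model, or `"copy_baseline"`.
#' @param corpus the training corpus the sample came from.
#' @param sample a [sample_sentences_by_quartile()] frame.
#' @param setup conditioning setup; must equal the model's training setup.
#' @param stopwords stopword list for extraction and composition.
#' @param keep_fraction passed to [select_phrases()].
#' @param across_phrases when `TRUE`, `pct_in` containment may also span
#'   adjacent key phrases in the concatenated input stream (the borders are
#'   unmarked in the model input; the default audits within single phrases).
#' @return one-row data frame classed `memorisation_row` with `n`, `quartile`,
#'   `k`, `pct_in`, `pct_out`, `beyond_input_rate`, `mean_ppl` and the
#'   composition fractions.
#' @export
audit_memorisation <- function(model, corpus, sample, setup = NULL,
                               stopwords = load_stopwords(),
                               keep_fraction = 0.6, across_phrases = FALSE) {
  copy_mode <- identical(model, "copy_baseline")
  if (copy_mode) {
    if (is.null(setup)) setup <- "key"
  } else {
    stopifnot(inherits(model, "gapfill_generator"))
    if (is.null(setup)) setup <- model$setup
    if (!identical(setup, model$setup)) {
      stop("setup mismatch: model was trained with '", model$setup,
           "', audit requested '", setup, "'")
    }
  }
  keep_docs <- unique(sample$document_id)
  sub <- corpus[corpus$document_id %in% keep_docs, , drop = FALSE]
  class(sub) <- c("ehr_corpus", "data.frame")
  pairs <- conditioned_pairs(sub, setup, stopwords, keep_fraction)
  key <- function(df) paste(df$document_id, df$paragraph_index, df$sentence_index)
  idx <- match(key(sample), key(pairs))
  stopifnot(!anyNA(idx))
  pairs <- pairs[idx, , drop = FALSE]
  attr(pairs, "setup") <- setup
  class(pairs) <- c("conditioned_pairs", "data.frame")

  grams <- strsplit(sample$target, " ", fixed = TRUE)
  in_hit <- vapply(seq_along(grams), function(i) {
    runs <- pairs$phrases[[i]]
    if (across_phrases) {
      contains_run(unlist(runs), grams[[i]])
    } else {
      any(vapply(runs, contains_run, logical(1), gram = grams[[i]]))
    }
  }, logical(1))

  if (copy_mode) {
    out_hit <- in_hit
    ppl <- NA_real_
  } else {
    gen <- generate_text(model, pairs)
    out_toks <- lapply(gen$output, tokenize_one)
    out_hit <- vapply(seq_along(grams), function(i) {
      contains_run(out_toks[[i]], grams[[i]])
    }, logical(1))
    ppl <- perplexity(model, pairs)
  }
  beyond <- !in_hit
  comp <- composition_of_leaks(sample$target[out_hit], stopwords)
  out <- data.frame(
    n = attr(sample, "n"), quartile = attr(sample, "quartile"),
    k = nrow(sample),
    pct_in = 100 * mean(in_hit),
    pct_out = 100 * mean(out_hit),
    beyond_input_rate = if (any(beyond)) 100 * mean(out_hit[beyond]) else 0,
    mean_ppl = ppl,
    frac_stopword = comp["stopword"], frac_punctuation = comp["punctuation"],
    frac_numeric = comp["numeric"], frac_other = comp["other"],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("memorisation_row", "data.frame")
  out
}

#' Token composition of leaked n-grams
#'
#' Fractions of stopword, punctuation and numeric tokens over all tokens of
#' the leaked n-grams (those restored in the generated output); the remainder
#' is `other`. An empty leak set yields all zeros.
#'
#' @param leaked character vector of space-joined n-grams.
#' @param stopwords stopword token set.
#' @return named numeric vector `stopword`, `punctuation`, `numeric`, `other`.
#' @export
composition_of_leaks <- function(leaked, stopwords = load_stopwords()) {
  toks <- unlist(strsplit(leaked, " ", fixed = TRUE))
  if (!length(toks)) {
    return(c(stopword = 0, punctuation = 0, numeric = 0, other = 0))
  }
  sw <- toks %in% stopwords
  pu <- !sw & is_punct_token(toks)
  nu <- !sw & !pu & is_numeric_token(toks)
  c(stopword = mean(sw), punctuation = mean(pu), numeric = mean(nu),
    other = mean(!(sw | pu | nu)))
}

#' Full memorisation report over (n, quartile) combinations
#'
#' @param model trained generator or `"copy_baseline"`.
#' @param corpus training corpus.
#' @param index [build_ngram_index()] of the corpus.
#' @param ns n-gram orders to audit.
#' @param k sample size per cell.
#' @param seed sampling seed.
#' @param ... passed to [audit_memorisation()].
#' @return data frame with one `memorisation_row` per (n, quartile).
#' @export
memorisation_report <- function(model, corpus, index, ns = c(2L, 3L, 5L),
                                k = 1000L, seed = 1L, ...) {
  rows <- list()
  for (n in ns) {
    for (q in c("high", "low")) {
      smp <- sample_sentences_by_quartile(corpus, index, n, q, k, seed)
      if (!nrow(smp)) next
      rows[[length(rows) + 1L]] <- audit_memorisation(model, corpus, smp, ...)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
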