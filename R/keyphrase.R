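# RAKE key-phrase extraction (Rose et al. deg/freq scoring), per-setup phrase
# selection, and construction of the conditioned input/target pairs that feed
# the gap-filling generator.

#' Load a stopword list
#'
#' One token per line, UTF-8. The packaged default is a standard English list
#' extended with common clinical-reporting verbs (reports, denies, noted, ...)
#' so that phrase candidates are content-word runs.
#'
#' @param path optional path to a custom list; default uses the packaged one.
#' @return character vector of stopword tokens.
#' @export
load_stopwords <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "stopwords_en.txt", package = "synthnotes")
  }
  sw <- readLines(path, encoding = "UTF-8")
  sw <- trimws(sw)
  sw[nzchar(sw)]
}

#' Extract RAKE key phrases from one paragraph
#'
#' Candidates are maximal runs of tokens that are neither stopwords nor
#' punctuation, taken within sentences (sentence boundaries and punctuation
#' tokens delimit phrases). Over all candidates of the paragraph,
#' `freq(w)` is the number of candidates containing word `w` (with
#' multiplicity) and `deg(w)` the summed length of those candidates; a word
#' scores `deg(w)/freq(w)` and a phrase the sum of its word scores.
#'
#' @param paragraph list of token vectors, one per sentence, in order.
#' @param stopwords character vector of stopword tokens.
#' @return data frame classed `keyphrases` with columns `phrase` (space-joined
#'   tokens), `score`, `sentence_index` (0-based within the paragraph) and
#'   `start` (1-based token offset within the sentence), ordered by textual
#'   position. Zero rows when the paragraph holds no content run.
#' @export
rake_extract <- function(paragraph, stopwords) {
  stopifnot(is.list(paragraph), length(paragraph) > 0L, length(stopwords) > 0L)
  cands <- list()
  for (si in seq_along(paragraph)) {
    toks <- paragraph[[si]]
    keep <- !(toks %in% stopwords) & !is_punct_token(toks)
    if (!length(toks)) next
    r <- rle(keep)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      cands[[length(cands) + 1L]] <- list(
        tokens = toks[starts[j]:ends[j]], sentence_index = si - 1L,
        start = starts[j]
      )
    }
  }
  if (!length(cands)) {
    return(empty_keyphrases())
  }
  words <- unlist(lapply(cands, `[[`, "tokens"))
  lens <- rep(vapply(cands, function(c) length(c$tokens), integer(1)),
              vapply(cands, function(c) length(c$tokens), integer(1)))
  freq <- tapply(rep(1L, length(words)), words, sum)
  deg <- tapply(lens, words, sum)
  wscore <- deg / freq
  out <- data.frame(
    phrase = vapply(cands, function(c) paste(c$tokens, collapse = " "), character(1)),
    score = vapply(cands, function(c) sum(wscore[c$tokens]), numeric(1)),
    sentence_index = vapply(cands, `[[`, integer(1), "sentence_index"),
    start = vapply(cands, `[[`, integer(1), "start"),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$sentence_index, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("keyphrases", "data.frame")
  out
}

empty_keyphrases <- function() {
  out <- data.frame(phrase = character(0), score = numeric(0),
                    sentence_index = integer(0), start = integer(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("keyphrases", "data.frame")
  out
}

#' Select key phrases for a conditioning setup
#'
#' `all` and `key` keep every extracted phrase; `top_meta` keeps phrases
#' scoring at or above the paragraph's nearest-rank score quantile (default:
#' the top 60% by score) and always retains each sentence's best phrase so the
#' one-best selection is a subset; `one_meta` keeps exactly the best-scored
#' phrase per sentence (ties broken by earlier position). Textual order is
#' preserved.
#'
#' @param phrases a `keyphrases` frame from one paragraph.
#' @param setup one of `"all"`, `"top_meta"`, `"one_meta"`, `"key"`.
#' @param keep_fraction fraction of phrases the `top_meta` quantile keeps.
#' @return the selected `keyphrases` rows, in textual order.
#' @export
select_phrases <- function(phrases, setup, keep_fraction = 0.6) {
  setup <- match.arg(setup, c("all", "top_meta", "one_meta", "key"))
  if (nrow(phrases) == 0L) return(phrases)
  if (setup %in% c("all", "key")) return(phrases)
  best_per_sentence <- function() {
    keep <- logical(nrow(phrases))
    for (si in unique(phrases$sentence_index)) {
      idx <- which(phrases$sentence_index == si)
      best <- idx[order(-phrases$score[idx], phrases$start[idx])][1]
      keep[best] <- TRUE
    }
    keep
  }
  if (setup == "one_meta") {
    out <- phrases[best_per_sentence(), , drop = FALSE]
  } else {
    s <- sort(phrases$score)
    thr <- s[min(length(s), floor((1 - keep_fraction) * length(s)) + 1L)]
    out <- phrases[phrases$score >= thr | best_per_sentence(), , drop = FALSE]
  }
  out <- out[order(out$sentence_index, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# metadata rendered as one reserved abbreviation token per field
meta_tokens <- function(row) {
  ts <- row$relative_timestamp
  c(tolower(row$diagnosis_code),
    tolower(row$gender),
    sprintf("age_%ds", (row$age %/% 10L) * 10L),
    if (row$death_flag) "death_yes" else "death_no",
    if (ts < 0L) "ts_pre" else if (ts <= 7L) "ts_week1" else "ts_later",
    paste0("sec_", row$section_label),
    paste0("ord_", min(row$sentence_ordinal, 10L)))
}

#' Build conditioned input/target pairs for a corpus
#'
#' Key phrases are extracted per paragraph ([rake_extract()]), selected per
#' setup ([select_phrases()]), and matched to their sentences. Each sentence
#' yields one pair: for `top_meta`/`one_meta` the input is the metadata block
#' (diagnosis code, gender, age decade, death flag, timestamp bucket, section,
#' ordinal - one reserved token each) followed by the selected phrase tokens
#' in textual order, with no markers between phrases; for `all` the input is
#' the phrase tokens only. The target is the original sentence; under the
#' `key` baseline setup the target is instead the concatenated phrases
#' themselves (the copy baseline's reference output).
#'
#' @param corpus an [ehr_corpus()].
#' @param setup one of `"all"`, `"top_meta"`, `"one_meta"`, `"key"`.
#' @param stopwords stopword vector (default: packaged list).
#' @param keep_fraction passed to [select_phrases()] for `top_meta`.
#' @return data frame classed `conditioned_pairs` with columns `document_id`,
#'   `paragraph_index`, `sentence_index`, `input`, `target` (space-joined
#'   tokens) and a list column `phrases` holding each sentence's selected
#'   phrase token runs; attribute `setup` records the setup.
#' @export
conditioned_pairs <- function(corpus, setup,
                              stopwords = load_stopwords(),
                              keep_fraction = 0.6) {
  setup <- match.arg(setup, c("all", "top_meta", "one_meta", "key"))
  validate_corpus(corpus)
  out <- vector("list", nrow(corpus))
  pos <- 0L
  for (doc in corpus_documents(corpus)) {
    for (pi in unique(doc$paragraph_index)) {
      par <- doc[doc$paragraph_index == pi, , drop = FALSE]
      par <- par[order(par$sentence_index), , drop = FALSE]
      toks <- lapply(par$text, tokenize_one)
      sel <- select_phrases(rake_extract(toks, stopwords), setup, keep_fraction)
      for (j in seq_len(nrow(par))) {
        row <- par[j, ]
        mine <- sel[sel$sentence_index == row$sentence_index, , drop = FALSE]
        runs <- lapply(strsplit(mine$phrase, " ", fixed = TRUE), identity)
        phrase_toks <- unlist(runs)
        if (is.null(phrase_toks)) phrase_toks <- character(0)
        input <- switch(setup,
          all = , key = phrase_toks,
          top_meta = , one_meta = c(meta_tokens(row), phrase_toks))
        target <- if (setup == "key") phrase_toks else toks[[j]]
        pos <- pos + 1L
        out[[pos]] <- list(
          document_id = row$document_id, paragraph_index = row$paragraph_index,
          sentence_index = row$sentence_index,
          input = detokenize(input), target = detokenize(target),
          phrases = runs
        )
      }
    }
  }
  out <- out[seq_len(pos)]
  pairs <- data.frame(
    document_id = vapply(out, `[[`, character(1), "document_id"),
    paragraph_index = vapply(out, `[[`, integer(1), "paragraph_index"),
    sentence_index = vapply(out, `[[`, integer(1), "sentence_index"),
    input = vapply(out, `[[`, character(1), "input"),
    target = vapply(out, `[[`, character(1), "target"),
    stringsAsFactors = FALSE
  )
  pairs$phrases <- lapply(out, `[[`, "phrases")
  attr(pairs, "setup") <- setup
  class(pairs) <- c("conditioned_pairs", "data.frame")
  pairs
}

#' @export
print.conditioned_pairs <- function(x, ...) {
  cat(sprintf("<conditioned_pairs> %d pairs, setup = %s\n", nrow(x),
              attr(x, "setup")))
  if (nrow(x)) {
    cat("  input : ", x$input[1], "\n  target: ", x$target[1], "\n", sep = "")
  }
  invisible(x)
}

#' Serialise conditioned pairs as two aligned line files
#'
#' @param pairs a `conditioned_pairs` frame.
#' @param stem output path stem; writes `<stem>.input.txt` and
#'   `<stem>.target.txt`, one space-joined token sequence per line.
#' @return the two paths, invisibly.
#' @export
write_pairs <- function(pairs, stem) {
  paths <- paste0(stem, c(".input.txt", ".target.txt"))
  writeLines(pairs$input, paths[1], useBytes = TRUE)
  writeLines(pairs$target, paths[2], useBytes = TRUE)
  invisible(paths)
}

#' Token vocabulary with frequency pruning
#'
#' Counts tokens over the inputs and targets of the training pairs and maps
#' every token seen at least `min_frequency` times to an integer index.
#' Indices 1-4 are reserved for `<pad>`, `<unk>`, `<s>`, `</s>`; remaining
#' tokens are ordered by descending frequency, then lexicographically. Tokens
#' below the threshold (in particular all frequency-1 words) encode to
#' `<unk>`.
#'
#' @param pairs a `conditioned_pairs` frame (training pairs only).
#' @param min_frequency minimum training frequency, at least 2.
#' @return list with `index` (named integer vector), `min_frequency`, and the
#'   special token names; classed `vocabulary`.
#' @export
build_vocabulary <- function(pairs, min_frequency = 2L) {
  if (nrow(pairs) == 0L) stop("cannot build a vocabulary from zero pairs")
  if (min_frequency < 2L) stop("min_frequency must be >= 2")
  toks <- c(unlist(strsplit(pairs$input, " ", fixed = TRUE)),
            unlist(strsplit(pairs$target, " ", fixed = TRUE)))
  toks <- toks[nzchar(toks)]
  freq <- table(toks)
  keep <- freq[freq >= min_frequency]
  ord <- order(-as.integer(keep), names(keep))
  specials <- c("<pad>", "<unk>", "<s>", "</s>")
  index <- stats::setNames(seq_len(4L + length(keep)),
                           c(specials, names(keep)[ord]))
  out <- list(index = index, min_frequency = as.integer(min_frequency),
              pad = 1L, unk = 2L, bos = 3L, eos = 4L)
  class(out) <- "vocabulary"
  out
}

#' @export
print.vocabulary <- function(x, ...) {
  cat(sprintf("<vocabulary> %d tokens (incl. 4 specials), min frequency %d\n",
              length(x$index), x$min_frequency))
  invisible(x)
}

# encode a token vector to integer indices (unknowns -> <unk>)
encode_tokens <- function(tokens, vocab) {
  idx <- unname(vocab$index[tokens])
  idx[is.na(idx)] <- vocab$unk
  as.integer(idx)
}

decode_tokens <- function(ids, vocab) {
  names(vocab$index)[ids]
}

#' Remove conditioning key phrases from paired corpora
#'
#' Deletes every occurrence of each selected phrase's token run from both the
#' genuine and the artificial corpus, dropping sentences emptied entirely -
#' the context-only ablation input for the extrinsic classifiers.
#'
#' @param genuine,artificial aligned [ehr_corpus()] objects.
#' @param phrases character vector of phrases (space-joined tokens), e.g.
#'   unique phrases from a `conditioned_pairs` frame.
#' @return list with elements `genuine` and `artificial`.
#' @export
strip_common_keyphrases <- function(genuine, artificial, phrases) {
  runs <- strsplit(unique(phrases), " ", fixed = TRUE)
  runs <- runs[order(-lengths(runs))]  # longest first so subsumed runs go too
  strip_one <- function(corpus) {
    keep <- logical(nrow(corpus))
    for (i in seq_len(nrow(corpus))) {
      toks <- tokenize_one(corpus$text[i])
      for (run in runs) toks <- delete_run(toks, run)
      corpus$text[i] <- detokenize(toks)
      keep[i] <- length(toks) > 0L
    }
    sub <- corpus[keep, , drop = FALSE]
    rownames(sub) <- NULL
    class(sub) <- c("ehr_corpus", "data.frame")
    sub
  }
  list(genuine = strip_one(genuine), artificial = strip_one(artificial))
}

# delete all (non-overlapping, left-to-right) occurrences of run from tokens
delete_run <- function(tokens, run) {
  k <- length(run)
  if (k == 0L || length(tokens) < k) return(tokens)
  out <- character(0)
  i <- 1L
  while (i <= length(tokens)) {
    if (i + k - 1L <= length(tokens) && all(tokens[i:(i + k - 1L)] == run)) {
      i <- i + k
    } else {
      out <- c(out, tokens[i])
      i <- i + 1L
    }
  }
  out
}
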