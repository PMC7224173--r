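#' @useDynLib synthnotes, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

SECTION_LABELS <- c("summary", "discharge_plan", "comments")

CORPUS_COLUMNS <- c(
  "document_id", "patient_id", "paragraph_index", "sentence_index", "text",
  "diagnosis_code", "diagnosis_description", "gender", "age", "death_flag",
  "relative_timestamp", "section_label", "sentence_ordinal"
)

#' Construct a sentence-level corpus
#'
#' A corpus is a data frame with one row per sentence and a fixed column set:
#' `document_id`, `patient_id`, `paragraph_index` (0-based), `sentence_index`
#' (0-based within paragraph), `text` (raw sentence), and the clinical
#' metadata fields `diagnosis_code`, `diagnosis_description`, `gender`,
#' `age` (integer years), `death_flag` (logical), `relative_timestamp`
#' (signed days from admission), `section_label` (one of `summary`,
#' `discharge_plan`, `comments`), `sentence_ordinal` (1-based position within
#' its section). Patient-level metadata is constant within a document;
#' ordinals increase by one within each section in document order.
#'
#' @param df data frame holding the columns above.
#' @return the validated corpus, classed `ehr_corpus`.
#' @export
ehr_corpus <- function(df) {
  validate_corpus(df)
  class(df) <- c("ehr_corpus", "data.frame")
  df
}

#' @export
print.ehr_corpus <- function(x, ...) {
  cat(sprintf(
    "<ehr_corpus> %d sentences, %d documents, %d patients, %d diagnosis codes\n",
    nrow(x), length(unique(x$document_id)), length(unique(x$patient_id)),
    length(unique(x$diagnosis_code))
  ))
  invisible(x)
}

validate_corpus <- function(df) {
  if (!is.data.frame(df)) stop("corpus must be a data frame")
  missing_cols <- setdiff(CORPUS_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("corpus is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  bad <- setdiff(unique(df$section_label), SECTION_LABELS)
  if (length(bad)) stop("unknown section_label: ", paste(bad, collapse = ", "))
  if (nrow(df) == 0L) return(invisible(df))
  if (any(df$paragraph_index < 0L) || any(df$sentence_index < 0L)) {
    stop("paragraph_index and sentence_index must be non-negative")
  }
  if (any(df$sentence_ordinal < 1L)) stop("sentence_ordinal must be >= 1")
  if (any(df$age < 0L)) stop("age must be non-negative")
  if (any(grepl("[\t\n]", df$text))) stop("sentence text may not contain tabs or newlines")
  # one patient and constant patient-level metadata per document
  per_doc <- split(df, df$document_id)
  for (d in per_doc) {
    for (col in c("patient_id", "diagnosis_code", "diagnosis_description",
                  "gender", "age", "death_flag")) {
      if (length(unique(d[[col]])) != 1L) {
        stop(sprintf("document %s has non-constant %s", d$document_id[1], col))
      }
    }
    for (sec in unique(d$section_label)) {
      ords <- d$sentence_ordinal[d$section_label == sec]
      if (!identical(as.integer(ords), seq_along(ords))) {
        stop(sprintf("document %s: ordinals in section %s are not 1,2,... in order",
                     d$document_id[1], sec))
      }
    }
  }
  invisible(df)
}

#' Read and write the corpus exchange format
#'
#' The exchange format is UTF-8, line-delimited, tab-separated text: a header
#' line with the fixed column set of [ehr_corpus()] followed by one record per
#' sentence, grouped by document. `age`, `paragraph_index`, `sentence_index`,
#' `relative_timestamp` and `sentence_ordinal` are decimal integers;
#' `death_flag` is `TRUE`/`FALSE`. Tabs and newlines are forbidden inside
#' fields, which makes the round trip `read_corpus(write_corpus(x))` exact.
#'
#' @param path file path.
#' @return `read_corpus` returns an `ehr_corpus`; `write_corpus` returns the
#'   path, invisibly.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("no such corpus file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L || (length(lines) == 1L && !nzchar(lines[1]))) {
    df <- as.data.frame(matrix(character(0), 0, length(CORPUS_COLUMNS)),
                        stringsAsFactors = FALSE)
    names(df) <- CORPUS_COLUMNS
    return(ehr_corpus(coerce_corpus_types(df)))
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header, CORPUS_COLUMNS)) {
    stop("line 1: bad header; expected the documented corpus column set")
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (!length(body)) {
    df <- as.data.frame(matrix(character(0), 0, length(CORPUS_COLUMNS)),
                        stringsAsFactors = FALSE)
    names(df) <- CORPUS_COLUMNS
    return(ehr_corpus(coerce_corpus_types(df)))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(CORPUS_COLUMNS))) {
    i <- which(nf != length(CORPUS_COLUMNS))[1]
    stop(sprintf("line %d: expected %d tab-separated fields, found %d",
                 i + 1L, length(CORPUS_COLUMNS), nf[i]))
  }
  df <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(df) <- CORPUS_COLUMNS
  int_cols <- c("paragraph_index", "sentence_index", "age",
                "relative_timestamp", "sentence_ordinal")
  for (col in int_cols) {
    v <- suppressWarnings(as.integer(df[[col]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      stop(sprintf("line %d: field %s is not an integer: '%s'",
                   i + 1L, col, df[[col]][i]))
    }
  }
  bad_flag <- !df$death_flag %in% c("TRUE", "FALSE")
  if (any(bad_flag)) {
    stop(sprintf("line %d: death_flag must be TRUE or FALSE, got '%s'",
                 which(bad_flag)[1] + 1L, df$death_flag[which(bad_flag)[1]]))
  }
  ehr_corpus(coerce_corpus_types(df))
}

coerce_corpus_types <- function(df) {
  for (col in c("paragraph_index", "sentence_index", "age",
                "relative_timestamp", "sentence_ordinal")) {
    df[[col]] <- as.integer(df[[col]])
  }
  df$death_flag <- as.logical(df$death_flag)
  for (col in setdiff(CORPUS_COLUMNS, c("paragraph_index", "sentence_index",
                                        "age", "relative_timestamp",
                                        "sentence_ordinal", "death_flag"))) {
    df[[col]] <- as.character(df[[col]])
  }
  rownames(df) <- NULL
  df[, CORPUS_COLUMNS]
}

#' @rdname read_corpus
#' @param corpus an `ehr_corpus`.
#' @export
write_corpus <- function(corpus, path) {
  validate_corpus(corpus)
  rows <- vapply(seq_len(nrow(corpus)), function(i) {
    paste(vapply(CORPUS_COLUMNS, function(col) {
      v <- corpus[[col]][i]
      if (is.logical(v)) if (v) "TRUE" else "FALSE" else as.character(v)
    }, character(1)), collapse = "\t")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(CORPUS_COLUMNS, collapse = "\t"), rows), con,
             useBytes = TRUE)
  invisible(path)
}

#' Patient-grouped train/validation/test split
#'
#' Assigns whole patients (all their documents) to the three parts, so no
#' patient contributes sentences to more than one part. Part sizes follow the
#' requested fractions by largest remainder, so each realised patient count is
#' within one of `fraction * n_patients`.
#'
#' @param corpus an `ehr_corpus`.
#' @param fractions numeric length 3 (train, validation, test), summing to 1.
#' @param seed integer seed controlling the patient shuffle.
#' @return list with elements `train`, `validation`, `test` (each an
#'   `ehr_corpus`), classed `corpus_split`.
#' @export
split_by_patient <- function(corpus, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  validate_corpus(corpus)
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must be three proportions summing to 1")
  }
  patients <- unique(corpus$patient_id)
  n <- length(patients)
  if (n < 3L) stop("need at least 3 distinct patients to split, got ", n)
  perm <- with_seed(seed, sample.int(n))
  patients <- patients[perm]
  counts <- floor(fractions * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac_part <- fractions * n - floor(fractions * n)
    extra <- order(frac_part, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  idx <- cumsum(counts)
  parts <- list(
    train = patients[seq_len(counts[1])],
    validation = if (counts[2] > 0) patients[(idx[1] + 1):idx[2]] else character(0),
    test = if (counts[3] > 0) patients[(idx[2] + 1):idx[3]] else character(0)
  )
  out <- lapply(parts, function(p) {
    sub <- corpus[corpus$patient_id %in% p, , drop = FALSE]
    rownames(sub) <- NULL
    class(sub) <- c("ehr_corpus", "data.frame")
    sub
  })
  class(out) <- "corpus_split"
  out
}

#' @export
print.corpus_split <- function(x, ...) {
  for (part in names(x)) {
    cat(sprintf("%-10s %6d sentences  %4d patients\n", part, nrow(x[[part]]),
                length(unique(x[[part]]$patient_id))))
  }
  invisible(x)
}

#' Corpus summary statistics
#'
#' @param corpus a non-empty `ehr_corpus`.
#' @return list with `n_tokens`, `n_sentences`, `n_documents`, `n_patients`,
#'   `mean_sentence_length`, and `frequency_spectrum` (named integer vector of
#'   unigram frequencies, sorted non-increasing).
#' @export
corpus_statistics <- function(corpus) {
  validate_corpus(corpus)
  if (nrow(corpus) == 0L) stop("corpus is empty")
  toks <- lapply(corpus$text, tokenize_one)
  n_tokens <- sum(lengths(toks))
  freq <- sort(table(unlist(toks)), decreasing = TRUE)
  list(
    n_tokens = n_tokens,
    n_sentences = nrow(corpus),
    n_documents = length(unique(corpus$document_id)),
    n_patients = length(unique(corpus$patient_id)),
    mean_sentence_length = n_tokens / nrow(corpus),
    frequency_spectrum = stats::setNames(as.integer(freq), names(freq))
  )
}

# run expr under a temporary RNG state, restoring the caller's state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# tokenised sentences of a corpus, as a list of character vectors
corpus_token_list <- function(corpus) lapply(corpus$text, tokenize_one)

# split a corpus into documents (list of data frames, file order preserved)
corpus_documents <- function(corpus) {
  split(as.data.frame(corpus), factor(corpus$document_id,
                                      levels = unique(corpus$document_id)))
}
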