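# Fixture corpora with the statistical structure the pipeline assumes:
# diagnosis-correlated marker phrases, Zipf-tailed filler vocabulary drawn
# through a small clause grammar, and planted rare n-grams occurring exactly
# once corpus-wide, with an answer key recording where everything went.

# fixed grammar words; all of these are on the packaged stopword list so RAKE
# candidates are exactly the drawn content slots
GRAMMAR_PATTERNS <- list(
  c("he", "reports", "C", "C", "and", "C", "C", "."),
  c("she", "denies", "C", "C", "but", "notes", "C", "C", "."),
  c("the", "patient", "was", "noted", "to", "have", "C", "C", "with", "C", "C", "."),
  c("on", "review", "she", "was", "C", "and", "C", "C", "with", "C", "C", "."),
  c("he", "was", "started", "on", "C", "C", "with", "C", "C", "and", "C", "."),
  c("plan", "to", "continue", "C", "C", "in", "the", "community", "with", "C", "C", ".")
)

BASE_CONTENT_WORDS <- c(
  "mood", "sleep", "appetite", "anxiety", "agitation", "insight", "risk",
  "medication", "olanzapine", "sertraline", "diazepam", "lithium", "dose",
  "symptoms", "thoughts", "concentration", "energy", "weight", "alcohol",
  "cannabis", "family", "housing", "follow", "clinic", "team", "leave",
  "ward", "review", "patient", "community", "self", "harm", "ideation",
  "paranoia", "voices", "stress", "memory", "appetite2", "engagement"
)

MARKER_PHRASES <- list(
  c("auditory", "hallucinations"), c("persistent", "anhedonia"),
  c("unstable", "relationships"), c("elevated", "grandiosity"),
  c("mixed", "affective"), c("alcohol", "dependence")
)

DIAGNOSES <- data.frame(
  code = c("F20", "F32", "F60", "F31", "F25", "F10"),
  description = c("schizophrenia", "major depressive disorder",
                  "specific personality disorders",
                  "bipolar affective disorder", "schizoaffective disorders",
                  "mental and behavioural disorders due to use of alcohol"),
  stringsAsFactors = FALSE
)

#' Configuration for the synthetic corpus generator
#'
#' @param n_patients number of patients.
#' @param docs_per_patient documents per patient.
#' @param sentences_per_doc integer range `c(min, max)` of sentences per
#'   document.
#' @param n_classes number of diagnosis codes; the first six use ICD-10-style
#'   mental-health codes and fixed two-word marker phrases, further classes get
#'   generated codes and markers.
#' @param class_signal_strength probability that a filler sentence carries its
#'   document's class marker phrase.
#' @param vocab_size total content-token budget: filler vocabulary plus marker,
#'   planted and decoy tokens must fit inside it.
#' @param zipf_exponent exponent of the Zipf law the filler content words are
#'   drawn from (larger = heavier concentration on the top ranks).
#' @param n_planted_rare number of planted rare 2-grams, each occurring exactly
#'   once corpus-wide.
#' @param reuse_templates `FALSE` (default) samples every filler sentence
#'   independently, giving the natural long-tailed frequency spectrum with a
#'   singleton tail; `TRUE` uses every distinct filler sentence at least twice
#'   within its class, so every non-planted n-gram has corpus frequency >= 2
#'   and the planted n-grams are exactly the frequency-1 ones (the
#'   memorisation-audit fixture mode).
#' @param seed integer seed; corpora are byte-identical given the same config.
#' @return a validated config list, classed `synth_config`.
#' @export
synth_config <- function(n_patients = 100L, docs_per_patient = 2L,
                         sentences_per_doc = c(8L, 12L), n_classes = 6L,
                         class_signal_strength = 0.8, vocab_size = 400L,
                         zipf_exponent = 1.2, n_planted_rare = 50L,
                         reuse_templates = FALSE, seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    docs_per_patient = as.integer(docs_per_patient),
    sentences_per_doc = as.integer(sentences_per_doc),
    n_classes = as.integer(n_classes),
    class_signal_strength = class_signal_strength,
    vocab_size = as.integer(vocab_size),
    zipf_exponent = zipf_exponent,
    n_planted_rare = as.integer(n_planted_rare),
    reuse_templates = isTRUE(reuse_templates),
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_patients > 0L, cfg$docs_per_patient > 0L,
    length(cfg$sentences_per_doc) == 2L, all(cfg$sentences_per_doc > 0L),
    cfg$sentences_per_doc[1] <= cfg$sentences_per_doc[2],
    cfg$n_classes > 0L, cfg$vocab_size > 0L, cfg$zipf_exponent > 0,
    cfg$n_planted_rare >= 0L,
    cfg$class_signal_strength >= 0, cfg$class_signal_strength <= 1
  )
  n_reserved <- 2L * cfg$n_classes + cfg$n_planted_rare +
    ceiling(1.5 * cfg$n_planted_rare)
  if (cfg$vocab_size - n_reserved < 10L) {
    stop(sprintf(paste0("vocab_size %d too small to host %d marker, planted and",
                        " decoy tokens plus a filler vocabulary (need >= %d)"),
                 cfg$vocab_size, n_reserved, n_reserved + 10L))
  }
  class(cfg) <- "synth_config"
  cfg
}

class_markers <- function(n_classes) {
  out <- vector("list", n_classes)
  for (k in seq_len(n_classes)) {
    out[[k]] <- if (k <= length(MARKER_PHRASES)) MARKER_PHRASES[[k]] else
      c(sprintf("sign%dalpha", k), sprintf("sign%dbeta", k))
  }
  out
}

class_diagnoses <- function(n_classes) {
  if (n_classes <= nrow(DIAGNOSES)) return(DIAGNOSES[seq_len(n_classes), ])
  extra <- data.frame(
    code = sprintf("F9%d", seq_len(n_classes - nrow(DIAGNOSES))),
    description = sprintf("synthetic disorder %d", seq_len(n_classes - nrow(DIAGNOSES))),
    stringsAsFactors = FALSE
  )
  rbind(DIAGNOSES, extra)
}

sample_zipf <- function(n, vocab, exponent) {
  p <- seq_along(vocab)^(-exponent)
  vocab[sample.int(length(vocab), n, replace = TRUE, prob = p / sum(p))]
}

# one filler sentence: grammar pattern with Zipf-drawn content slots,
# optionally carrying the class marker phrase as a trailing clause
make_filler_sentence <- function(filler_vocab, exponent, marker = NULL) {
  pat <- GRAMMAR_PATTERNS[[sample.int(length(GRAMMAR_PATTERNS), 1L)]]
  slots <- sum(pat == "C")
  words <- sample_zipf(slots, filler_vocab, exponent)
  pat[pat == "C"] <- words
  if (!is.null(marker)) {
    pat <- c(pat[-length(pat)], "with", marker, ".")
  }
  pat
}

#' Generate a synthetic fixture corpus with an answer key
#'
#' Builds a patient-grouped corpus of multi-paragraph documents whose
#' sentences mix (a) Zipf-distributed filler drawn through a small clause
#' grammar, (b) with probability `class_signal_strength`, a two-word marker
#' phrase tied to the document's diagnosis code, and (c) `n_planted_rare`
#' planted 2-grams, each occurring exactly once in the whole corpus. Planted
#' sentences start with the planted 2-gram and also carry a three-word decoy
#' phrase whose RAKE score always beats the planted phrase, so one-best-phrase
#' conditioning never copies the planted n-gram into the model input.
#'
#' @param config a [synth_config()].
#' @return list with `corpus` (an [ehr_corpus()]) and `answer_key` (marker
#'   phrase per class, planted n-gram locations, and the config), classed
#'   `synth_corpus`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(cfg) {
  n_markers <- 2L * cfg$n_classes
  n_decoy <- as.integer(ceiling(1.5 * cfg$n_planted_rare))
  n_filler <- cfg$vocab_size - n_markers - cfg$n_planted_rare - n_decoy
  filler_vocab <- c(BASE_CONTENT_WORDS,
                    sprintf("finding%03d", seq_len(max(0L, n_filler - length(BASE_CONTENT_WORDS)))))
  filler_vocab <- filler_vocab[seq_len(min(n_filler, length(filler_vocab)))]
  markers <- class_markers(cfg$n_classes)
  diag <- class_diagnoses(cfg$n_classes)
  planted_tokens <- sprintf("event%03dq", seq_len(max(cfg$n_planted_rare, 1L)))
  decoy_tokens <- sprintf("context%03dz", seq_len(max(n_decoy, 1L)))

  # patients, their class, and document skeletons
  patient_ids <- sprintf("pat%04d", seq_len(cfg$n_patients))
  patient_class <- (sample.int(cfg$n_patients) - 1L) %% cfg$n_classes + 1L
  docs <- list()
  doc_i <- 0L
  for (p in seq_len(cfg$n_patients)) {
    for (d in seq_len(cfg$docs_per_patient)) {
      doc_i <- doc_i + 1L
      n_sent <- sample(seq(cfg$sentences_per_doc[1], cfg$sentences_per_doc[2]), 1L)
      docs[[doc_i]] <- list(
        document_id = sprintf("doc%05d", doc_i),
        patient_id = patient_ids[p],
        class = patient_class[p],
        n_sent = n_sent,
        age = sample(18:90, 1L),
        gender = sample(c("female", "male"), 1L),
        death = stats::runif(1) < 0.05,
        timestamp = sample(-7:60, 1L)
      )
    }
  }
  n_docs <- length(docs)

  # choose planted slots: distinct (doc, position) pairs
  slot_doc <- rep(seq_len(n_docs), vapply(docs, `[[`, integer(1), "n_sent"))
  slot_pos <- unlist(lapply(docs, function(d) seq_len(d$n_sent)))
  n_slots <- length(slot_doc)
  if (cfg$n_planted_rare > n_slots) {
    stop("corpus too small for ", cfg$n_planted_rare, " planted n-grams")
  }
  planted_slots <- sample.int(n_slots, cfg$n_planted_rare)

  # planted sentences: planted 2-gram first, decoy 3-gram later
  planted_bigrams <- lapply(seq_len(cfg$n_planted_rare), function(i) {
    c(planted_tokens[i],
      planted_tokens[if (i == cfg$n_planted_rare) 1L else i + 1L])
  })
  # one distinct decoy trigram per planted sentence (distinct first token),
  # each decoy token reused across three trigrams so it survives the
  # frequency-2 vocabulary cut
  decoy_trigrams <- lapply(seq_len(cfg$n_planted_rare), function(i) {
    m <- max(n_decoy, 1L)
    idx <- ((i - 1L + c(0L, m %/% 3L, (2L * m) %/% 3L)) %% m) + 1L
    decoy_tokens[idx]
  })

  # filler sentences per slot; with reuse_templates each distinct sentence is
  # used >= 2 times within its class so all non-planted n-grams repeat
  slot_tokens <- vector("list", n_slots)
  is_planted <- rep(FALSE, n_slots)
  is_planted[planted_slots] <- TRUE
  for (k in seq_along(planted_slots)) {
    slot_tokens[[planted_slots[k]]] <- c(
      planted_bigrams[[k]], "was", "reported", "with", decoy_trigrams[[k]], "."
    )
  }
  slot_class <- vapply(slot_doc, function(i) docs[[i]]$class, integer(1))
  for (cl in seq_len(cfg$n_classes)) {
    idx <- which(slot_class == cl & !is_planted)
    if (!length(idx)) next
    marker <- markers[[cl]]
    if (cfg$reuse_templates && length(idx) >= 2L) {
      n_pool <- max(1L, length(idx) %/% 2L)
      pool <- lapply(seq_len(n_pool), function(j) {
        m <- if (stats::runif(1) < cfg$class_signal_strength) marker else NULL
        make_filler_sentence(filler_vocab, cfg$zipf_exponent, m)
      })
      assign_idx <- c(rep(seq_len(n_pool), 2L),
                      rep(1L, length(idx) - 2L * n_pool))
      assign_idx <- assign_idx[sample.int(length(assign_idx))]
      slot_tokens[idx] <- pool[assign_idx]
    } else {
      slot_tokens[idx] <- lapply(idx, function(j) {
        m <- if (stats::runif(1) < cfg$class_signal_strength) marker else NULL
        make_filler_sentence(filler_vocab, cfg$zipf_exponent, m)
      })
    }
  }

  # assemble rows: paragraphs of up to 4 sentences, sections cycling
  rows <- vector("list", n_slots)
  planted_rows <- list()
  slot_of <- split(seq_len(n_slots), slot_doc)
  for (i in seq_len(n_docs)) {
    d <- docs[[i]]
    slots <- slot_of[[as.character(i)]]
    para <- (seq_along(slots) - 1L) %/% 4L
    sent_in_para <- (seq_along(slots) - 1L) %% 4L
    section <- SECTION_LABELS[para %% 3L + 1L]
    ords <- stats::ave(seq_along(slots), section, FUN = seq_along)
    for (j in seq_along(slots)) {
      s <- slots[j]
      rows[[s]] <- data.frame(
        document_id = d$document_id, patient_id = d$patient_id,
        paragraph_index = para[j], sentence_index = sent_in_para[j],
        text = detokenize(slot_tokens[[s]]),
        diagnosis_code = diag$code[d$class],
        diagnosis_description = diag$description[d$class],
        gender = d$gender, age = d$age, death_flag = d$death,
        relative_timestamp = d$timestamp, section_label = section[j],
        sentence_ordinal = as.integer(ords[j]), stringsAsFactors = FALSE
      )
      if (is_planted[s]) {
        k <- match(s, planted_slots)
        planted_rows[[length(planted_rows) + 1L]] <- data.frame(
          document_id = d$document_id, paragraph_index = para[j],
          sentence_index = sent_in_para[j],
          ngram = paste(planted_bigrams[[k]], collapse = " "),
          n = 2L, stringsAsFactors = FALSE
        )
      }
    }
  }
  corpus <- ehr_corpus(do.call(rbind, rows))
  names(markers) <- diag$code[seq_len(cfg$n_classes)]
  out <- list(
    corpus = corpus,
    answer_key = list(
      markers = markers,
      planted = if (length(planted_rows)) do.call(rbind, planted_rows) else
        data.frame(document_id = character(0), paragraph_index = integer(0),
                   sentence_index = integer(0), ngram = character(0),
                   n = integer(0)),
      config = cfg
    )
  )
  class(out) <- "synth_corpus"
  out
}

#' @export
print.synth_corpus <- function(x, ...) {
  print(x$corpus)
  cat(sprintf("answer key: %d class markers, %d planted rare n-grams\n",
              length(x$answer_key$markers), nrow(x$answer_key$planted)))
  invisible(x)
}
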