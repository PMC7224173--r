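# Intrinsic text-preservation metrics: ROUGE-L recall, corpus BLEU,
# translation edit rate with greedy shift search, sentence lengths, and the
# TER-bin cumulative distribution.

# map two token vectors onto shared integer codes for the C++ kernels
codes2 <- function(a, b) {
  lev <- unique(c(a, b))
  list(a = match(a, lev), b = match(b, lev))
}

#' ROUGE-L recall
#'
#' Longest-common-subsequence recall of the reference within the hypothesis:
#' `LCS(hypothesis, reference) / length(reference)`.
#'
#' @param hypothesis,reference token vectors; the reference must be non-empty.
#' @return a number in `[0, 1]`; 1 exactly when the reference is a
#'   subsequence of the hypothesis.
#' @export
rouge_l <- function(hypothesis, reference) {
  if (length(reference) == 0L) stop("reference must be non-empty")
  if (length(hypothesis) == 0L) return(0)
  cd <- codes2(hypothesis, reference)
  cpp_lcs(cd$a, cd$b) / length(reference)
}

ngrams_of <- function(tokens, n) {
  L <- length(tokens)
  if (L < n) return(character(0))
  if (n == 1L) return(tokens)
  vapply(seq_len(L - n + 1L), function(i) {
    paste(tokens[i:(i + n - 1L)], collapse = "\x01")
  }, character(1))
}

#' Corpus BLEU
#'
#' Geometric mean of clipped n-gram precisions for `n = 1..max_n`, aggregated
#' over the whole corpus, times the brevity penalty
#' `exp(min(0, 1 - ref_len/hyp_len))`, on the 0-100 scale. No smoothing: any
#' zero modified precision yields a score of 0.
#'
#' @param hypotheses,references aligned non-empty lists of token vectors.
#' @param max_n largest n-gram order (default 4).
#' @return a number in `[0, 100]`.
#' @export
bleu <- function(hypotheses, references, max_n = 4L) {
  if (length(hypotheses) == 0L) stop("empty hypothesis set")
  if (length(hypotheses) != length(references)) {
    stop("hypotheses and references are misaligned: ", length(hypotheses),
         " vs ", length(references))
  }
  hyp_len <- sum(lengths(hypotheses))
  ref_len <- sum(lengths(references))
  if (hyp_len == 0L) return(0)
  log_p <- numeric(0)
  for (n in seq_len(max_n)) {
    clipped <- 0L
    total <- 0L
    for (i in seq_along(hypotheses)) {
      hg <- ngrams_of(hypotheses[[i]], n)
      total <- total + length(hg)
      if (!length(hg)) next
      rg <- table(ngrams_of(references[[i]], n))
      ht <- table(hg)
      common <- intersect(names(ht), names(rg))
      clipped <- clipped + sum(pmin(ht[common], rg[common]))
    }
    if (total == 0L) break  # no hypothesis n-grams of this order exist
    if (clipped == 0L) return(0)
    log_p <- c(log_p, log(clipped / total))
  }
  if (!length(log_p)) return(0)
  bp <- exp(min(0, 1 - ref_len / hyp_len))
  100 * bp * exp(mean(log_p))
}

#' Translation edit rate
#'
#' Minimum number of substitutions, insertions, deletions and word-span
#' shifts (each shift moves one contiguous hypothesis span and costs 1)
#' turning the hypothesis into the reference, divided by the reference
#' length. For short hypotheses (up to 8 tokens) the shift search is exact
#' (bounded-depth enumeration of shift sequences); beyond that it is the
#' standard greedy procedure - repeatedly apply the single shift that most
#' reduces the remaining edit distance, stopping when none helps. Both
#' guarantee `ter <= levenshtein / length(reference)`.
#'
#' @param hypothesis,reference token vectors; the reference must be non-empty.
#' @return a non-negative number (0 exactly when the sequences are equal).
#' @export
ter <- function(hypothesis, reference) {
  if (length(reference) == 0L) stop("reference must be non-empty")
  if (identical(hypothesis, reference)) return(0)
  if (length(hypothesis) == 0L) return(1)
  cd <- codes2(hypothesis, reference)
  cpp_ter(cd$a, cd$b)$total / length(reference)
}

#' Corpus-level intrinsic metric report
#'
#' Compares a generated corpus against its sentence-aligned genuine source:
#' ROUGE-L and TER averaged over sentences, corpus-level BLEU, mean generated
#' sentence length, and the per-sentence TER vector for CDF plotting.
#'
#' @param generated,genuine sentence-aligned [ehr_corpus()] objects (same
#'   documents, paragraphs and sentence positions, in the same order).
#' @param model_ppl optional perplexity to carry in the report.
#' @return list classed `metric_report` with `rouge_l`, `bleu`, `ter`,
#'   `mean_sentence_length`, `ppl`, `n_sentences`, `per_sentence_ter`.
#' @export
evaluate_corpus <- function(generated, genuine, model_ppl = NULL) {
  if (nrow(generated) != nrow(genuine)) {
    stop("corpora are not aligned: ", nrow(generated), " vs ", nrow(genuine),
         " sentences")
  }
  key_gen <- paste(generated$document_id, generated$paragraph_index,
                   generated$sentence_index)
  key_ref <- paste(genuine$document_id, genuine$paragraph_index,
                   genuine$sentence_index)
  if (!identical(key_gen, key_ref)) {
    i <- which(key_gen != key_ref)[1]
    stop("alignment mismatch at document ", genuine$document_id[i])
  }
  hyp <- lapply(generated$text, tokenize_one)
  ref <- lapply(genuine$text, tokenize_one)
  nonempty <- lengths(ref) > 0L
  rl <- mapply(rouge_l, hyp[nonempty], ref[nonempty])
  tr <- mapply(ter, hyp[nonempty], ref[nonempty])
  report <- list(
    rouge_l = mean(rl),
    bleu = bleu(hyp[nonempty], ref[nonempty]),
    ter = mean(tr),
    mean_sentence_length = mean(lengths(hyp)),
    ppl = if (is.null(model_ppl)) NA_real_ else model_ppl,
    n_sentences = sum(nonempty),
    per_sentence_ter = as.numeric(tr)
  )
  class(report) <- "metric_report"
  report
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("ROUGE-L %.3f  BLEU %.2f  TER %.3f  mean length %.2f",
              x$rouge_l, x$bleu, x$ter, x$mean_sentence_length))
  if (!is.na(x$ppl)) cat(sprintf("  PPL %.2f", x$ppl))
  cat(sprintf("  (%d sentences)\n", x$n_sentences))
  invisible(x)
}

#' Cumulative distribution of TER bins
#'
#' Right-closed bins of width `bin_width` starting at 0; the cumulative
#' fraction of sentences with TER at or below each bin edge. Values above 1
#' are pooled into a final overflow bin, so the last cumulative value is 1.
#'
#' @param per_sentence_ter non-empty numeric vector of per-sentence TER.
#' @param bin_width positive bin width (default 0.1).
#' @return list classed `ter_cdf` with `edges` (last edge `Inf`) and
#'   `cumulative`.
#' @export
ter_cdf <- function(per_sentence_ter, bin_width = 0.1) {
  if (!length(per_sentence_ter)) stop("no TER values")
  if (bin_width <= 0) stop("bin_width must be positive")
  edges <- seq(bin_width, 1, by = bin_width)
  if (max(edges) < 1) edges <- c(edges, 1)
  cum <- vapply(edges, function(e) mean(per_sentence_ter <= e + 1e-12),
                numeric(1))
  out <- list(edges = c(edges, Inf), cumulative = c(cum, 1))
  class(out) <- "ter_cdf"
  out
}

#' @export
plot.ter_cdf <- function(x, ...) {
  edges <- x$edges
  edges[is.infinite(edges)] <- max(edges[is.finite(edges)]) +
    diff(edges[1:2])
  graphics::plot(edges, x$cumulative, type = "s", ylim = c(0, 1),
                 xlab = "TER bin", ylab = "cumulative frequency", ...)
  invisible(x)
}

#' Write a metric report as flat key-value text
#'
#' Emits `<stem>.metrics.txt` (one `key<TAB>value` per line) and
#' `<stem>.ter.txt` (one per-sentence TER value per line).
#'
#' @param report a `metric_report`.
#' @param stem output path stem.
#' @export
write_metric_report <- function(report, stem) {
  kv <- c(rouge_l = report$rouge_l, bleu = report$bleu, ter = report$ter,
          mean_sentence_length = report$mean_sentence_length,
          ppl = report$ppl, n_sentences = report$n_sentences)
  writeLines(sprintf("%s\t%.10g", names(kv), kv), paste0(stem, ".metrics.txt"))
  writeLines(sprintf("%.10g", report$per_sentence_ter), paste0(stem, ".ter.txt"))
  invisible(stem)
}
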