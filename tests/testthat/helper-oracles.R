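# Independent oracles, kept deliberately naive: they re-derive every quantity
# from first principles (exhaustive enumeration, explicit loops) and never
# call the code paths they check.

# Levenshtein distance by the textbook DP, in plain R
r_lev <- function(a, b) {
  n <- length(a); m <- length(b)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1L] <- 0:n
  d[1L, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L, d[i + 1L, j] + 1L,
                               d[i, j] + (a[i] != b[j]))
    }
  }
  d[n + 1L, m + 1L]
}

# LCS length by exhaustive subsequence enumeration (only for short sequences)
oracle_lcs <- function(a, b) {
  n <- length(a)
  if (n == 0L) return(0L)
  best <- 0L
  is_subseq <- function(x, y) {
    j <- 1L
    for (t in y) {
      if (j <= length(x) && x[j] == t) j <- j + 1L
    }
    j > length(x)
  }
  for (mask in 0:(2^n - 1L)) {
    sel <- a[bitwAnd(bitwShiftR(mask, 0:(n - 1L)), 1L) == 1L]
    if (length(sel) > best && is_subseq(sel, b)) best <- length(sel)
  }
  best
}

# exact TER numerator by exhaustive search over shift sequences (bounded
# depth-first with pruning; feasible for sequences of length <= 6)
oracle_ter_edits <- function(hyp, ref) {
  best <- r_lev(hyp, ref)
  seen <- new.env(parent = emptyenv())
  recurse <- function(h, nshift) {
    if (nshift + 1L >= best) return(invisible())  # a further shift cannot win
    L <- length(h)
    if (L < 2L) return(invisible())
    for (i in seq_len(L)) {
      for (len in seq_len(L - i + 1L)) {
        rest_len <- L - len
        for (k in 0:rest_len) {
          rest <- h[-(i:(i + len - 1L))]
          h2 <- append(rest, h[i:(i + len - 1L)], after = k)
          if (identical(h2, h)) next
          key <- paste(c(nshift + 1L, h2), collapse = "\x01")
          if (!is.null(seen[[key]])) next
          seen[[key]] <- TRUE
          tot <- nshift + 1L + r_lev(h2, ref)
          if (tot < best) best <<- tot
          recurse(h2, nshift + 1L)
        }
      }
    }
  }
  recurse(hyp, 0L)
  best
}

# RAKE deg/freq scoring re-derived with explicit loops over candidate runs
oracle_rake <- function(paragraph, stopwords) {
  cands <- list()
  for (si in seq_along(paragraph)) {
    toks <- paragraph[[si]]
    run <- character(0)
    flush <- function() {
      if (length(run)) cands[[length(cands) + 1L]] <<- run
      run <<- character(0)
    }
    for (t in toks) {
      if (t %in% stopwords || grepl("^[[:punct:]]+$", t)) flush() else run <- c(run, t)
    }
    flush()
  }
  if (!length(cands)) return(numeric(0))
  words <- unique(unlist(cands))
  freq <- sapply(words, function(w) sum(sapply(cands, function(c) sum(c == w))))
  deg <- sapply(words, function(w) {
    sum(sapply(cands, function(c) if (w %in% c) length(c) * sum(c == w) else 0L))
  })
  score <- deg / freq
  stats::setNames(
    vapply(cands, function(c) sum(score[c]), numeric(1)),
    vapply(cands, paste, character(1), collapse = " ")
  )
}

# brute-force two-sample KS D: evaluate both ECDFs at every pooled point
oracle_ks_d <- function(a, b) {
  pts <- c(a, b)
  max(vapply(pts, function(x) abs(mean(a <= x) - mean(b <= x)), numeric(1)))
}
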