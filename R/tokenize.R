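#' Tokenise a string
#'
#' Deterministic whitespace tokeniser used throughout the package: the text is
#' lowercased, split on whitespace, and leading/trailing punctuation characters
#' are detached as standalone single-character tokens. Internal punctuation
#' (e.g. hyphens inside a word) is left in place, so the rule is idempotent:
#' re-tokenising the space-joined token sequence reproduces it.
#'
#' @param text character vector (each element tokenised independently when
#'   length > 1; a single string returns a character vector of tokens).
#' @return for a single string, a character vector of tokens (length 0 for
#'   empty input); for a character vector, a list of such vectors.
#' @examples
#' tokenize("He has no allergies.")
#' tokenize("F20, schizophrenia")
#' @export
tokenize <- function(text) {
  if (length(text) == 1L) return(tokenize_one(text))
  lapply(text, tokenize_one)
}

tokenize_one <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(character(0))
  words <- strsplit(trimws(tolower(text)), "[[:space:]]+")[[1]]
  out <- character(0)
  for (w in words) out <- c(out, split_punct(w))
  out
}

# detach leading/trailing punctuation as single-character tokens
split_punct <- function(w) {
  pre <- character(0); post <- character(0)
  while (nchar(w) > 1L && grepl("^[[:punct:]]", w)) {
    pre <- c(pre, substr(w, 1L, 1L)); w <- substr(w, 2L, nchar(w))
  }
  while (nchar(w) > 1L && grepl("[[:punct:]]$", w)) {
    post <- c(substr(w, nchar(w), nchar(w)), post); w <- substr(w, 1L, nchar(w) - 1L)
  }
  c(pre, w, post)
}

#' @rdname tokenize
#' @param tokens character vector of tokens.
#' @export
detokenize <- function(tokens) paste(tokens, collapse = " ")

is_punct_token <- function(tok) grepl("^[[:punct:]]+$", tok)

is_numeric_token <- function(tok) grepl("^[0-9]+([.,][0-9]+)*$", tok)
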