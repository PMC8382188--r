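#' Tokenization settings
#'
#' Settings controlling how free text is split into words and k-mers.
#' Words are separated on whitespace; leading and trailing punctuation is
#' stripped so that gene symbols and ontology identifiers (internal
#' punctuation, e.g. "MP:0001262") survive intact.
#'
#' @param k integer k-mer length (>= 1). Words of length <= k pass through
#'   whole; longer words are split into all overlapping substrings of
#'   length k.
#' @param case_fold lowercase all text before tokenization?
#'
#' @return an object of class \code{token_settings}.
#' @examples
#' kmerize("vascular", token_settings(k = 6))
#' @export
token_settings <- function(k = 6L, case_fold = TRUE) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L)
    stop("k must be an integer >= 1")
  structure(list(k = k, case_fold = isTRUE(case_fold)),
            class = "token_settings")
}

#' @exportS3Method base::print
print.token_settings <- function(x, ...) {
  cat("token settings: k =", x$k,
      if (x$case_fold) "(case-folded)" else "(case-sensitive)", "\n")
  invisible(x)
}

#' Split text into words
#'
#' @param text character scalar (or vector, concatenated).
#' @param settings a \code{\link{token_settings}} object.
#' @return character vector of words; zero-length for empty text.
#' @export
tokenize <- function(text, settings = token_settings()) {
  text <- paste(text, collapse = " ")
  if (settings$case_fold)
    text <- tolower(text)
  words <- strsplit(text, "[[:space:]]+")[[1]]
  words <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", words)
  words[nzchar(words)]
}

#' Split a word into overlapping k-mers
#'
#' A word of length L > k yields its L - k + 1 overlapping substrings of
#' length k, in order; shorter words pass through whole.
#'
#' @param word character scalar, non-empty.
#' @param settings a \code{\link{token_settings}} object.
#' @return character vector of k-mers (empty for an empty word).
#' @examples
#' kmerize("vascular", token_settings(k = 6)) # "vascul" "ascula" "scular"
#' @export
kmerize <- function(word, settings = token_settings()) {
  n <- nchar(word)
  if (length(word) != 1L)
    stop("kmerize() expects a single word; see kmerize_words()")
  if (is.na(n) || n == 0L)
    return(character(0))
  k <- settings$k
  if (n <= k)
    return(word)
  substring(word, 1:(n - k + 1L), k:n)
}

#' k-merize a vector of words
#'
#' @param words character vector.
#' @param settings a \code{\link{token_settings}} object.
#' @return list of character vectors, one per word.
#' @export
kmerize_words <- function(words, settings = token_settings()) {
  lapply(words, kmerize, settings = settings)
}
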