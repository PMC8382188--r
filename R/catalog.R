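#' Scan a corpus and build a feature catalog
#'
#' First pass over a document collection: tallies, for every k-mer, the
#' number of documents containing it, and assigns each retained k-mer an
#' integer column. Feature importance follows
#' \deqn{w = c_0 - c_1 \log_{10}(n / N)}
#' where \eqn{n} is the number of documents containing the k-mer and
#' \eqn{N} the total number of documents. \code{c1 = 0} treats all features
#' equally (suited to unweighted gene sets); \code{c0 = 0} gives pure
#' information-content (inverse document frequency) weighting, which
#' down-weights ubiquitous words in natural-language text. Negative values
#' of the formula are clipped at zero: a common feature can become
#' uninformative, but never carries negative importance.
#'
#' @param texts character vector of documents (at least one non-empty).
#' @param settings a \code{\link{token_settings}} object.
#' @param c0,c1 weighting constants (both >= 0).
#' @param max_features cap on catalog size; if the corpus has more distinct
#'   k-mers, the most document-frequent are retained (ties broken
#'   lexicographically, so the catalog is deterministic).
#'
#' @return an object of class \code{feature_catalog} with elements
#'   \code{index} (named integer vector k-mer -> column), \code{doc_count},
#'   \code{n_docs}, \code{weights}, \code{c0}, \code{c1}, \code{settings}.
#' @export
scan_corpus <- function(texts, settings = token_settings(),
                        c0 = 0, c1 = 1, max_features = 200000L) {
  if (length(texts) == 0L)
    stop("empty corpus: nothing to index")
  per_doc <- lapply(texts, function(txt) {
    unique(unlist(kmerize_words(tokenize(txt, settings), settings),
                  use.names = FALSE))
  })
  all_feats <- unlist(per_doc, use.names = FALSE)
  if (length(all_feats) == 0L)
    stop("empty corpus: no features found in any document")
  counts <- table(all_feats)
  feats <- names(counts)
  n <- as.integer(counts)
  if (length(feats) > max_features) {
    keep <- order(-n, feats)[seq_len(max_features)]
    feats <- feats[keep]
    n <- n[keep]
  }
  ord <- order(feats)
  feats <- feats[ord]
  n <- n[ord]
  N <- length(texts)
  w <- pmax(0, c0 - c1 * log10(n / N))
  index <- seq_along(feats)
  names(index) <- feats
  structure(list(index = index, doc_count = n, n_docs = N,
                 weights = w, c0 = c0, c1 = c1,
                 max_features = as.integer(max_features),
                 settings = settings),
            class = "feature_catalog")
}

#' @exportS3Method base::print
print.feature_catalog <- function(x, ...) {
  cat("feature catalog:", length(x$index), "k-mers over", x$n_docs,
      "documents (k =", x$settings$k,
      paste0(", c0 = ", x$c0, ", c1 = ", x$c1, ")"), "\n")
  invisible(x)
}

#' Feature weights of a catalog
#'
#' @param catalog a \code{feature_catalog}.
#' @param features optional character vector of k-mers; unknown k-mers get NA.
#' @return named numeric vector of weights.
#' @export
feature_weights <- function(catalog, features = NULL) {
  w <- catalog$weights
  names(w) <- names(catalog$index)
  if (is.null(features)) w else w[features]
}

#' Number of features in a catalog
#' @param catalog a \code{feature_catalog}.
#' @return integer.
#' @export
n_features <- function(catalog) length(catalog$index)
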