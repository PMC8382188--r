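# Sparse encoded vectors: indices strictly increasing, values numeric.
# Values may be negative (user annotations, diffusion); stored documents
# are unit-norm, raw queries need not be.

new_encoded <- function(indices, values, n_features) {
  stopifnot(length(indices) == length(values))
  if (is.unsorted(indices, strictly = TRUE)) {
    ord <- order(indices)
    indices <- indices[ord]
    values <- values[ord]
  }
  structure(list(indices = as.integer(indices), values = as.numeric(values),
                 n_features = as.integer(n_features)),
            class = "encoded_vector")
}

#' Empty encoded vector
#' @param n_features dimension of the feature space.
#' @return an \code{encoded_vector} with no nonzero entries.
#' @export
empty_encoded <- function(n_features) {
  new_encoded(integer(0), numeric(0), n_features)
}

#' @exportS3Method base::print
print.encoded_vector <- function(x, ...) {
  cat("encoded vector:", length(x$indices), "of", x$n_features,
      "features, L2 norm", format(ev_norm(x), digits = 6), "\n")
  invisible(x)
}

#' Number of nonzero entries of an encoded vector
#' @param v an \code{encoded_vector}.
#' @return integer.
#' @export
ev_nnz <- function(v) length(v$indices)

#' L2 norm of an encoded vector
#' @param v an \code{encoded_vector}.
#' @return numeric scalar.
#' @export
ev_norm <- function(v) sqrt(sum(v$values^2))

ev_scale <- function(v, a) new_encoded(v$indices, v$values * a, v$n_features)

ev_normalize <- function(v) {
  nrm <- ev_norm(v)
  if (nrm == 0) v else ev_scale(v, 1 / nrm)
}

# sparse addition a + b
ev_add <- function(a, b) {
  stopifnot(a$n_features == b$n_features)
  idx <- c(a$indices, b$indices)
  val <- c(a$values, b$values)
  agg <- rowsum(val, idx)
  keep <- agg[, 1] != 0
  new_encoded(as.integer(rownames(agg))[keep], agg[keep, 1], a$n_features)
}

ev_dot <- function(a, b) {
  m <- match(a$indices, b$indices)
  ok <- !is.na(m)
  sum(a$values[ok] * b$values[m[ok]])
}

#' Convert an encoded vector to a Matrix sparse vector
#' @param v an \code{encoded_vector}.
#' @return a \code{Matrix::sparseVector}.
#' @export
as_sparse_vector <- function(v) {
  Matrix::sparseVector(x = v$values, i = v$indices, length = v$n_features)
}

#' Convert an encoded vector to a dense numeric vector
#'
#' Registered for \code{as.double}, so \code{as.numeric(v)} also works.
#'
#' @param x an \code{encoded_vector}.
#' @param ... unused.
#' @return numeric vector of length \code{n_features}.
#' @exportS3Method base::as.double
as.double.encoded_vector <- function(x, ...) {
  out <- numeric(x$n_features)
  out[x$indices] <- x$values
  out
}

#' Encode text as a weighted sparse k-mer vector
#'
#' Tokenizes the text, k-merizes every word and accumulates feature values.
#' A word occurring m times in the item contributes with a sublinear term
#' 1 + log(m) (natural log), multiplied by the catalog weight of each of
#' its k-mers. K-mers of a word longer than k are additionally scaled by
#' k / L (L = word length), so that a long word carries roughly the same
#' total mass as a short one despite its overlapping k-mers sharing
#' content. K-mers absent from the catalog are dropped.
#'
#' @param text character scalar.
#' @param catalog a \code{\link{scan_corpus}} catalog.
#' @param normalize scale the result to unit L2 norm? (Stored documents are
#'   always normalized; raw queries may be encoded with
#'   \code{normalize = FALSE}.)
#' @return an \code{encoded_vector}; empty if no catalogued feature occurs.
#' @export
encode <- function(text, catalog, normalize = TRUE) {
  settings <- catalog$settings
  words <- tokenize(text, settings)
  if (length(words) == 0L)
    return(empty_encoded(n_features(catalog)))
  counts <- table(words)
  k <- settings$k
  idx_all <- integer(0)
  val_all <- numeric(0)
  for (i in seq_along(counts)) {
    w <- names(counts)[i]
    tf <- 1 + log(as.integer(counts[i]))
    kmers <- kmerize(w, settings)
    L <- nchar(w)
    adj <- if (L > k) k / L else 1
    cols <- catalog$index[kmers]
    ok <- !is.na(cols)
    if (!any(ok)) next
    cols <- cols[ok]
    vals <- tf * adj * catalog$weights[cols]
    idx_all <- c(idx_all, cols)
    val_all <- c(val_all, vals)
  }
  if (length(idx_all) == 0L)
    return(empty_encoded(n_features(catalog)))
  agg <- rowsum(val_all, idx_all)
  keep <- agg[, 1] != 0
  v <- new_encoded(as.integer(rownames(agg))[keep], agg[keep, 1],
                   n_features(catalog))
  if (normalize) ev_normalize(v) else v
}
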