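#' Free-text search against a knowledge base
#'
#' Encodes the query text, optionally applies the diffusion transform
#' (then re-normalizes so cosine ranking against unit-norm stored items is
#' scale-consistent), and performs an exact nearest-neighbor lookup in one
#' collection.
#'
#' @param kb a \code{knowledge_base}.
#' @param text query text.
#' @param collection collection to search.
#' @param n number of hits (default 5).
#' @param diffusion optional named strengths for \code{\link{diffuse}}.
#' @return data.frame of hits (rank, id, title, similarity).
#' @export
kb_search <- function(kb, text, collection, n = 5L, diffusion = NULL) {
  q <- encode(text, kb$catalog, normalize = FALSE)
  if (!is.null(diffusion))
    q <- diffuse(q, kb, diffusion)
  kb_nearest(kb, q, collection, n = n)
}

#' Greedy decomposition of a query into stored items
#'
#' Explains a query as a positive linear combination of a small number of
#' distinct stored items. The greedy loop: (1) find the item most similar
#' to the current residual; (2) refit the coefficients of all selected
#' items against the original query by unconstrained least squares;
#' (3) recompute the residual. It stops when the requested number of
#' components is reached, when a coefficient would become non-positive,
#' or when the residual norm falls below \code{tol} times the query norm.
#' The residual norm is non-increasing across iterations, and no item is
#' ever selected twice. The result is greedy, not a globally optimal
#' sparse decomposition.
#'
#' With \code{refit = FALSE} earlier coefficients are frozen and each new
#' coefficient is the plain projection of the current residual on the new
#' item (matching-pursuit style).
#'
#' Diffusion, when requested, is applied once to the initial query (and
#' the result re-normalized), never to residuals, in keeping with 1-step
#' diffusion semantics.
#'
#' @param kb a \code{knowledge_base}.
#' @param text query text.
#' @param collection collection to decompose against.
#' @param max_components maximum number of components (>= 1).
#' @param diffusion optional named strengths for \code{\link{diffuse}}.
#' @param refit refit all coefficients each iteration (default) or freeze
#'   earlier ones?
#' @param tol relative residual tolerance.
#' @return an object of class \code{kb_decomposition}: list with
#'   \code{components} (data.frame rank, id, title, coefficient),
#'   \code{residual_norm}, and \code{residual_trace} (norm after each
#'   accepted component).
#' @export
kb_decompose <- function(kb, text, collection, max_components = 5L,
                         diffusion = NULL, refit = TRUE, tol = 1e-6) {
  cc <- kb$collections[[collection]]
  if (is.null(cc))
    stop("no collection named '", collection, "'")
  if (max_components < 1L)
    stop("max_components must be >= 1")
  q <- encode(text, kb$catalog, normalize = FALSE)
  if (!is.null(diffusion))
    q <- diffuse(q, kb, diffusion)
  q <- ev_normalize(q)
  empty <- structure(
    list(components = data.frame(rank = integer(0), id = character(0),
                                 title = character(0),
                                 coefficient = numeric(0),
                                 stringsAsFactors = FALSE),
         residual_norm = ev_norm(q), residual_trace = numeric(0)),
    class = "kb_decomposition")
  if (length(q$indices) == 0L) {
    warning("empty query vector: empty decomposition")
    return(empty)
  }
  V <- cc$vectors
  ids <- cc$items$id
  qmat <- methods::as(as_sparse_vector(q), "CsparseMatrix")
  qnorm <- ev_norm(q)
  r <- qmat
  sel <- integer(0)
  coefs <- numeric(0)
  trace <- numeric(0)
  while (length(sel) < max_components) {
    sims <- as.numeric(Matrix::crossprod(V, r))
    if (length(sel))
      sims[sel] <- -Inf
    best <- order(-sims, ids)[1L]
    if (!is.finite(sims[best]) || sims[best] <= 0)
      break
    cand <- c(sel, best)
    B <- V[, cand, drop = FALSE]
    if (refit) {
      G <- as.matrix(Matrix::crossprod(B))
      rhs <- as.numeric(Matrix::crossprod(B, qmat))
      new_coefs <- tryCatch(solve(G, rhs), error = function(e) NULL)
      if (is.null(new_coefs))
        break
    } else {
      new_coefs <- c(coefs, sims[best])
    }
    if (any(new_coefs <= 0))
      break
    sel <- cand
    coefs <- new_coefs
    r <- qmat - B %*% coefs
    trace <- c(trace, sqrt(sum(r@x^2)))
    if (trace[length(trace)] < tol * qnorm)
      break
  }
  structure(
    list(components = data.frame(rank = seq_along(sel), id = ids[sel],
                                 title = cc$items$title[sel],
                                 coefficient = coefs,
                                 stringsAsFactors = FALSE),
         residual_norm = if (length(trace)) trace[length(trace)] else qnorm,
         residual_trace = trace),
    class = "kb_decomposition")
}

#' @exportS3Method base::print
print.kb_decomposition <- function(x, ...) {
  cat("decomposition:", nrow(x$components), "component(s), residual norm",
      format(x$residual_norm, digits = 6), "\n")
  if (nrow(x$components))
    print(x$components, row.names = FALSE)
  invisible(x)
}
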