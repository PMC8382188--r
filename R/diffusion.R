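#' Diffusion row for a single feature
#'
#' The diffusion matrix for a collection is defined entry-wise as
#' \deqn{D_{ij} = \hat c_{ij} \, \frac{2 w_i w_j}{w_i + w_j}}
#' where \eqn{\hat c_{ij} = c_{ij} / c_{ii}} is the row-normalized
#' co-occurrence (unit diagonal) and the second factor is the harmonic
#' mean of the two feature weights. The harmonic mean makes informative
#' k-mers participate more in diffusion and prevents weight from flowing
#' into uninformative k-mers (a zero-weight partner yields zero transfer).
#' A feature never seen in the collection (\eqn{c_{ii} = 0}) has an empty
#' row.
#'
#' @param kb a \code{knowledge_base}.
#' @param collection collection whose co-occurrence drives the row.
#' @param feature a k-mer string or integer feature index.
#' @return an \code{encoded_vector} holding the sparse row D_i.
#' @export
diffusion_row <- function(kb, collection, feature) {
  cc <- kb$collections[[collection]]
  if (is.null(cc))
    stop("no collection named '", collection, "'")
  i <- if (is.character(feature)) kb$catalog$index[[feature]] else
    as.integer(feature)
  if (is.null(i) || is.na(i) || i < 1L || i > n_features(kb$catalog))
    stop("unknown feature")
  C <- cc$cooc
  cii <- C[i, i]
  if (cii == 0)
    return(empty_encoded(n_features(kb$catalog)))
  row <- C[i, ]
  j <- which(row != 0)
  chat <- row[j] / cii
  w <- kb$catalog$weights
  denom <- w[i] + w[j]
  harm <- ifelse(denom > 0, 2 * w[i] * w[j] / denom, 0)
  vals <- chat * harm
  keep <- vals != 0
  new_encoded(j[keep], vals[keep], n_features(kb$catalog))
}

# s * D %*% q restricted to sources in q's own support, for one collection
diffuse_one <- function(kb, collection, q, s) {
  cc <- kb$collections[[collection]]
  C <- cc$cooc
  idx <- q$indices
  qv <- q$values
  cii <- C[cbind(idx, idx)]
  live <- cii > 0
  if (!any(live))
    return(empty_encoded(q$n_features))
  idx <- idx[live]
  qv <- qv[live]
  cii <- cii[live]
  R <- methods::as(C[idx, , drop = FALSE], "TsparseMatrix")
  r <- R@i + 1L        # local source row
  j <- R@j + 1L        # target feature
  w <- kb$catalog$weights
  wi <- w[idx[r]]
  wj <- w[j]
  denom <- wi + wj
  harm <- ifelse(denom > 0, 2 * wi * wj / denom, 0)
  vals <- (R@x / cii[r]) * qv[r] * harm
  agg <- rowsum(vals, j)
  keep <- agg[, 1] != 0
  if (!any(keep))
    return(empty_encoded(q$n_features))
  ev_scale(new_encoded(as.integer(rownames(agg))[keep], agg[keep, 1],
                       q$n_features), s)
}

check_strengths <- function(kb, strengths) {
  if (length(strengths) == 0L)
    return(numeric(0))
  if (is.null(names(strengths)) || any(!nzchar(names(strengths))))
    stop("diffusion strengths must be a named vector/list")
  strengths <- unlist(strengths)
  unknown <- setdiff(names(strengths), names(kb$collections))
  if (length(unknown))
    stop("unknown collection(s) in diffusion strengths: ",
         paste(unknown, collapse = ", "))
  if (any(strengths < 0))
    stop("diffusion strengths must be >= 0")
  strengths
}

#' Apply the diffusion transform to a query vector
#'
#' Computes \eqn{q \to q + \sum_d s_d D_d q'} over the named collections,
#' where \eqn{q'} is the restriction of the transform to sources present
#' in the \emph{original} query: imputation happens in a first pass from
#' the original support only, and the imputed contributions are summed
#' into the query in a second pass. Features imputed from one collection
#' therefore never source diffusion from another (1-step diffusion), which
#' keeps the result sparse and avoids the over-smoothing of iterated
#' diffusion. Query values may be negative (e.g. negatively-weighted user
#' annotations); the transform is linear and sign-agnostic. All-zero
#' strengths give the identity.
#'
#' @param query an \code{encoded_vector} (raw, any norm).
#' @param kb a \code{knowledge_base}.
#' @param strengths named numeric vector or list: collection name ->
#'   diffusion strength s >= 0.
#' @return the diffused \code{encoded_vector} (not re-normalized).
#' @export
diffuse <- function(query, kb, strengths) {
  strengths <- check_strengths(kb, strengths)
  out <- query
  for (nm in names(strengths)) {
    s <- strengths[[nm]]
    if (s == 0)
      next
    out <- ev_add(out, diffuse_one(kb, nm, query, s))
  }
  out
}

#' Explain which features diffusion imputes
#'
#' Ranks the features absent from the raw query by the absolute value
#' they receive through diffusion, with a per-collection breakdown.
#'
#' @param kb a \code{knowledge_base}.
#' @param query query text (character) or an \code{encoded_vector}.
#' @param strengths as in \code{\link{diffuse}}.
#' @param top_m number of imputed features to report.
#' @return data.frame with columns feature, value, and one contribution
#'   column per diffusing collection, sorted by decreasing |value|.
#' @export
explain_imputation <- function(kb, query, strengths, top_m = 10L) {
  if (is.character(query))
    query <- encode(query, kb$catalog, normalize = FALSE)
  strengths <- check_strengths(kb, strengths)
  strengths <- strengths[strengths > 0]
  feats <- names(kb$catalog$index)
  empty <- data.frame(feature = character(0), value = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(strengths) == 0L)
    return(empty)
  parts <- lapply(names(strengths), function(nm)
    diffuse_one(kb, nm, query, strengths[[nm]]))
  names(parts) <- names(strengths)
  total <- Reduce(ev_add, parts, empty_encoded(query$n_features))
  new_idx <- setdiff(total$indices, query$indices)
  if (length(new_idx) == 0L)
    return(empty)
  val <- total$values[match(new_idx, total$indices)]
  ord <- order(-abs(val), feats[new_idx])
  top <- head(ord, top_m)
  out <- data.frame(feature = feats[new_idx][top], value = val[top],
                    stringsAsFactors = FALSE)
  for (nm in names(parts)) {
    p <- parts[[nm]]
    m <- match(new_idx[top], p$indices)
    out[[paste0("from_", nm)]] <- ifelse(is.na(m), 0, p$values[m])
  }
  out
}
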