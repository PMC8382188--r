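#' Knowledge-base configuration
#'
#' Defaults follow the tool's standard instance profiles: k = 6 with
#' uniform weighting (\code{c0 = 1, c1 = 0}) suits unweighted gene-set
#' collections, while k = 6 or 8 with information-content weighting
#' (\code{c0 = 0, c1 = 1}) suits natural-language text where common words
#' should count less. The feature catalog is capped at 200,000 k-mers.
#'
#' @param k k-mer length.
#' @param c0,c1 feature-weighting constants, see \code{\link{scan_corpus}}.
#' @param max_features catalog size cap.
#' @param case_fold lowercase text before tokenization?
#' @param backend nearest-neighbor backend; only \code{"exact"}
#'   (brute-force cosine, deterministic) is provided.
#' @return an object of class \code{kb_config}.
#' @export
kb_config <- function(k = 6L, c0 = 0, c1 = 1, max_features = 200000L,
                      case_fold = TRUE, backend = "exact") {
  backend <- match.arg(backend, "exact")
  if (c0 < 0 || c1 < 0)
    stop("c0 and c1 must be >= 0")
  structure(list(k = as.integer(k), c0 = c0, c1 = c1,
                 max_features = as.integer(max_features),
                 case_fold = isTRUE(case_fold), backend = backend),
            class = "kb_config")
}

as_item_frame <- function(x, collection) {
  if (is.data.frame(x)) {
    if (!all(c("id", "title", "body") %in% names(x)))
      stop("collection '", collection,
           "' must have columns id, title, body")
    data.frame(id = as.character(x$id), title = as.character(x$title),
               body = as.character(x$body), stringsAsFactors = FALSE)
  } else if (is.list(x)) {
    do.call(rbind, lapply(x, function(it)
      data.frame(id = as.character(it$id), title = as.character(it$title),
                 body = as.character(it$body), stringsAsFactors = FALSE)))
  } else {
    stop("collection '", collection, "' must be a data.frame or list")
  }
}

item_text <- function(items) paste(items$title, items$body)

# distinct feature indices per encoded item -> symmetric co-occurrence
# counts; each item increments every feature pair (including the diagonal)
# by 1 / L, L = number of distinct features, so short items record
# co-occurrence with higher weight.
cooc_from_features <- function(feature_list, n_feat) {
  ii <- vector("list", length(feature_list))
  jj <- vector("list", length(feature_list))
  xx <- vector("list", length(feature_list))
  for (m in seq_along(feature_list)) {
    f <- feature_list[[m]]
    L <- length(f)
    if (L == 0L) next
    ii[[m]] <- rep(f, each = L)
    jj[[m]] <- rep(f, times = L)
    xx[[m]] <- rep(1 / L, L * L)
  }
  i <- unlist(ii)
  Matrix::sparseMatrix(i = if (is.null(i)) integer(0) else i,
                       j = if (is.null(i)) integer(0) else unlist(jj),
                       x = if (is.null(i)) numeric(0) else unlist(xx),
                       dims = c(n_feat, n_feat))
}

#' Increment a co-occurrence matrix with one item
#'
#' Every pair (i, j) of distinct features present in the item, including
#' the diagonal, is incremented by 1 / L where L is the number of distinct
#' features, so co-occurrence within short items carries more weight.
#'
#' @param C sparse symmetric feature-by-feature matrix.
#' @param v the item's \code{encoded_vector} (only the support is used).
#' @return updated sparse matrix.
#' @export
increment_cooccurrence <- function(C, v) {
  f <- v$indices
  if (length(f) == 0L)
    return(C)
  C + cooc_from_features(list(f), nrow(C))
}

encode_collection <- function(items, catalog) {
  texts <- item_text(items)
  vecs <- lapply(texts, encode, catalog = catalog, normalize = TRUE)
  n_feat <- n_features(catalog)
  lens <- vapply(vecs, function(v) length(v$indices), integer(1))
  j <- rep(seq_along(vecs), lens)
  i <- unlist(lapply(vecs, `[[`, "indices"))
  x <- unlist(lapply(vecs, `[[`, "values"))
  if (is.null(i)) i <- integer(0)
  if (is.null(x)) x <- numeric(0)
  M <- Matrix::sparseMatrix(i = i, j = j, x = x,
                            dims = c(n_feat, length(vecs)))
  colnames(M) <- items$id
  list(vectors = M,
       cooc = cooc_from_features(lapply(vecs, `[[`, "indices"), n_feat))
}

#' Build a knowledge base from text collections
#'
#' Runs the three build stages: (1) a corpus scan over all collections to
#' learn the shared feature catalog; (2) encoding and storage of every
#' item as a unit-norm sparse vector; (3) construction of the per-collection
#' nearest-neighbor matrix and co-occurrence statistics. Collections built
#' here are \emph{primary} tier: they are never modified afterwards.
#' Run-time additions go to separate user-tier collections via
#' \code{\link{kb_add_item}}.
#'
#' @param collections named list; each element a data.frame (or list of
#'   lists) with fields \code{id}, \code{title}, \code{body}.
#' @param config a \code{\link{kb_config}}.
#' @return an object of class \code{knowledge_base}.
#' @export
kb_build <- function(collections, config = kb_config()) {
  if (length(collections) == 0L || is.null(names(collections)) ||
      any(!nzchar(names(collections))))
    stop("collections must be a non-empty named list")
  frames <- mapply(as_item_frame, collections, names(collections),
                   SIMPLIFY = FALSE)
  for (nm in names(frames))
    if (is.null(frames[[nm]]) || nrow(frames[[nm]]) == 0L)
      stop("collection '", nm, "' is empty")
  all_ids <- unlist(lapply(frames, `[[`, "id"), use.names = FALSE)
  if (anyDuplicated(all_ids))
    stop("duplicate item ids: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  settings <- token_settings(k = config$k, case_fold = config$case_fold)
  catalog <- scan_corpus(unlist(lapply(frames, item_text)), settings,
                         c0 = config$c0, c1 = config$c1,
                         max_features = config$max_features)
  colls <- lapply(names(frames), function(nm) {
    enc <- encode_collection(frames[[nm]], catalog)
    list(tier = "primary", items = frames[[nm]],
         vectors = enc$vectors, cooc = enc$cooc)
  })
  names(colls) <- names(frames)
  structure(list(catalog = catalog, config = config, collections = colls),
            class = "knowledge_base")
}

#' @exportS3Method base::print
print.knowledge_base <- function(x, ...) {
  cat("knowledge base:", length(x$collections), "collection(s),",
      n_features(x$catalog), "features\n")
  for (nm in names(x$collections))
    cat(sprintf("  %s [%s]: %d items\n", nm, x$collections[[nm]]$tier,
                nrow(x$collections[[nm]]$items)))
  invisible(x)
}

#' Collection names of a knowledge base
#' @param kb a \code{knowledge_base}.
#' @param tier optionally restrict to \code{"primary"} or \code{"user"}.
#' @return character vector.
#' @export
kb_collections <- function(kb, tier = NULL) {
  nms <- names(kb$collections)
  if (is.null(tier))
    return(nms)
  nms[vapply(kb$collections, `[[`, "", "tier") == tier]
}

#' Add a user-tier item at run time
#'
#' Inserts a new text snippet into a user-tier collection (created on
#' first use). The item is immediately searchable in its own collection
#' and immediately contributes to that collection's co-occurrence
#' statistics, hence to diffusion. Primary collections and their indexes
#' are never touched, so additions take time independent of the size of
#' the primary data.
#'
#' @param kb a \code{knowledge_base}.
#' @param collection target user-tier collection name; must not name a
#'   primary collection.
#' @param id unique item id.
#' @param title,body item text.
#' @return the updated \code{knowledge_base}.
#' @export
kb_add_item <- function(kb, collection, id, title, body = "") {
  existing <- kb$collections[[collection]]
  if (!is.null(existing) && existing$tier == "primary")
    stop("collection '", collection,
         "' is primary tier; user items must go to a user collection")
  all_ids <- unlist(lapply(kb$collections, function(cc) cc$items$id),
                    use.names = FALSE)
  if (id %in% all_ids)
    stop("item id '", id, "' already present")
  v <- encode(paste(title, body), kb$catalog, normalize = TRUE)
  col_vec <- as(as_sparse_vector(v), "CsparseMatrix")
  item <- data.frame(id = as.character(id), title = as.character(title),
                     body = as.character(body), stringsAsFactors = FALSE)
  if (is.null(existing)) {
    M <- col_vec
    colnames(M) <- id
    kb$collections[[collection]] <-
      list(tier = "user", items = item, vectors = M,
           cooc = cooc_from_features(list(v$indices),
                                     n_features(kb$catalog)))
  } else {
    M <- cbind(existing$vectors, col_vec)
    colnames(M) <- c(existing$items$id, id)
    existing$items <- rbind(existing$items, item)
    existing$vectors <- M
    existing$cooc <- increment_cooccurrence(existing$cooc, v)
    kb$collections[[collection]] <- existing
  }
  kb
}

#' Drop a user-tier collection
#'
#' Removes a user collection entirely; primary collections cannot be
#' dropped, so primary search results are restored exactly.
#'
#' @param kb a \code{knowledge_base}.
#' @param collection user-tier collection name.
#' @return the updated \code{knowledge_base}.
#' @export
kb_drop_collection <- function(kb, collection) {
  cc <- kb$collections[[collection]]
  if (is.null(cc))
    stop("no collection named '", collection, "'")
  if (cc$tier == "primary")
    stop("refusing to drop primary collection '", collection, "'")
  kb$collections[[collection]] <- NULL
  kb
}

#' Exact nearest-neighbor lookup
#'
#' Ranks the items of one collection by cosine similarity to the query
#' (the query is unit-normalized internally; stored items are unit norm).
#' Ties are broken deterministically by item id.
#'
#' @param kb a \code{knowledge_base}.
#' @param query an \code{encoded_vector}.
#' @param collection collection name.
#' @param n number of hits.
#' @return data.frame with columns rank, id, title, similarity. An empty
#'   query yields zero rows with a warning.
#' @export
kb_nearest <- function(kb, query, collection, n = 5L) {
  cc <- kb$collections[[collection]]
  if (is.null(cc))
    stop("no collection named '", collection, "'")
  if (n < 1L)
    stop("n must be >= 1")
  empty <- data.frame(rank = integer(0), id = character(0),
                      title = character(0), similarity = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(query$indices) == 0L) {
    warning("empty query vector: no results")
    return(empty)
  }
  q <- ev_normalize(query)
  sims <- as.numeric(Matrix::crossprod(cc$vectors, as_sparse_vector(q)))
  ord <- order(-sims, cc$items$id)
  top <- ord[seq_len(min(n, length(ord)))]
  data.frame(rank = seq_along(top), id = cc$items$id[top],
             title = cc$items$title[top], similarity = sims[top],
             stringsAsFactors = FALSE)
}

#' Retrieve a stored item by id
#' @param kb a \code{knowledge_base}.
#' @param id item id.
#' @return one-row data.frame with id, title, body, collection, tier.
#' @export
kb_item <- function(kb, id) {
  for (nm in names(kb$collections)) {
    cc <- kb$collections[[nm]]
    hit <- which(cc$items$id == id)
    if (length(hit)) {
      out <- cc$items[hit, , drop = FALSE]
      out$collection <- nm
      out$tier <- cc$tier
      rownames(out) <- NULL
      return(out)
    }
  }
  stop("no item with id '", id, "'")
}

#' Save / load a knowledge base
#'
#' Embedded single-file persistence for a built instance.
#'
#' @param kb a \code{knowledge_base}.
#' @param path file path.
#' @return \code{kb_save} returns \code{path} invisibly; \code{kb_load}
#'   returns the \code{knowledge_base}.
#' @export
kb_save <- function(kb, path) {
  saveRDS(kb, path)
  invisible(path)
}

#' @rdname kb_save
#' @export
kb_load <- function(path) {
  kb <- readRDS(path)
  if (!inherits(kb, "knowledge_base"))
    stop("'", path, "' does not contain a knowledge base")
  kb
}
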