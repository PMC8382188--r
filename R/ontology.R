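#' Parse an OBO flat file
#'
#' Minimal reader for the OBO term stanzas used here: extracts id, name,
#' definition, comment, synonyms, is_a parents and the obsolete flag.
#' (No installed R package in this stack parses OBO, hence the bundled
#' reader; it covers the standard tag-value syntax.)
#'
#' @param source a file path, or a character vector of OBO lines.
#' @return an object of class \code{ontology}: list with \code{terms}
#'   (data.frame id, name, def, comment, obsolete), \code{synonyms} and
#'   \code{parents} (named lists keyed by term id).
#' @export
read_obo <- function(source) {
  lines <- if (length(source) == 1L && file.exists(source))
    readLines(source) else unlist(strsplit(source, "\n", fixed = TRUE))
  lines <- trimws(lines)
  term_starts <- which(lines == "[Term]")
  stanza_starts <- grep("^\\[.*\\]$", lines)
  terms <- list()
  synonyms <- list()
  parents <- list()
  n_malformed <- 0L
  for (s in term_starts) {
    nxt <- stanza_starts[stanza_starts > s]
    block <- lines[(s + 1L):(if (length(nxt)) nxt[1L] - 1L
                             else length(lines))]
    block <- block[nzchar(block)]
    get1 <- function(tag) {
      hit <- grep(paste0("^", tag, ":"), block, value = TRUE)
      if (length(hit) == 0L) "" else
        trimws(sub(paste0("^", tag, ":"), "", hit[1L]))
    }
    id <- get1("id")
    if (!nzchar(id)) {
      n_malformed <- n_malformed + 1L
      next
    }
    def <- get1("def")
    def <- gsub('\\s*\\[.*\\]\\s*$', "", def)
    def <- gsub('^"|"$', "", def)
    syn_lines <- grep("^synonym:", block, value = TRUE)
    syns <- vapply(syn_lines, function(x) {
      m <- regmatches(x, regexpr('"[^"]*"', x))
      if (length(m)) gsub('^"|"$', "", m) else ""
    }, "", USE.NAMES = FALSE)
    isa_lines <- grep("^is_a:", block, value = TRUE)
    isa <- vapply(isa_lines, function(x)
      trimws(sub("!.*$", "", sub("^is_a:", "", x))), "",
      USE.NAMES = FALSE)
    terms[[id]] <- data.frame(
      id = id, name = get1("name"), def = def, comment = get1("comment"),
      obsolete = tolower(get1("is_obsolete")) == "true",
      stringsAsFactors = FALSE)
    synonyms[[id]] <- syns[nzchar(syns)]
    parents[[id]] <- isa[nzchar(isa)]
  }
  if (n_malformed > 0L)
    warning(n_malformed, " malformed [Term] stanza(s) skipped")
  structure(list(terms = do.call(rbind, c(terms, list(make.row.names = FALSE))),
                 synonyms = synonyms, parents = parents),
            class = "ontology")
}

#' @exportS3Method base::print
print.ontology <- function(x, ...) {
  cat("ontology:", nrow(x$terms), "terms (",
      sum(x$terms$obsolete), "obsolete )\n")
  invisible(x)
}

term_name <- function(obo, id) {
  m <- match(id, obo$terms$id)
  ifelse(is.na(m), "", obo$terms$name[m])
}

top_ancestor <- function(obo, id) {
  seen <- character(0)
  cur <- id
  repeat {
    pars <- obo$parents[[cur]]
    pars <- setdiff(pars, seen)
    if (length(pars) == 0L)
      return(cur)
    cur <- sort(pars)[1L]      # deterministic tie-break: smallest id
    seen <- c(seen, cur)
    if (length(seen) > nrow(obo$terms))
      return(cur)              # cycle guard
  }
}

#' Convert ontology terms to knowledge-base items
#'
#' One item per non-obsolete term; the body concatenates the term name,
#' definition, comment, synonyms, the names of its is_a parents and the
#' name of its top ancestor, tying each term to both its meaning and its
#' position in the hierarchy.
#'
#' @param obo an \code{\link{read_obo}} ontology.
#' @return data.frame with columns id, title, body.
#' @export
obo_to_items <- function(obo) {
  terms <- obo$terms[!obo$terms$obsolete, , drop = FALSE]
  body <- vapply(terms$id, function(id) {
    row <- terms[terms$id == id, ]
    paste(c(row$name, row$def, row$comment, obo$synonyms[[id]],
            term_name(obo, obo$parents[[id]]),
            term_name(obo, top_ancestor(obo, id))),
          collapse = " ")
  }, "")
  data.frame(id = terms$id, title = terms$name, body = body,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Undirected is_a graph of an ontology
#'
#' @param obo an \code{\link{read_obo}} ontology.
#' @return an \pkg{igraph} undirected graph over non-obsolete term ids.
#' @export
ontology_graph <- function(obo) {
  keep <- obo$terms$id[!obo$terms$obsolete]
  edges <- do.call(rbind, lapply(keep, function(id) {
    p <- intersect(obo$parents[[id]], keep)
    if (length(p)) cbind(id, p) else NULL
  }))
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(keep)
  if (!is.null(edges))
    g <- igraph::add_edges(g, t(edges))
  g
}

#' Shortest is_a path length between two terms
#'
#' Zero for identical terms, one for parent/child, two for siblings or
#' grandparents, and so on; \code{Inf} for disconnected pairs.
#'
#' @param graph an \code{\link{ontology_graph}}.
#' @param a,b term ids present in the graph.
#' @return numeric (integer-valued, or Inf when unreachable).
#' @export
path_length <- function(graph, a, b) {
  as.numeric(igraph::distances(graph, v = a, to = b))
}

#' Evaluate cross-ontology term translation
#'
#' Runs every query through top-5 search in the target collection and
#' scores it against the expected target term: exact-match precision at
#' rank 1 and within the top 5, plus the ontology-graph path length of
#' the rank-1 hit and the best (smallest) path length among the top 5.
#' Queries that encode to nothing are recorded as misses with unreachable
#' path length. Unreachable path lengths are excluded from the mean path
#' summaries and counted separately.
#'
#' @param queries data.frame with columns id, title, body (e.g. from
#'   \code{\link{obo_to_items}} on the source ontology).
#' @param kb a \code{knowledge_base} holding the target collection.
#' @param expected named character vector: query id -> expected target
#'   term id; must cover every query.
#' @param graph the target ontology's \code{\link{ontology_graph}}.
#' @param collection target collection name.
#' @param diffusion optional named strengths for \code{\link{diffuse}}.
#' @param n number of search hits considered (default 5).
#' @param method label recorded in the per-query table.
#' @return list with \code{summary} (means) and \code{table} (per-query
#'   rows: id, name, expected, expected_name, target, target_name,
#'   target_N, method, precision, pathlen, precision_bestN,
#'   pathlen_bestN).
#' @export
evaluate_translation <- function(queries, kb, expected, graph, collection,
                                 diffusion = NULL, n = 5L,
                                 method = "plain") {
  missing <- setdiff(queries$id, names(expected))
  if (length(missing))
    stop("expected mapping missing for: ",
         paste(utils::head(missing, 3), collapse = ", "))
  target_items <- kb$collections[[collection]]$items
  rows <- lapply(seq_len(nrow(queries)), function(i) {
    qid <- queries$id[i]
    exp_id <- expected[[qid]]
    hits <- suppressWarnings(
      kb_search(kb, paste(queries$title[i], queries$body[i]), collection,
                n = n, diffusion = diffusion))
    if (nrow(hits) == 0L) {
      target <- NA_character_
      p1 <- 0L; p5 <- 0L
      pl1 <- Inf; pl5 <- Inf
      targets <- character(0)
    } else {
      targets <- hits$id
      target <- targets[1L]
      p1 <- as.integer(target == exp_id)
      p5 <- as.integer(exp_id %in% targets)
      pls <- vapply(targets, function(t) path_length(graph, t, exp_id),
                    numeric(1))
      pl1 <- pls[1L]
      pl5 <- min(pls)
    }
    data.frame(
      id = qid, name = queries$title[i], expected = exp_id,
      expected_name = target_items$title[match(exp_id, target_items$id)],
      target = target,
      target_name = target_items$title[match(target, target_items$id)],
      target_N = paste(targets, collapse = ";"), method = method,
      precision = p1, pathlen = pl1, precision_bestN = p5,
      pathlen_bestN = pl5, stringsAsFactors = FALSE)
  })
  table <- do.call(rbind, rows)
  finite1 <- is.finite(table$pathlen)
  finite5 <- is.finite(table$pathlen_bestN)
  list(summary = list(
         precision_top1 = mean(table$precision),
         precision_top5 = mean(table$precision_bestN),
         mean_pathlen_top1 = if (any(finite1))
           mean(table$pathlen[finite1]) else NA_real_,
         mean_pathlen_best5 = if (any(finite5))
           mean(table$pathlen_bestN[finite5]) else NA_real_,
         n_unreachable_top1 = sum(!finite1),
         n_queries = nrow(table)),
       table = table)
}
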