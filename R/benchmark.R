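#' Build a knowledge base from a gene-set collection
#'
#' Standard instance profile for unweighted gene sets: k = 6 and uniform
#' feature weighting (c0 = 1, c1 = 0), so every gene symbol counts
#' equally regardless of how many sets it appears in.
#'
#' @param collection a \code{set_collection}.
#' @param collection_name name of the collection inside the store.
#' @param config a \code{\link{kb_config}}.
#' @return a \code{knowledge_base}.
#' @export
geneset_kb <- function(collection, collection_name = "sets",
                       config = kb_config(k = 6L, c0 = 1, c1 = 0)) {
  colls <- list(sets_to_items(collection))
  names(colls) <- collection_name
  kb_build(colls, config)
}

#' Run the synthetic gene-set benchmark for one grid cell
#'
#' Generates benchmark sets under one recipe and scores the Fisher exact
#' baseline, nearest-neighbor search, and greedy decomposition against
#' the ground-truth source sets with the sum-of-Jaccard score. All three
#' methods report at most \code{n_report} ranked hits.
#'
#' @param collection a \code{set_collection}.
#' @param spec a \code{\link{benchmark_spec}}.
#' @param kb optional pre-built knowledge base over the collection (built
#'   with \code{\link{geneset_kb}} if omitted).
#' @param collection_name knowledge-base collection name.
#' @param methods subset of c("fisher", "search", "decompose").
#' @param n_report ranked hits per method (default 5).
#' @param score_method pairing mode for \code{\link{score_sum_jaccard}}.
#' @return data.frame with one row per (replicate, method): columns
#'   n_components, coverage, signal, replicate, method, score.
#' @export
run_geneset_benchmark <- function(collection, spec, kb = NULL,
                                  collection_name = "sets",
                                  methods = c("fisher", "search",
                                              "decompose"),
                                  n_report = 5L,
                                  score_method = "assignment") {
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(kb) && any(c("search", "decompose") %in% methods))
    kb <- geneset_kb(collection, collection_name)
  benchmarks <- generate_benchmarks(collection, spec)
  rows <- list()
  for (r in seq_along(benchmarks)) {
    bm <- benchmarks[[r]]
    truth_sets <- collection$sets[bm$truth]
    query_text <- paste(bm$genes, collapse = " ")
    for (m in methods) {
      ids <- switch(m,
        fisher = fisher_rank(bm$genes, collection, n = n_report)$id,
        search = kb_search(kb, query_text, collection_name,
                           n = n_report)$id,
        decompose = kb_decompose(kb, query_text, collection_name,
                                 max_components = n_report)$components$id)
      sc <- score_sum_jaccard(collection$sets[ids], truth_sets,
                              method = score_method)
      rows[[length(rows) + 1L]] <- data.frame(
        n_components = spec$n_components, coverage = spec$coverage,
        signal = spec$signal, replicate = r, method = m,
        score = sc$sum_jaccard, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run the benchmark over a grid of recipes
#'
#' @param collection a \code{set_collection}.
#' @param components,coverages,signals grid levels.
#' @param replicates replicates per cell.
#' @param seed base seed; each cell derives its own deterministic seed.
#' @param ... passed to \code{\link{run_geneset_benchmark}}.
#' @return row-bound data.frame of per-replicate scores.
#' @export
run_benchmark_grid <- function(collection, components = 1:4,
                               coverages = c(0.25, 0.5, 0.75, 1),
                               signals = c(0.25, 0.5, 0.75, 1),
                               replicates = 10L, seed = 1L, ...) {
  kb <- geneset_kb(collection)
  grid <- benchmark_grid_size(components, coverages, signals,
                              replicates)$grid
  out <- lapply(seq_len(nrow(grid)), function(i) {
    spec <- benchmark_spec(grid$n_components[i], grid$coverage[i],
                           grid$signal[i], replicates,
                           seed = (seed * 1000L + i) %% .Machine$integer.max)
    run_geneset_benchmark(collection, spec, kb = kb, ...)
  })
  do.call(rbind, out)
}
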