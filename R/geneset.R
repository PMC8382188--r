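#' Gene-set collections
#'
#' A \code{set_collection} is a named list of gene-symbol vectors together
#' with the gene universe they are drawn from.
#'
#' @param sets named list of character vectors (set id -> member genes).
#' @param universe character vector of all gene symbols.
#' @return an object of class \code{set_collection}.
#' @export
set_collection <- function(sets, universe) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be a named list")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  structure(list(sets = sets, universe = unique(as.character(universe))),
            class = "set_collection")
}

#' @exportS3Method base::print
print.set_collection <- function(x, ...) {
  sz <- lengths(x$sets)
  cat("set collection:", length(x$sets), "sets, sizes",
      min(sz), "-", max(sz), "over", length(x$universe), "genes\n")
  invisible(x)
}

#' Read / write GMT gene-set files
#'
#' GMT is tab-separated: set name, description, then member genes.
#'
#' @param path file path.
#' @param universe optional universe; defaults to the union of all members.
#' @return \code{read_gmt}: a \code{set_collection} (descriptions kept in
#'   attribute \code{"descriptions"}); \code{write_gmt}: \code{path},
#'   invisibly.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3L
  if (any(bad))
    warning(sum(bad), " malformed GMT line(s) skipped")
  parts <- parts[!bad]
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  desc <- vapply(parts, `[[`, "", 2L)
  if (is.null(universe))
    universe <- unique(unlist(sets, use.names = FALSE))
  out <- set_collection(sets, universe)
  attr(out, "descriptions") <- desc
  out
}

#' @rdname read_gmt
#' @param collection a \code{set_collection}.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm)
    paste(c(nm, nm, collection$sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Convert a set collection to knowledge-base items
#'
#' Each set becomes one text item whose body lists the member symbols, so
#' a symbol-per-k-mer encoding (uniform weighting, k at least the symbol
#' length) treats sets as bags of genes.
#'
#' @param collection a \code{set_collection}.
#' @return data.frame with columns id, title, body.
#' @export
sets_to_items <- function(collection) {
  data.frame(id = names(collection$sets), title = names(collection$sets),
             body = vapply(collection$sets, paste, "", collapse = " "),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benchmark generation recipe
#'
#' Describes one cell of the synthetic gene-set benchmark grid: how many
#' source sets contribute (\code{n_components}), which fraction of each
#' source set's genes is transferred (\code{coverage}), and which fraction
#' of the final benchmark comes from source sets as opposed to random
#' universe genes (\code{signal}).
#'
#' @param n_components integer >= 1.
#' @param coverage fraction in (0, 1].
#' @param signal fraction in (0, 1].
#' @param replicates number of benchmark sets to generate.
#' @param seed RNG seed for reproducibility.
#' @return an object of class \code{benchmark_spec}.
#' @export
benchmark_spec <- function(n_components = 1L, coverage = 0.5, signal = 0.5,
                           replicates = 1L, seed = 1L) {
  if (coverage <= 0 || coverage > 1)
    stop("coverage must be in (0, 1]")
  if (signal <= 0 || signal > 1)
    stop("signal must be in (0, 1]")
  if (n_components < 1L)
    stop("n_components must be >= 1")
  structure(list(n_components = as.integer(n_components),
                 coverage = coverage, signal = signal,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "benchmark_spec")
}

#' Generate synthetic benchmark gene sets
#'
#' For each replicate: sample \code{n_components} distinct source sets;
#' transfer an exact rounded fraction \code{coverage} of each source set's
#' genes (sampled without replacement, at least one gene); then add genes
#' drawn uniformly from the rest of the universe until source genes make
#' up fraction \code{signal} of the benchmark. With
#' \code{mode = "bernoulli"} each source gene is instead kept
#' independently with probability \code{coverage}.
#'
#' @param collection a \code{set_collection}.
#' @param spec a \code{\link{benchmark_spec}}.
#' @param universe gene universe (defaults to the collection's).
#' @param mode coverage sampling mode: exact \code{"fraction"} (default)
#'   or \code{"bernoulli"}.
#' @return list of \code{benchmark_set} objects, each with fields
#'   \code{genes}, \code{truth} (source set ids) and \code{spec}.
#' @export
generate_benchmarks <- function(collection, spec,
                                universe = collection$universe,
                                mode = c("fraction", "bernoulli")) {
  mode <- match.arg(mode)
  if (spec$n_components > length(collection$sets))
    stop("not enough sets for ", spec$n_components, " components")
  set.seed(spec$seed)
  lapply(seq_len(spec$replicates), function(rep) {
    truth <- sample(names(collection$sets), spec$n_components)
    src <- unique(unlist(lapply(truth, function(id) {
      g <- collection$sets[[id]]
      if (mode == "fraction") {
        n_take <- max(1L, round(length(g) * spec$coverage))
        sample(g, n_take)
      } else {
        g[stats::runif(length(g)) <= spec$coverage]
      }
    })))
    if (length(src) == 0L)
      src <- sample(collection$sets[[truth[1L]]], 1L)
    n_noise <- round(length(src) * (1 - spec$signal) / spec$signal)
    pool <- setdiff(universe,
                    unlist(collection$sets[truth], use.names = FALSE))
    noise <- sample(pool, min(n_noise, length(pool)))
    structure(list(genes = c(src, noise), truth = truth, spec = spec),
              class = "benchmark_set")
  })
}

#' Size of a benchmark grid
#'
#' Enumerates the full generation grid without constructing any sets and
#' returns the total number of benchmark sets it defines, plus the grid
#' itself. At the standard grid (components 1-4, four coverage and four
#' signal levels, 1000 replicates) this is 64,000.
#'
#' @param components integer vector of component counts.
#' @param coverages,signals numeric vectors of fraction levels.
#' @param replicates replicates per grid cell.
#' @return list with \code{n_benchmarks} and the \code{grid} data.frame.
#' @export
benchmark_grid_size <- function(components = 1:4,
                                coverages = c(0.25, 0.5, 0.75, 1),
                                signals = c(0.25, 0.5, 0.75, 1),
                                replicates = 1000L) {
  grid <- expand.grid(n_components = components, coverage = coverages,
                      signal = signals, KEEP.OUT.ATTRS = FALSE)
  grid$replicates <- as.integer(replicates)
  list(n_benchmarks = sum(grid$replicates), grid = grid)
}

#' Rank gene sets by one-sided Fisher exact test
#'
#' For each set the 2x2 table (in query) x (in set) over the universe is
#' tested for over-representation; the one-sided p-value is the upper
#' hypergeometric tail. Sets are ranked by ascending p, ties broken by id.
#'
#' @param query_genes character vector of query gene symbols (non-empty,
#'   assumed within the universe).
#' @param collection a \code{set_collection}.
#' @param universe gene universe (defaults to the collection's).
#' @param n number of hits to report.
#' @return data.frame with columns rank, id, p_value, overlap, set_size.
#' @export
fisher_rank <- function(query_genes, collection,
                        universe = collection$universe, n = 5L) {
  query_genes <- unique(as.character(query_genes))
  if (length(query_genes) == 0L)
    stop("empty query gene set")
  N <- length(universe)
  nq <- length(query_genes)
  ids <- names(collection$sets)
  m <- lengths(collection$sets)
  overlap <- vapply(collection$sets, function(s)
    sum(query_genes %in% s), integer(1))
  p <- stats::phyper(overlap - 1L, m, N - m, nq, lower.tail = FALSE)
  ord <- order(p, ids)
  top <- ord[seq_len(min(n, length(ord)))]
  data.frame(rank = seq_along(top), id = ids[top], p_value = p[top],
             overlap = overlap[top], set_size = m[top],
             stringsAsFactors = FALSE, row.names = NULL)
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) 0 else length(intersect(a, b)) / u
}

# best one-to-one assignment of truth components to reported hits,
# maximizing total Jaccard; exact enumeration for small |truth| (the
# benchmark uses at most 4 components), greedy otherwise
best_assignment <- function(ji) {
  nt <- nrow(ji)
  nh <- ncol(ji)
  if (nt <= 6L) {
    combos <- utils::combn(nh, min(nt, nh), simplify = FALSE)
    best <- 0
    best_sel <- rep(NA_integer_, nt)
    perm_all <- function(v) {
      if (length(v) <= 1L) return(list(v))
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perm_all(v[-i]), function(p) c(v[i], p))))
    }
    for (cmb in combos) {
      for (p in perm_all(cmb)) {
        sel <- rep(NA_integer_, nt)
        sel[seq_along(p)] <- p
        tot <- sum(ji[cbind(seq_along(p), p)])
        if (tot > best) {
          best <- tot
          best_sel <- sel
        }
      }
    }
    return(best_sel)
  }
  sel <- rep(NA_integer_, nt)
  used <- logical(nh)
  for (step in seq_len(min(nt, nh))) {
    jj <- ji
    jj[, used] <- -1
    jj[!is.na(sel), ] <- -1
    pos <- which(jj == max(jj), arr.ind = TRUE)[1L, ]
    sel[pos[1L]] <- pos[2L]
    used[pos[2L]] <- TRUE
  }
  sel
}

#' Sum-of-Jaccard score of reported gene sets against the ground truth
#'
#' Each ground-truth component is paired with one distinct reported hit
#' and the Jaccard indexes of the pairs are summed. The default pairing is
#' the optimal one-to-one assignment over the reported hits (order
#' invariant); \code{method = "positional"} instead compares the i-th
#' ranked hit with the i-th truth component. The score lies in
#' [0, number of components] and counts, effectively, how many components
#' the top of the ranking recovers.
#'
#' @param reported list of gene-symbol vectors in rank order (the top
#'   hits of a method).
#' @param truth list of ground-truth component gene sets.
#' @param method \code{"assignment"} (default) or \code{"positional"}.
#' @return list with \code{sum_jaccard}, \code{per_component_ji} and the
#'   hit index assigned to each component (\code{assignment}).
#' @export
score_sum_jaccard <- function(reported, truth,
                              method = c("assignment", "positional")) {
  method <- match.arg(method)
  nt <- length(truth)
  if (nt == 0L)
    stop("truth must be non-empty")
  if (length(reported) == 0L)
    return(list(sum_jaccard = 0, per_component_ji = rep(0, nt),
                assignment = rep(NA_integer_, nt)))
  if (method == "positional") {
    per <- vapply(seq_len(nt), function(i)
      if (i <= length(reported)) jaccard(truth[[i]], reported[[i]]) else 0,
      numeric(1))
    return(list(sum_jaccard = sum(per), per_component_ji = per,
                assignment = ifelse(seq_len(nt) <= length(reported),
                                    seq_len(nt), NA_integer_)))
  }
  ji <- outer(seq_len(nt), seq_along(reported),
              Vectorize(function(i, j) jaccard(truth[[i]], reported[[j]])))
  ji <- matrix(ji, nrow = nt)
  sel <- best_assignment(ji)
  per <- ifelse(is.na(sel), 0, ji[cbind(seq_len(nt), sel)])
  list(sum_jaccard = sum(per), per_component_ji = per, assignment = sel)
}

#' Gene sets from overlapping genomic windows
#'
#' Tiles each chromosome with overlapping windows of the given sizes and
#' emits one gene set per window that contains at least one gene. A gene
#' belongs to a window when its start coordinate lies inside it. Set ids
#' encode the window as chrom:start-end.
#'
#' @param gene_coords data.frame with columns gene, chrom, start, end
#'   (1-based inclusive). Malformed rows (missing values, end < start)
#'   are skipped with a warning count.
#' @param window_sizes numeric vector of window widths in bases.
#' @param overlap_step step between window starts as a fraction of the
#'   window size (default 0.5: half-overlapping windows).
#' @return a \code{set_collection} over the genes present.
#' @export
genomic_window_sets <- function(gene_coords, window_sizes,
                                overlap_step = 0.5) {
  if (any(window_sizes <= 0) || overlap_step <= 0)
    stop("window sizes and overlap_step must be positive")
  needed <- c("gene", "chrom", "start", "end")
  if (!all(needed %in% names(gene_coords)))
    stop("gene_coords needs columns gene, chrom, start, end")
  gc <- gene_coords[needed]
  gc$start <- suppressWarnings(as.numeric(gc$start))
  gc$end <- suppressWarnings(as.numeric(gc$end))
  bad <- is.na(gc$gene) | is.na(gc$chrom) | is.na(gc$start) |
    is.na(gc$end) | gc$end < gc$start | gc$start < 1
  if (any(bad))
    warning(sum(bad), " malformed coordinate row(s) skipped")
  gc <- gc[!bad, , drop = FALSE]
  sets <- list()
  for (size in window_sizes) {
    step <- max(1, round(size * overlap_step))
    for (chrom in unique(gc$chrom)) {
      starts_g <- gc$start[gc$chrom == chrom]
      genes_g <- gc$gene[gc$chrom == chrom]
      w_starts <- seq(1, max(starts_g), by = step)
      for (ws in w_starts) {
        we <- ws + size - 1
        inside <- starts_g >= ws & starts_g <= we
        if (any(inside))
          sets[[sprintf("%s:%.0f-%.0f", chrom, ws, we)]] <-
            unique(c(sets[[sprintf("%s:%.0f-%.0f", chrom, ws, we)]],
                     genes_g[inside]))
      }
    }
  }
  set_collection(sets, unique(gc$gene))
}

#' Read gene coordinates from a GFF3/GTF annotation
#'
#' Thin wrapper over \pkg{rtracklayer}; keeps rows of type "gene" and
#' returns the columns \code{\link{genomic_window_sets}} expects.
#'
#' @param path GFF3/GTF file path.
#' @param name_attribute attribute holding the gene name (tried in order
#'   with "gene_name", "Name", "gene_id", "ID").
#' @return data.frame with columns gene, chrom, start, end.
#' @export
read_gene_coords <- function(path,
                             name_attribute = c("gene_name", "Name",
                                                "gene_id", "ID")) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("read_gene_coords requires the rtracklayer package")
  gr <- rtracklayer::import(path)
  md <- as.data.frame(gr)
  if ("type" %in% names(md))
    md <- md[md$type == "gene", , drop = FALSE]
  name_col <- intersect(name_attribute, names(md))[1L]
  if (is.na(name_col))
    stop("no gene name attribute found in ", path)
  data.frame(gene = as.character(md[[name_col]]),
             chrom = as.character(md$seqnames),
             start = md$start, end = md$end,
             stringsAsFactors = FALSE, row.names = NULL)
}
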