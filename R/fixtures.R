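# Deterministic synthetic fixtures: gene universes and GO-like set
# collections, toy two-ontology pairs with known translations, and text
# corpora with planted co-occurrence. Everything is generated in code
# under a seed so tests and benchmarks need no downloads.

random_word <- function(len = 8L) {
  paste(sample(letters, len, replace = TRUE), collapse = "")
}

#' Synthetic GO-like gene-set collection
#'
#' Generates a gene universe of symbols (fixed-width, so each symbol is a
#' single k-mer at k = 6) and a collection of sets with sizes in the given
#' bounds, mirroring a GO biological-process collection filtered to sets
#' of 5-100 genes. With \code{nesting_fraction > 0} a fraction of the
#' sets are derived from earlier sets as subsets (children) or supersets
#' (parents), emulating the parent/child redundancy of a real ontology
#' collection; chains of derivations can arise, so redundancy can be
#' deep. With \code{disjoint = TRUE} sets partition the universe (no
#' shared genes), which is the clean regime for exact multi-component
#' recovery.
#'
#' @param n_sets number of sets.
#' @param universe_size number of gene symbols in the universe.
#' @param set_size_range integer c(min, max) set sizes.
#' @param nesting_fraction fraction of sets derived from earlier sets.
#' @param disjoint draw sets without sharing genes?
#' @param seed RNG seed.
#' @return a \code{set_collection}.
#' @export
make_set_collection <- function(n_sets = 500L, universe_size = 20000L,
                                set_size_range = c(5L, 100L),
                                nesting_fraction = 0, disjoint = FALSE,
                                seed = 1L) {
  if (universe_size < max(set_size_range))
    stop("universe smaller than the largest allowed set")
  if (disjoint && nesting_fraction > 0)
    stop("disjoint sets cannot be nested")
  set.seed(seed)
  universe <- sprintf("g%05d", seq_len(universe_size))
  sizes <- sample(set_size_range[1L]:set_size_range[2L], n_sets,
                  replace = TRUE)
  ids <- sprintf("set%04d", seq_len(n_sets))
  sets <- vector("list", n_sets)
  names(sets) <- ids
  if (disjoint) {
    if (sum(sizes) > universe_size)
      stop("universe too small for ", n_sets, " disjoint sets")
    pool <- sample(universe)
    offset <- 0L
    for (i in seq_len(n_sets)) {
      sets[[i]] <- pool[(offset + 1L):(offset + sizes[i])]
      offset <- offset + sizes[i]
    }
    return(set_collection(sets, universe))
  }
  n_nested <- floor(nesting_fraction * n_sets)
  n_base <- n_sets - n_nested
  if (n_base < 1L)
    stop("nesting_fraction leaves no base sets")
  for (i in seq_len(n_base))
    sets[[i]] <- sample(universe, sizes[i])
  for (i in seq_len(n_nested) + n_base) {
    src <- sets[[sample(i - 1L, 1L)]]
    if (stats::runif(1) < 0.5 || length(src) >= set_size_range[2L]) {
      # child: subset of the source, about half its size
      sz <- max(set_size_range[1L],
                min(length(src) - 1L, round(length(src) / 2)))
      sets[[i]] <- sample(src, max(sz, 1L))
    } else {
      # parent: source plus extra genes, capped at the size bound
      extra <- min(length(src), set_size_range[2L] - length(src))
      sets[[i]] <- c(src, sample(setdiff(universe, src), extra))
    }
  }
  set_collection(sets, universe)
}

obo_stanza <- function(id, name, def = "", parents = character(0),
                       synonyms = character(0)) {
  c("[Term]",
    paste0("id: ", id),
    paste0("name: ", name),
    if (nzchar(def)) paste0('def: "', def, '" []'),
    vapply(synonyms, function(s)
      paste0('synonym: "', s, '" EXACT []'), ""),
    vapply(parents, function(p) paste0("is_a: ", p), ""),
    "")
}

#' Toy two-ontology pair with known translations
#'
#' Builds a source ontology (queries) and a target ontology, two OBO
#' texts with a known one-to-one expected translation. Easy pairs share
#' a distinctive concept word, so plain search translates them; hard
#' pairs share no words at all (the source side uses one vocabulary, the
#' target another), standing in for cross-species terminology gaps. The
#' fixture also returns a vocabulary corpus (one item per word, so every
#' query word enters the feature catalog without creating cross-word
#' co-occurrence) and bridge snippets that pair each hard query word with
#' its target-side counterpart; diffusing over a collection holding the
#' bridges is what rescues the hard pairs.
#'
#' @param n_terms total term pairs (>= 5).
#' @param n_hard number of hard pairs among them.
#' @param seed RNG seed.
#' @return list with \code{obo_source}, \code{obo_target} (character OBO
#'   texts), \code{corpus} and \code{bridges} (item data.frames),
#'   \code{expected} (named vector query id -> target id),
#'   \code{hard_queries} (ids of the hard source terms).
#' @export
make_toy_ontology_pair <- function(n_terms = 30L, n_hard = 5L, seed = 1L) {
  if (n_terms < 5L || n_hard >= n_terms - 4L)
    stop("need at least 5 terms and several easy pairs")
  set.seed(seed)
  syn_pairs <- matrix(c(
    "arm", "limb", "kidney", "renal", "elevated", "heightened",
    "heart", "cardiac", "brain", "cerebral", "belly", "abdomen",
    "eye", "ocular", "liver", "hepatic", "skin", "dermal",
    "bone", "skeletal"), ncol = 2, byrow = TRUE)
  n_easy <- n_terms - n_hard
  concept <- replicate(n_easy, random_word(9L))
  hard_src <- replicate(n_hard, random_word(9L))
  hard_tgt <- replicate(n_hard, random_word(9L))
  src_id <- sprintf("HA:%07d", seq_len(n_terms) + 100L)
  tgt_id <- sprintf("MB:%07d", seq_len(n_terms) + 100L)
  tgt_root <- "MB:0000001"
  tgt_mid <- c("MB:0000002", "MB:0000003")
  src_root <- "HA:0000001"
  boiler <- c("morphology", "physiology")
  src_lines <- obo_stanza(src_root, "source phenotype root")
  tgt_lines <- c(obo_stanza(tgt_root, "target phenotype root"),
                 obo_stanza(tgt_mid[1L], "general morphology",
                            parents = tgt_root),
                 obo_stanza(tgt_mid[2L], "general physiology",
                            parents = tgt_root))
  for (i in seq_len(n_easy)) {
    sp <- syn_pairs[1L + (i - 1L) %% nrow(syn_pairs), ]
    b <- boiler[1L + i %% 2L]
    src_lines <- c(src_lines, obo_stanza(
      src_id[i], paste("abnormal", sp[1L], concept[i]),
      def = paste("an abnormality of the", sp[1L], "involving",
                  concept[i], b),
      parents = src_root))
    tgt_lines <- c(tgt_lines, obo_stanza(
      tgt_id[i], paste("abnormal", sp[2L], concept[i]),
      def = paste("any anomaly of the", sp[2L], "related to",
                  concept[i], b),
      parents = tgt_mid[1L + i %% 2L]))
  }
  for (j in seq_len(n_hard)) {
    i <- n_easy + j
    src_lines <- c(src_lines, obo_stanza(
      src_id[i], paste("paroxysmal", hard_src[j]),
      def = paste("episodes of", hard_src[j], "morphology physiology"),
      parents = src_root))
    tgt_lines <- c(tgt_lines, obo_stanza(
      tgt_id[i], hard_tgt[j],
      def = paste("state of", hard_tgt[j]),
      parents = tgt_mid[2L]))
  }
  vocab <- unique(c(concept, hard_src, hard_tgt, as.vector(syn_pairs)))
  corpus <- data.frame(id = sprintf("word%03d", seq_along(vocab)),
                       title = vocab, body = vocab,
                       stringsAsFactors = FALSE)
  bridges <- do.call(rbind, lapply(seq_len(n_hard), function(j)
    data.frame(id = sprintf("bridge%02d_%d", j, 1:3),
               title = "note",
               body = paste(hard_src[j], hard_tgt[j]),
               stringsAsFactors = FALSE)))
  expected <- tgt_id
  names(expected) <- src_id
  list(obo_source = paste(src_lines, collapse = "\n"),
       obo_target = paste(tgt_lines, collapse = "\n"),
       corpus = corpus, bridges = bridges, expected = expected,
       hard_queries = src_id[n_easy + seq_len(n_hard)])
}

#' Random text corpus with planted co-occurrence
#'
#' Documents draw words uniformly from a pseudo-word vocabulary, except
#' that planted word pairs always appear together: whenever the first
#' word of a pair is drawn, its partner is appended. Useful for testing
#' that co-occurrence statistics and diffusion pick up real structure.
#'
#' @param n_docs number of documents.
#' @param vocabulary_size number of distinct words.
#' @param words_per_doc words drawn per document.
#' @param n_planted number of planted always-co-occurring pairs.
#' @param seed RNG seed.
#' @param id_prefix prefix for document ids (ids must be unique across
#'   the collections of one knowledge base).
#' @return list with \code{items} (data.frame id, title, body) and
#'   \code{planted} (two-column matrix of word pairs).
#' @export
make_text_corpus <- function(n_docs = 100L, vocabulary_size = 50L,
                             words_per_doc = 8L, n_planted = 5L,
                             seed = 1L, id_prefix = "doc") {
  set.seed(seed)
  vocab <- unique(replicate(vocabulary_size, random_word(7L)))
  if (2L * n_planted > length(vocab))
    stop("vocabulary too small for the planted pairs")
  planted <- cbind(vocab[seq_len(n_planted)],
                   vocab[n_planted + seq_len(n_planted)])
  items <- do.call(rbind, lapply(seq_len(n_docs), function(d) {
    words <- sample(vocab, words_per_doc, replace = TRUE)
    hit <- words %in% planted[, 1L]
    if (any(hit))
      words <- c(words, planted[match(words[hit], planted[, 1L]), 2L])
    data.frame(id = sprintf("%s%04d", id_prefix, d),
               title = sprintf("%s%04d", id_prefix, d),
               body = paste(unique(words), collapse = " "),
               stringsAsFactors = FALSE)
  }))
  list(items = items, planted = planted)
}
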