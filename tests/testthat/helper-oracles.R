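# Shared fixtures and independent oracles used across the suite.

# brute-force cosine ranking over a collection, independent of the
# matrix-multiply path inside kb_nearest: dense arithmetic, item by item
oracle_rank <- function(kb, query, collection, n = 5L) {
  cc <- kb$collections[[collection]]
  qd <- as.numeric(query)
  qn <- sqrt(sum(qd^2))
  sims <- vapply(seq_len(ncol(cc$vectors)), function(j) {
    v <- as.numeric(cc$vectors[, j])
    sum(qd * v) / qn
  }, numeric(1))
  ord <- order(-sims, cc$items$id)
  top <- ord[seq_len(min(n, length(ord)))]
  data.frame(id = cc$items$id[top], similarity = sims[top],
             stringsAsFactors = FALSE)
}

# dense diffusion oracle: q + sum_d s_d D_d q with sources restricted to
# the original query support, computed with full dense matrices
oracle_diffuse <- function(kb, query, strengths) {
  nf <- n_features(kb$catalog)
  w <- kb$catalog$weights
  q <- as.numeric(query)
  out <- q
  for (nm in names(strengths)) {
    s <- strengths[[nm]]
    if (s == 0) next
    C <- as.matrix(kb$collections[[nm]]$cooc)
    D <- matrix(0, nf, nf)
    for (i in seq_len(nf)) {
      if (C[i, i] == 0) next
      for (j in seq_len(nf)) {
        if (C[i, j] == 0 || w[i] + w[j] == 0) next
        D[i, j] <- (C[i, j] / C[i, i]) * 2 * w[i] * w[j] / (w[i] + w[j])
      }
    }
    restricted <- numeric(nf)
    restricted[query$indices] <- query$values
    out <- out + s * as.numeric(restricted %*% D)
  }
  out
}

# exhaustive hypergeometric upper-tail, from binomial coefficients only
oracle_hyper_p <- function(overlap, set_size, universe_size, query_size) {
  kk <- overlap:min(set_size, query_size)
  sum(choose(set_size, kk) * choose(universe_size - set_size,
                                    query_size - kk)) /
    choose(universe_size, query_size)
}

# small mixed-text knowledge base used by several suites
toy_kb <- function(config = kb_config(k = 6, c0 = 0, c1 = 1)) {
  items <- data.frame(
    id = c("vasc", "renal", "prost", "card"),
    title = c("vascular disorder", "renal failure",
              "prostate inflammation", "cardiac arrest"),
    body = c("abnormality of the vascular system",
             "failure of the kidney renal organ",
             "inflammation of the prostate gland",
             "sudden stop of the cardiac heart muscle"),
    stringsAsFactors = FALSE)
  kb_build(list(main = items), config)
}

# deterministic text-corpus knowledge base of a given size
corpus_kb <- function(n_docs = 100L, seed = 1L,
                      config = kb_config(k = 6, c0 = 0, c1 = 1),
                      vocabulary_size = 60L) {
  corp <- make_text_corpus(n_docs = n_docs, seed = seed,
                           vocabulary_size = vocabulary_size)
  list(kb = kb_build(list(docs = corp$items), config), corpus = corp)
}
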