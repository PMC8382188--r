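test_that("build validates its inputs", {
  items <- data.frame(id = "a", title = "t", body = "some text here")
  expect_error(kb_build(list()), "non-empty named list")
  expect_error(kb_build(list(main = items[0, ])), "'main' is empty")
  dup <- data.frame(id = c("a", "a"), title = c("x", "y"),
                    body = c("aa bb", "cc dd"))
  expect_error(kb_build(list(main = dup)), "duplicate item ids")
  two <- list(c1 = items, c2 = items)
  expect_error(kb_build(two), "duplicate item ids")
})

test_that("stored items answer top-1 self-queries", {
  kb <- toy_kb()
  for (i in seq_len(nrow(kb$collections$main$items))) {
    it <- kb$collections$main$items[i, ]
    hits <- kb_search(kb, paste(it$title, it$body), "main", n = 1)
    expect_equal(hits$id, it$id)
    expect_equal(hits$similarity, 1, tolerance = 1e-9)
  }
})

test_that("searches are restricted to the named collection", {
  a <- data.frame(id = c("a1", "a2"), title = c("x", "y"),
                  body = c("alpha bravo", "charlie delta"))
  b <- data.frame(id = c("b1", "b2"), title = c("x", "y"),
                  body = c("alpha bravo", "echo foxtrot"))
  kb <- kb_build(list(collA = a, collB = b), kb_config(c0 = 1, c1 = 0))
  expect_true(all(kb_search(kb, "alpha bravo", "collA", n = 2)$id
                  %in% c("a1", "a2")))
  expect_true(all(kb_search(kb, "alpha bravo", "collB", n = 2)$id
                  %in% c("b1", "b2")))
  expect_error(kb_search(kb, "alpha", "nope"), "no collection")
})

test_that("exact nearest-neighbor ranking matches the brute-force oracle", {
  ck <- corpus_kb(n_docs = 50, seed = 23)
  kb <- ck$kb
  set.seed(403)
  for (rep in 1:5) {
    words <- sample(ck$corpus$items$body, 3)
    q <- encode(paste(words, collapse = " "), kb$catalog,
                normalize = FALSE)
    got <- kb_nearest(kb, q, "docs", n = 10)
    want <- oracle_rank(kb, q, "docs", n = 10)
    expect_equal(got$id, want$id)
    expect_equal(got$similarity, want$similarity, tolerance = 1e-12)
  }
})

test_that("orthogonal queries tie at zero and break ties by id", {
  a <- data.frame(id = c("b", "a", "c"), title = c("x", "y", "z"),
                  body = c("aaa", "bbb", "ccc"))
  b <- data.frame(id = "other", title = "w", body = "qqq")
  kb <- kb_build(list(main = a, aux = b), kb_config(c0 = 1, c1 = 0))
  # a feature known to the catalog but absent from every item in 'main'
  q <- encode("qqq", kb$catalog, normalize = FALSE)
  hits <- kb_nearest(kb, q, "main", n = 3)
  expect_equal(hits$similarity, c(0, 0, 0))
  expect_equal(hits$id, c("a", "b", "c"))
  # a fully unknown query encodes to nothing and warns
  qz <- encode("zzz", kb$catalog, normalize = FALSE)
  expect_warning(empty <- kb_nearest(kb, qz, "main"), "empty query")
  expect_equal(nrow(empty), 0L)
})

test_that("co-occurrence increments follow the inverse-length rule", {
  items <- data.frame(id = "i1", title = "aaa", body = "bbb")
  kb <- kb_build(list(main = items), kb_config(c0 = 1, c1 = 0))
  C <- kb$collections$main$cooc
  idx <- kb$catalog$index
  expect_equal(C[idx[["aaa"]], idx[["bbb"]]], 1 / 2)
  expect_equal(C[idx[["aaa"]], idx[["aaa"]]], 1 / 2)
  # single-feature item touches only its diagonal
  v <- encode("aaa", kb$catalog)
  C2 <- increment_cooccurrence(C, v)
  expect_equal(C2[idx[["aaa"]], idx[["aaa"]]], 1 / 2 + 1)
  expect_equal(C2[idx[["bbb"]], idx[["bbb"]]], 1 / 2)
  # identical items double the increments (linearity)
  C3 <- increment_cooccurrence(increment_cooccurrence(C * 0, v), v)
  expect_equal(as.matrix(C3), as.matrix(2 * increment_cooccurrence(C * 0, v)))
})

test_that("co-occurrence is symmetric, order-invariant, with the right mass", {
  corp <- make_text_corpus(n_docs = 40, seed = 31)
  kb <- kb_build(list(docs = corp$items), kb_config(c0 = 1, c1 = 0))
  C <- kb$collections$docs$cooc
  expect_equal(as.matrix(C), t(as.matrix(C)))
  expect_true(all(C@x >= 0))
  # total mass oracle: each item contributes L^2 * (1/L) = L
  feats <- lapply(paste(corp$items$title, corp$items$body), function(tx)
    encode(tx, kb$catalog)$indices)
  expect_equal(sum(C), sum(lengths(feats)))
  # insert order does not change the final matrix
  C_fwd <- Reduce(function(acc, f)
    increment_cooccurrence(acc, structure(list(indices = f), class = "encoded_vector")),
    feats, C * 0)
  C_rev <- Reduce(function(acc, f)
    increment_cooccurrence(acc, structure(list(indices = f), class = "encoded_vector")),
    rev(feats), C * 0)
  expect_equal(as.matrix(C_fwd), as.matrix(C_rev))
  expect_equal(as.matrix(C_fwd), as.matrix(C))
  # diagonal strictly positive for every used feature
  used <- sort(unique(unlist(feats)))
  expect_true(all(Matrix::diag(C)[used] > 0))
})

test_that("user-tier additions are isolated from primary collections", {
  kb <- toy_kb()
  expect_error(kb_add_item(kb, "main", "x1", "snippet", "text"),
               "primary tier")
  before_vec <- kb$collections$main$vectors
  before_cooc <- kb$collections$main$cooc
  # snippet vocabulary must be in the build-time catalog to encode
  kb <- kb_add_item(kb, "notes", "n1", "note", "vascular kidney")
  kb <- kb_add_item(kb, "notes", "n2", "note", "prostate gland organ")
  expect_error(kb_add_item(kb, "notes", "n1", "dup", "x"), "already present")
  # immediate self-retrieval in the user collection
  hits <- kb_search(kb, "note vascular kidney", "notes", n = 1)
  expect_equal(hits$id, "n1")
  # primary structures byte-identical: no rebuild happened
  expect_identical(before_vec, kb$collections$main$vectors)
  expect_identical(before_cooc, kb$collections$main$cooc)
  expect_equal(kb_collections(kb, tier = "user"), "notes")
  # dropping the user tier restores primary-only state
  base_hits <- kb_search(toy_kb(), "inflammation prostate", "main")
  kb2 <- kb_drop_collection(kb, "notes")
  expect_identical(kb_search(kb2, "inflammation prostate", "main"),
                   base_hits)
  expect_error(kb_drop_collection(kb2, "main"), "primary")
})

test_that("user additions accumulate the analytic co-occurrence total", {
  ck <- corpus_kb(n_docs = 20, seed = 41)
  kb <- ck$kb
  corp <- make_text_corpus(n_docs = 30, seed = 42)
  total <- 0
  for (r in seq_len(nrow(corp$items))) {
    v <- encode(paste(corp$items$title[r], corp$items$body[r]),
                kb$catalog)
    total <- total + ev_nnz(v)   # item contributes L^2 / L
    kb <- kb_add_item(kb, "extra", paste0("x", r), corp$items$title[r],
                      corp$items$body[r])
  }
  expect_equal(sum(kb$collections$extra$cooc), total)
})

test_that("a knowledge base survives a save/load round trip", {
  kb <- toy_kb()
  path <- tempfile(fileext = ".rds")
  kb_save(kb, path)
  kb2 <- kb_load(path)
  expect_identical(kb_search(kb2, "vascular system", "main"),
                   kb_search(kb, "vascular system", "main"))
  saveRDS(1:3, path)
  expect_error(kb_load(path), "does not contain")
  unlink(path)
})

test_that("stored items can be retrieved by id with provenance", {
  kb <- kb_add_item(toy_kb(), "notes", "n1", "note", "text")
  it <- kb_item(kb, "renal")
  expect_equal(it$collection, "main")
  expect_equal(it$tier, "primary")
  expect_equal(kb_item(kb, "n1")$tier, "user")
  expect_error(kb_item(kb, "ghost"), "no item")
})
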