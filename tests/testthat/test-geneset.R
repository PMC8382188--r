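test_that("benchmark recipes validate their fractions", {
  expect_error(benchmark_spec(coverage = 0), "coverage")
  expect_error(benchmark_spec(coverage = 1.2), "coverage")
  expect_error(benchmark_spec(signal = 0), "signal")
  expect_error(benchmark_spec(n_components = 0), "n_components")
})

test_that("benchmark generation follows coverage and signal recipes", {
  coll <- set_collection(list(s1 = sprintf("g%02d", 1:10),
                              s2 = sprintf("h%02d", 1:10)),
                         universe = c(sprintf("g%02d", 1:10),
                                      sprintf("h%02d", 1:10),
                                      sprintf("u%02d", 1:80)))
  # full coverage, full signal, one component: exactly the source set
  pure <- generate_benchmarks(coll, benchmark_spec(1, 1, 1, 5, seed = 2))
  for (bm in pure)
    expect_setequal(bm$genes, coll$sets[[bm$truth]])
  # exact-fraction mode: half of a 10-gene source is 5 genes
  half <- generate_benchmarks(coll, benchmark_spec(1, 0.5, 1, 5, seed = 3))
  for (bm in half) {
    expect_length(bm$genes, 5L)
    expect_true(all(bm$genes %in% coll$sets[[bm$truth]]))
  }
  # signal 0.5 doubles the size with non-source genes
  noisy <- generate_benchmarks(coll, benchmark_spec(1, 0.5, 0.5, 5, seed = 4))
  for (bm in noisy) {
    src <- intersect(bm$genes, coll$sets[[bm$truth]])
    expect_equal(length(src) / length(bm$genes), 0.5, tolerance = 0.11)
  }
  # reproducible under seed
  a <- generate_benchmarks(coll, benchmark_spec(2, 0.5, 0.5, 10, seed = 7))
  b <- generate_benchmarks(coll, benchmark_spec(2, 0.5, 0.5, 10, seed = 7))
  expect_identical(a, b)
})

test_that("the full benchmark grid enumerates 64,000 sets", {
  gs <- benchmark_grid_size(components = 1:4,
                            coverages = c(0.25, 0.5, 0.75, 1),
                            signals = c(0.25, 0.5, 0.75, 1),
                            replicates = 1000L)
  expect_equal(nrow(gs$grid), 64L)
  expect_equal(gs$n_benchmarks, 64000L)
})

test_that("fisher ranking matches the enumeration oracle exactly", {
  # closed form: query identical to a 10-gene set in a 100-gene universe
  universe <- sprintf("g%03d", 1:100)
  coll <- set_collection(list(hit = universe[1:10],
                              other = universe[21:40]), universe)
  fr <- fisher_rank(universe[1:10], coll)
  expect_equal(fr$id[1], "hit")
  expect_equal(fr$p_value[1], 1 / choose(100, 10), tolerance = 1e-12)
  # enumeration oracle on random small universes
  set.seed(408)
  for (rep in 1:10) {
    N <- sample(10:30, 1)
    uni <- sprintf("u%02d", seq_len(N))
    m <- sample(2:(N - 2), 1)
    nq <- sample(2:(N - 2), 1)
    sets <- list(s = sample(uni, m))
    q <- sample(uni, nq)
    p <- fisher_rank(q, set_collection(sets, uni), n = 1)$p_value
    ov <- length(intersect(q, sets$s))
    expect_equal(p, oracle_hyper_p(ov, m, N, nq), tolerance = 1e-12)
    # independent cross-check against the library test
    ft <- stats::fisher.test(matrix(c(ov, m - ov, nq - ov,
                                      N - m - nq + ov), 2),
                             alternative = "greater")
    expect_equal(p, ft$p.value, tolerance = 1e-9)
  }
  expect_error(fisher_rank(character(0), coll), "empty query")
})

test_that("disjoint queries rank deterministically by id", {
  universe <- sprintf("g%03d", 1:50)
  coll <- set_collection(list(b = universe[1:5], a = universe[6:10]),
                         universe)
  fr <- fisher_rank(universe[40:45], coll, n = 2)
  expect_equal(fr$id, c("a", "b"))
  expect_true(all(fr$p_value > 0.5))
})

test_that("sum-of-Jaccard scoring matches hand-computed cases", {
  A <- sprintf("g%02d", 1:10)
  B <- c(sprintf("g%02d", 1:5), sprintf("x%02d", 1:5))
  expect_equal(score_sum_jaccard(list(A), list(A))$sum_jaccard, 1)
  # |A intersect B| = 5, |A union B| = 15
  expect_equal(score_sum_jaccard(list(B), list(A))$sum_jaccard, 1 / 3)
  # four perfect hits in scrambled order still score 4 under assignment
  truth <- lapply(1:4, function(i) sprintf("c%d_%02d", i, 1:8))
  sc <- score_sum_jaccard(truth[c(3, 1, 4, 2)], truth)
  expect_equal(sc$sum_jaccard, 4)
  expect_equal(sc$per_component_ji, rep(1, 4))
  # positional pairing is order-sensitive
  pos <- score_sum_jaccard(truth[c(2, 1, 3, 4)], truth,
                           method = "positional")
  expect_equal(pos$sum_jaccard, 2)
  expect_equal(score_sum_jaccard(list(), truth)$sum_jaccard, 0)
})

test_that("scores stay within [0, n_components] on random inputs", {
  set.seed(409)
  uni <- sprintf("g%03d", 1:60)
  for (rep in 1:10) {
    nt <- sample(1:4, 1)
    truth <- lapply(seq_len(nt), function(i) sample(uni, 8))
    reported <- lapply(1:5, function(i) sample(uni, sample(3:12, 1)))
    sc <- score_sum_jaccard(reported, truth)
    expect_gte(sc$sum_jaccard, 0)
    expect_lte(sc$sum_jaccard, nt)
    expect_equal(sc$sum_jaccard, sum(sc$per_component_ji))
  }
  # equals n_components iff hits reproduce the truth exactly
  truth <- lapply(1:3, function(i) sample(uni, 5))
  expect_equal(score_sum_jaccard(truth, truth)$sum_jaccard, 3)
})

test_that("genomic windows collect genes by their start coordinate", {
  gc3 <- data.frame(gene = c("a", "b", "c"), chrom = "chr1",
                    start = c(1e6, 2e6, 70e6), end = c(1.1e6, 2.1e6, 70.1e6))
  coll <- genomic_window_sets(gc3, window_sizes = 50e6, overlap_step = 0.5)
  first <- coll$sets[["chr1:1-50000000"]]
  expect_setequal(first, c("a", "b"))
  # windows without genes are not emitted
  expect_false(any(vapply(coll$sets, length, 1L) == 0))
  # recount oracle on a larger toy annotation
  set.seed(410)
  gc20 <- data.frame(gene = sprintf("g%02d", 1:20), chrom = "chr2",
                     start = sort(sample.int(9e6, 20)), end = NA)
  gc20$end <- gc20$start + 1000
  co <- genomic_window_sets(gc20, window_sizes = 2e6, overlap_step = 0.5)
  total <- sum(vapply(co$sets, length, 1L))
  brute <- 0L
  for (ws in seq(1, max(gc20$start), by = 1e6))
    brute <- brute + sum(gc20$start >= ws & gc20$start <= ws + 2e6 - 1)
  expect_equal(total, brute)
  # malformed rows are skipped with a warning
  bad <- rbind(gc3, data.frame(gene = "z", chrom = "chr1",
                               start = 10, end = 5))
  expect_warning(genomic_window_sets(bad, 50e6), "malformed")
})

test_that("GMT files round-trip through the reader and writer", {
  coll <- make_set_collection(n_sets = 20, universe_size = 500,
                              set_size_range = c(5L, 20L), seed = 12)
  path <- tempfile(fileext = ".gmt")
  write_gmt(coll, path)
  back <- read_gmt(path, universe = coll$universe)
  expect_equal(back$sets, coll$sets)
  writeLines(c(readLines(path), "short\tline"), path)
  expect_warning(read_gmt(path), "malformed")
  unlink(path)
})
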