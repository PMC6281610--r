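test_that("enrichment_score matches hand-derivable running sums", {
  sig5 <- toy_signature()                      # scores 5..1 for g1..g5
  es <- enrichment_score(sig5, c("g1", "g3"), w = 0)
  expect_equal(es$es, 2 / 3, tolerance = 1e-12)
  expect_equal(es$extremum_index, 3L)
  sig4 <- toy_signature(c(4, 3, 2, 1))
  expect_equal(enrichment_score(sig4, "g1", w = 0)$es, 1)
  expect_equal(enrichment_score(sig4, "g1", w = 0)$extremum_index, 1L)
  # bottom-ranked single-gene query: the sum dips by 3 misses of 1/3 each
  bot <- enrichment_score(sig4, "g4", w = 0)
  expect_equal(bot$es, -1, tolerance = 1e-12)
  expect_equal(bot$extremum_index, 3L)
  expect_error(enrichment_score(sig5, c("zz")), "disjoint")
  expect_error(enrichment_score(sig5, paste0("g", 1:5)), "whole signature")
})

test_that("enrichment_score equals the exhaustive oracle on random small cases", {
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(3:10, 1)
    ids <- sprintf("x%02d", 1:n)
    scores <- setNames(round(rnorm(n), 3), ids)
    sig <- gene_signature(scores)
    k <- sample(1:(n - 1), 1)
    query <- sample(ids, k)
    for (w in c(0, 1, 1.5)) {
      ora <- oracle_enrichment(scores, ids, query, w)
      got <- enrichment_score(sig, query, w)
      expect_equal(got$es, ora$es, tolerance = 1e-12)
      expect_equal(got$extremum_index, ora$index)
      expect_equal(got$running_sum, ora$running, tolerance = 1e-12)
    }
  }
})

test_that("weighted ES agrees with fgsea's statistic on shared conventions", {
  skip_if_not_installed("fgsea")
  set.seed(77)
  ids <- sprintf("g%03d", 1:200)
  scores <- setNames(sort(rnorm(200), decreasing = TRUE), ids)
  sig <- gene_signature(scores)
  query <- sample(ids, 20)
  got <- enrichment_score(sig, query, w = 1)$es
  ref <- fgsea::calcGseaStat(sig$score,
                             selectedStats = which(sig$gene %in% query),
                             gseaParam = 1, scoreType = "std")
  expect_equal(got, ref, tolerance = 1e-6)
})

test_that("negating scores and reversing ranks negates ES", {
  set.seed(11)
  ids <- sprintf("g%02d", 1:30)
  scores <- setNames(rnorm(30), ids)
  query <- sample(ids, 7)
  for (w in c(0, 1)) {
    a <- enrichment_score(gene_signature(scores), query, w)$es
    b <- enrichment_score(gene_signature(-scores), query, w)$es
    expect_equal(a, -b, tolerance = 1e-12)
  }
})

test_that("leading_edge follows the extremum on both tails", {
  sig5 <- toy_signature()
  expect_setequal(leading_edge(sig5, c("g1", "g3"), w = 0), c("g1", "g3"))
  sig4 <- toy_signature(c(4, 3, 2, 1))
  expect_equal(leading_edge(sig4, "g1", w = 0), "g1")
  expect_equal(leading_edge(sig4, "g4", w = 0), "g4")
})

test_that("permutation_nes centers, floors and reproduces deterministically", {
  set.seed(3)
  ids <- sprintf("g%03d", 1:50)
  sig <- gene_signature(setNames(rnorm(50), ids))
  top <- sig$gene[1:5]
  r1 <- permutation_nes(sig, top, n_perm = 200, seed = 42)
  r2 <- permutation_nes(sig, top, n_perm = 200, seed = 42)
  expect_identical(r1$nes, r2$nes)
  expect_identical(r1$p, r2$p)
  expect_gt(r1$nes, 0)
  expect_gte(r1$p, 1 / 201)
  # a maximally enriched query hits the add-one floor
  expect_equal(r1$p, 1 / 201, tolerance = 1e-12)
  expect_identical(sign(r1$nes), sign(r1$es))
})

test_that("two_tail_gsea signs: self-query enriches both tails, negation flips", {
  set.seed(13)
  ids <- sprintf("g%03d", 1:300)
  scores <- setNames(rnorm(300), ids)
  sig <- gene_signature(scores)
  self <- two_tail_gsea(sig, sig, top_n = 40, n_perm = 200, seed = 7)
  expect_gt(self$positive$nes, 0)
  expect_lt(self$negative$nes, 0)
  flip <- two_tail_gsea(sig, gene_signature(-scores), top_n = 40,
                        n_perm = 200, seed = 7)
  expect_lt(flip$positive$nes, 0)
  expect_gt(flip$negative$nes, 0)
  expect_warning(two_tail_gsea(sig, sig, top_n = 200, n_perm = 50, seed = 1),
                 "top_n")
  small <- gene_signature(setNames(rnorm(8), ids[1:8]))
  expect_error(two_tail_gsea(small, sig, top_n = 2), "10 genes")
})

test_that("leading-edge overlap fraction and chi-square match a hand 2x2 table", {
  uni <- sprintf("u%03d", 1:100)
  a <- uni[1:10]
  b <- c(uni[1:8], uni[11:12])
  res <- leading_edge_overlap_test(a, b, uni)
  expect_equal(res$overlap, 0.8)
  # 2x2 table [[8,2],[2,88]]: chi-square with no continuity correction
  tab <- matrix(c(8, 2, 2, 88), 2, byrow = TRUE)
  e <- outer(rowSums(tab), colSums(tab)) / 100
  expect_equal(res$statistic, sum((tab - e)^2 / e), tolerance = 1e-10)
  expect_equal(leading_edge_overlap_test(a, a, uni)$overlap, 1)
  expect_equal(leading_edge_overlap_test(uni[1:5], uni[6:10], uni)$overlap, 0)
  expect_equal(leading_edge_overlap_test(a, b, uni, denominator = "union")$overlap,
               8 / 12)
  expect_error(leading_edge_overlap_test(a, b, character(0)), "empty universe")
})

test_that("GMT parsing enforces unique names and nonempty sets", {
  f <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg2\tg4"), f)
  gmt <- read_gmt(f)
  expect_named(gmt, c("setA", "setB"))
  expect_equal(gmt$setB, c("g2", "g4"))
  writeLines(c("setA\tdesc\tg1", "setA\tdesc\tg2"), f)
  expect_error(read_gmt(f), "duplicate")
  writeLines(c("setA\tdesc\tg1", "setB\tdesc"), f)
  expect_error(read_gmt(f), "empty")
})

test_that("pathway_enrichment flags a planted set at the p floor and skips tiny sets", {
  set.seed(21)
  ids <- sprintf("g%03d", 1:200)
  sig <- gene_signature(setNames(rnorm(200), ids))
  gmt <- list(planted = sig$gene[1:20],
              random = sample(ids, 25),
              tiny = sample(ids, 3))
  expect_warning(tab <- pathway_enrichment(sig, gmt, n_perm = 200, seed = 5),
                 "skipping")
  expect_false("tiny" %in% tab$set)
  planted <- tab[tab$set == "planted", ]
  expect_gt(planted$nes, 0)
  expect_equal(planted$p, 1 / 201, tolerance = 1e-12)
  expect_true(planted$significant)
  expect_error(pathway_enrichment(sig, list(off = c("zz1", "zz2"))),
               "no gene set overlaps")
})
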