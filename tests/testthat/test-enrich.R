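# The weighted running-sum enrichment score, its permutation null and FDR,
# leading edges, candidate ranking, overlap arithmetic and ORA.

test_that("worked five-gene running sum reproduces the closed-form profile", {
  rk <- make_ranked(c(5, 4, 3, 2, 1))
  es <- enrichment_score(rk, rk$gene_id[c(1, 4)], p = 1, profile = TRUE)
  expect_equal(es$running,
               c(5 / 7, 5 / 7 - 1 / 3, 5 / 7 - 2 / 3, 1 / 3, 0),
               tolerance = 1e-12)
  expect_equal(es$es, 5 / 7, tolerance = 1e-12)
  expect_identical(es$peak_rank, 1L)
  expect_identical(es$leading_edge, rk$gene_id[1])
  expect_equal(es$n_r, 7)
})

test_that("extreme sets reach the ES bounds", {
  rk <- make_ranked(c(5, 4, 3, 2, 1))
  top <- enrichment_score(rk, rk$gene_id[1:2])
  expect_equal(top$es, 1, tolerance = 1e-12)
  expect_identical(top$leading_edge, rk$gene_id[1:2])
  bottom <- enrichment_score(rk, rk$gene_id[5])
  expect_equal(bottom$es, -1, tolerance = 1e-12)
  expect_identical(bottom$leading_edge, rk$gene_id[5])
})

test_that("the reversed-list mirror has a negative ES with the tail leading edge", {
  rk <- make_ranked(c(1, 2, 3, 4, 5))
  es <- enrichment_score(rk, rk$gene_id[c(2, 5)], profile = TRUE)
  expect_equal(es$es, -5 / 7, tolerance = 1e-12)
  expect_identical(es$leading_edge, rk$gene_id[5])
})

test_that("ES matches a brute-force running-sum walk on random instances", {
  set.seed(101)
  for (i in 1:300) {
    N <- sample(10:50, 1)
    k <- sample(2:min(8, N - 2), 1)
    w <- sort(round(rnorm(N, 0, 0.4), 3), decreasing = TRUE)
    rk <- make_ranked(w)
    hits <- sample(N, k)
    if (sum(abs(w[hits])) == 0) next
    mine <- enrichment_score(rk, rk$gene_id[hits], p = 1)
    brute <- brute_running_sum(w, hits, p = 1)
    expect_equal(mine$es, brute$es, tolerance = 1e-12)
  }
})

test_that("p = 0 reduces the ES to the two-sample KS statistic", {
  set.seed(103)
  for (i in 1:100) {
    N <- sample(10:50, 1)
    k <- sample(2:6, 1)
    rk <- make_ranked(sort(rnorm(N), decreasing = TRUE))
    hits <- sample(N, k)
    mine <- enrichment_score(rk, rk$gene_id[hits], p = 0)
    expect_equal(mine$es, brute_ks_stat(N, hits), tolerance = 1e-12)
  }
})

test_that("ES agrees with an independent GSEA implementation", {
  skip_if_not_installed("fgsea")
  set.seed(107)
  for (i in 1:100) {
    N <- sample(50:200, 1)
    k <- sample(5:20, 1)
    stats <- sort(rnorm(N), decreasing = TRUE)
    rk <- make_ranked(stats)
    hits <- sort(sample(N, k))
    mine <- enrichment_score(rk, rk$gene_id[hits], p = 1)
    ref <- fgsea::calcGseaStat(stats, hits, gseaParam = 1)
    expect_equal(mine$es, ref, tolerance = 1e-10)
  }
})

test_that("ES is invariant to positive rescaling of the weights", {
  set.seed(109)
  w <- sort(abs(rnorm(40)), decreasing = TRUE)
  hits <- sample(40, 6)
  a <- enrichment_score(make_ranked(w), sprintf("g%03d", hits))
  b <- enrichment_score(make_ranked(17.3 * w), sprintf("g%03d", hits))
  expect_equal(a$es, b$es, tolerance = 1e-12)
})

test_that("degenerate inputs raise the documented errors", {
  rk <- make_ranked(c(0, 0, 0.5, 0.4))
  expect_error(enrichment_score(rk, rk$gene_id[1:2]), "degenerate weights")
  expect_error(enrichment_score(rk, rk$gene_id), "whole ranked universe")
  expect_error(enrichment_score(rk, c("nope")), "no members")
  expect_error(permutation_null(rk, 2, 0), "n_perm")
  expect_error(permutation_null(rk, 4, 10), "smaller than the universe")
})

test_that("the permutation null is seeded and self-consistent", {
  set.seed(113)
  rk <- make_ranked(sort(rnorm(100), decreasing = TRUE))
  a <- permutation_null(rk, 10, 200, seed = 5)
  b <- permutation_null(rk, 10, 200, seed = 5)
  expect_identical(a, b)
  expect_true(all(abs(a) <= 1))
  # Monte-Carlo self-consistency: two independent halves agree within 3 SE
  c1 <- permutation_null(rk, 10, 400, seed = 7)
  c2 <- permutation_null(rk, 10, 400, seed = 11)
  se <- sqrt(var(c1) / 400 + var(c2) / 400)
  expect_lt(abs(mean(c1) - mean(c2)), 3 * se)
})

test_that("normalization handles zero and unmatched-sign ES", {
  nulls <- list(s0 = c(-0.5, -0.4, 0.3, 0.6), s1 = c(0.2, 0.4, -0.3, -0.1))
  res <- data.frame(set_id = c("s0", "s1"), es = c(0, 0.3),
                    stringsAsFactors = FALSE)
  out <- normalize_and_fdr(res, nulls)
  expect_equal(out$nes[1], 0)
  expect_equal(out$nominal_p[1], 1)
  expect_equal(out$nes[2], 0.3 / mean(c(0.2, 0.4)), tolerance = 1e-12)
  expect_equal(out$nominal_p[2], 0.5)

  onesided <- list(s2 = c(0.1, 0.2, 0.3))
  res2 <- data.frame(set_id = "s2", es = -0.5, stringsAsFactors = FALSE)
  out2 <- normalize_and_fdr(res2, onesided)
  expect_true(out2$p_floor)
  expect_equal(out2$nominal_p, 1 / 4)
})

test_that("candidate ranking follows count then correlation magnitude", {
  rk <- make_ranked(c(0.51, 0.26, -0.17, -0.18, 0.1, 0.05, -0.02, 0.3),
                    gene_id = c("NL", "CD", "H4E", "H4A", "x1", "x2", "x3", "x4"))
  mk_res <- function(le_sets, sign) {
    data.frame(set_id = sprintf("S%d", seq_along(le_sets)),
               es = sign * 0.8, nes = sign * 2, nominal_p = 0, fdr_q = 0.01,
               sign = sign, stringsAsFactors = FALSE) |>
      (function(df) { df$leading_edge <- I(le_sets); df })()
  }
  # CD appears in 27 significant sets, NL in 26: count dominates |mean_r|
  le <- c(lapply(1:26, function(i) c("CD", "NL")), list("CD"))
  cl <- candidate_ranking(mk_res(le, 1), rk)
  expect_identical(cl$positive$gene_id[1:2], c("CD", "NL"))
  expect_identical(cl$positive$n_leading_edge_sets[1:2], c(27L, 26L))
  expect_null(cl$negative)

  # tie on the count: more extreme mean_r first (-0.18 before -0.17)
  le_neg <- lapply(1:23, function(i) c("H4A", "H4E"))
  cln <- candidate_ranking(mk_res(le_neg, -1), rk)
  expect_identical(cln$negative$gene_id[1:2], c("H4A", "H4E"))

  # single significant set: its leading edge ordered by |mean_r|, <= 10
  single <- mk_res(list(c("x1", "NL", "x3")), 1)
  cls <- candidate_ranking(single, rk)
  expect_identical(cls$positive$gene_id, c("NL", "x1", "x3"))

  # deterministic: identical output on re-run
  expect_identical(cl, candidate_ranking(mk_res(le, 1), rk))
})

test_that("overlap percentages reproduce the printed arithmetic", {
  sets_a <- sprintf("s%03d", 1:60)
  sets_b <- c(sprintf("s%03d", 1:3), sprintf("t%03d", 1:58))  # union 118, shared 3
  ov <- overlap_analysis(character(0), character(0), sets_a, sets_b)
  expect_identical(ov$sets$shared, 3L)
  expect_identical(ov$sets$union, 118L)
  expect_equal(ov$sets$pct_shared, 2.5)

  genes_a <- sprintf("g%04d", 1:800)
  genes_b <- c(sprintf("g%04d", 1:135), sprintf("h%04d", 1:597))  # union 1397
  ov2 <- overlap_analysis(genes_a, genes_b, character(0), character(0))
  expect_identical(ov2$genes$shared, 135L)
  expect_identical(ov2$genes$union, 1397L)
  expect_equal(ov2$genes$pct_shared, 9.7)
  expect_lte(abs(ov2$genes$pct_shared - 9.6), 0.1 + 1e-9)

  dis <- overlap_analysis(c("a", "b"), c("c"), "s1", "s2")
  expect_equal(dis$genes$pct_shared, 0)
  same <- overlap_analysis(c("a", "b"), c("a", "b"), "s1", "s1")
  expect_equal(same$genes$pct_shared, 100)
  expect_identical(same$genes$shared + same$genes$only_a + same$genes$only_b,
                   same$genes$union)
})

test_that("ORA matches exact hypergeometric enumeration", {
  universe <- sprintf("u%02d", 1:20)
  gs <- list(full = universe[1:5], off = universe[6:10])
  out <- ora(universe[1:5], gs, universe)
  expect_equal(out$p[out$set_id == "full"], 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(out$p[out$set_id == "off"], 1)
  expect_equal(out$q, p.adjust(out$p, "BH"))

  empty <- ora(character(0), gs, universe)
  expect_true(all(empty$p == 1))

  # monotone decreasing in overlap
  ps <- vapply(1:5, function(k) {
    ora(universe[1:5], list(s = c(universe[1:k], universe[11:(15 - k + 1)])),
        universe)$p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("network export keeps significant sets and Jaccard edges", {
  res <- data.frame(set_id = c("A", "B", "C"), es = c(0.5, 0.4, 0.3),
                    nes = c(2, 1.9, 0.5), nominal_p = 0,
                    fdr_q = c(0.01, 0.02, 0.5), sign = 1, size = c(3L, 3L, 3L),
                    stringsAsFactors = FALSE)
  gs <- list(A = c("g1", "g2", "g3"), B = c("g2", "g3", "g4"),
             C = c("g7", "g8", "g9"))
  net <- enrichment_network(res, gs, jaccard_min = 0.25)
  expect_identical(net$nodes$set_id, c("A", "B"))
  expect_identical(nrow(net$edges), 1L)
  expect_equal(net$edges$jaccard, 0.5)
})

test_that("GMT files round-trip identically", {
  gs <- list(alpha = c("g1", "g2", "g3"), beta = c("g9", "g2"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gs, path, descriptions = c("first", "second"))
  back <- read_gmt(path)
  expect_identical(back[names(gs)], gs)
  expect_identical(attr(back, "descriptions"), c("first", "second"))
  skip_if_not_installed("fgsea")
  ref <- fgsea::gmtPathways(path)
  expect_identical(ref[names(gs)], gs)
})
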