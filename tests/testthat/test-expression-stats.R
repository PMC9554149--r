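# Differential expression, co-expression screening, gene-set scoring and
# hypergeometric enrichment.

make_counts <- function(m) tiny_expr(m, "count")

test_that("differential expression applies inclusive FC and strict p cutoffs", {
  set.seed(1)
  n <- 20
  base <- matrix(rpois(50 * 2 * n, 100), nrow = 50,
                 dimnames = list(sprintf("g%02d", 1:50),
                                 sprintf("s%02d", 1:(2 * n))))
  labels <- rep(c("A", "B"), each = n)
  # flat gene: identical values in both classes
  base[1, ] <- 100
  de <- differential_expression(make_counts(base), labels,
                                positive_class = "B")
  expect_equal(de$log2FC[1], 0, tolerance = 0.01)
  expect_false(de$is_deg[1])
  expect_true(all(de$is_deg == (abs(de$log2FC) >= 1 & de$p_value < 0.05)))

  g_shift <- base
  g_shift[2, labels == "B"] <- rpois(n, 450)  # ~2.2-fold up on log2 scale
  de2 <- differential_expression(make_counts(g_shift), labels,
                                 positive_class = "B")
  expect_true(de2$is_deg[2])
  expect_identical(de2$direction[2], "up")

  # engineered gene sitting exactly on the |log2FC| = 1 boundary: flat
  # background keeps size factors at 1, and (199+1)/(99+1) doubles exactly
  flat <- matrix(100, nrow = 50, ncol = 2 * n,
                 dimnames = list(sprintf("f%02d", 1:50),
                                 sprintf("s%02d", 1:(2 * n))))
  flat <- rbind(flat, edge = c(rep(99, n), rep(199, n)))
  de3 <- differential_expression(make_counts(flat), labels,
                                 positive_class = "B")
  expect_equal(de3$log2FC[de3$gene_id == "edge"], 1)
  expect_true(de3$is_deg[de3$gene_id == "edge"])
})

test_that("log2FC is antisymmetric under class-label swap", {
  set.seed(2)
  m <- matrix(rnbinom(100 * 24, mu = 80, size = 10), nrow = 100,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("s%02d", 1:24)))
  labels <- rep(c("A", "B"), each = 12)
  de_b <- differential_expression(make_counts(m), labels, positive_class = "B")
  de_a <- differential_expression(make_counts(m), labels, positive_class = "A")
  expect_equal(de_b$log2FC, -de_a$log2FC)
  expect_equal(de_b$p_value, de_a$p_value)
})

test_that("differential expression rejects invalid designs", {
  m <- matrix(1:12, nrow = 3,
              dimnames = list(c("a", "b", "c"), sprintf("s%d", 1:4)))
  expect_error(differential_expression(make_counts(m), c("A", "A", "A", "B")),
               "at least 2 samples")
  expect_error(differential_expression(tiny_expr(m, "tpm"),
                                       rep(c("A", "B"), 2)),
               "count-scale")
})

test_that("co-expression screen keeps only strong positive correlations", {
  set.seed(3)
  n <- 30
  anchor <- rnorm(n, 50, 5)
  m <- rbind(anchor = anchor,
             clone = 2 * anchor + 3,        # PCC = 1 under affine transform
             anti = max(anchor) - anchor,   # PCC = -1
             noise = rnorm(n, 50, 5))
  colnames(m) <- sprintf("s%02d", 1:n)
  e <- tiny_expr(m, "tpm")
  pairs <- pearson_coexpression(e, "anchor", c("clone", "anti", "noise"))
  expect_identical(pairs$candidate, "clone")
  expect_equal(pairs$pcc, 1, tolerance = 1e-12)

  m2 <- rbind(m, flat = rep(5, n))
  expect_warning(
    p2 <- pearson_coexpression(tiny_expr(m2, "tpm"), "anchor",
                               c("clone", "flat")),
    "constant")
  expect_identical(p2$candidate, "clone")
})

test_that("co-expression null retains essentially no pairs", {
  set.seed(4)
  m <- matrix(rnbinom(201 * 50, mu = 100, size = 10), nrow = 201,
              dimnames = list(sprintf("g%03d", 1:201), sprintf("s%02d", 1:50)))
  pairs <- pearson_coexpression(tiny_expr(m, "count"), "g001",
                                rownames(m)[-1])
  expect_lte(nrow(pairs), 1)
})

test_that("gene-set score is rank-based and directionally sensitive", {
  set.seed(5)
  m <- matrix(rnbinom(200 * 30, mu = 100, size = 5), nrow = 200,
              dimnames = list(sprintf("g%03d", 1:200), sprintf("s%02d", 1:30)))
  e <- tiny_expr(m, "tpm")
  members <- rownames(m)[1:20]

  # identical columns give identical scores
  m_same <- matrix(rep(m[, 1], 5), ncol = 5,
                   dimnames = list(rownames(m), sprintf("c%d", 1:5)))
  sc_same <- gene_set_score(tiny_expr(m_same, "tpm"), members)
  expect_true(all(sc_same == sc_same[1]))

  # monotone within-sample transform leaves scores unchanged
  sc <- gene_set_score(e, members)
  sc_log <- gene_set_score(tiny_expr(log1p(m), "tpm"), members)
  expect_equal(sc, sc_log)

  # boosting member ranks in half the samples raises their scores
  m_up <- m
  m_up[members, 16:30] <- m_up[members, 16:30] * 8
  sc_up <- gene_set_score(tiny_expr(m_up, "tpm"), members)
  expect_gt(mean(sc_up[16:30]), mean(sc_up[1:15]))
  expect_lt(t.test(sc_up[16:30], sc_up[1:15])$p.value, 0.05)

  # degenerate set covering all genes: constant score
  sc_all <- gene_set_score(e, rownames(m))
  expect_true(all(sc_all == sc_all[1]))
  expect_error(gene_set_score(e, c("nope1", "nope2")), "empty intersection")
})

test_that("enrichment p-values equal the closed-form hypergeometric tail", {
  universe <- sprintf("u%02d", 1:30)
  set_a <- universe[1:8]
  query <- universe[c(1:6, 25:28)]
  res <- enrichment_test(query, list(A = set_a), universe, p_threshold = 1e-4)
  # closed form: sum over overlaps >= 6 of choose(8,k) choose(22,10-k) / choose(30,10)
  p_manual <- sum(vapply(6:8, function(k) {
    choose(8, k) * choose(22, 10 - k)
  }, numeric(1))) / choose(30, 10)
  expect_equal(res$p_value[res$set == "A"], p_manual, tolerance = 1e-12)

  res2 <- enrichment_test(universe[25:30], list(A = set_a), universe)
  expect_equal(res2$p_value, 1, tolerance = 1e-12)

  expect_error(enrichment_test(c("zz"), list(A = set_a), universe), "subset")
  expect_error(enrichment_test(character(0), list(A = set_a), universe),
               "non-empty")
})

test_that("null enrichment p-values are roughly uniform", {
  set.seed(6)
  universe <- sprintf("u%03d", 1:200)
  gset <- universe[1:40]
  ps <- replicate(200, {
    q <- sample(universe, 30)
    enrichment_test(q, list(S = gset), universe)$p_value
  })
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.75)
  expect_lt(mean(ps < 0.05), 0.12)
})
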