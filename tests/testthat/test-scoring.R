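# Per-cluster summaries and per-cell signature scores.

test_that("cluster summaries compute exact percentages and means", {
  # one gene, one cluster of 4 cells, expressed in 1 -> pct 25, mean 2
  em <- make_expr(matrix(c(0, 0, 2, 6, 1, 1, 1, 1), nrow = 2, byrow = TRUE),
                  genes = c("gA", "gB"))
  ann <- make_ann(colnames(em$values), cluster = "k1")
  s <- summarize_by_cluster(em, ann, c("gA", "gB"))
  expect_equal(s$pct_expressed[s$gene == "gA"], 50)
  expect_equal(s$mean_expr[s$gene == "gA"], 2)
  expect_equal(s$pct_expressed[s$gene == "gB"], 100)

  # absent genes skipped and reported
  expect_warning(s2 <- summarize_by_cluster(em, ann, c("gA", "gZ")),
                 "gZ")
  expect_equal(attr(s2, "missing_genes"), "gZ")
  expect_setequal(s2$gene, "gA")

  # conservation: sum over clusters of pct/100 * cluster size = expressing cells
  set.seed(5)
  m <- matrix(rpois(20 * 30, 0.8), 20, 30)
  em3 <- make_expr(m, layer = "counts")
  ann3 <- make_ann(colnames(em3$values),
                   cluster = sample(c("a", "b", "c"), 30, replace = TRUE))
  s3 <- summarize_by_cluster(em3, ann3, rownames(em3$values))
  cl_sizes <- table(ann3$cluster)
  for (g in rownames(em3$values)) {
    rows <- s3[s3$gene == g, ]
    expr_cells <- sum(rows$pct_expressed / 100 *
                        as.numeric(cl_sizes[rows$cluster]))
    expect_equal(expr_cells, sum(m[match(g, rownames(em3$values)), ] > 0))
  }
})

test_that("marker specificity is the pct gap to the best other cluster", {
  s <- data.frame(gene = "gA", cluster = c("t", "o1", "o2"),
                  pct_expressed = c(80, 10, 5), mean_expr = 1)
  class(s) <- c("cluster_summary", "data.frame")
  expect_equal(marker_specificity(s, "gA", "t"), 70)
  s$pct_expressed <- c(40, 40, 40)
  expect_equal(marker_specificity(s, "gA", "t"), 0)
  s$pct_expressed <- c(100, 0, 0)  # perfectly exclusive planted marker
  expect_equal(marker_specificity(s, "gA", "t"), 100)
  expect_error(marker_specificity(s, "gA", "nope"), "unknown cluster")
  expect_error(marker_specificity(s, "gZ", "t"), "not in summary")
})

test_that("z-score signature scores match hand computation", {
  em <- make_expr(matrix(c(1, 3), 1, 2), genes = "gA")
  sc <- zscore_signature_score(em, "gA")
  expect_equal(sc$score, c(-1, 1) / sqrt(2), tolerance = 1e-10)

  # each retained gene's z-vector has sample mean 0 and sd 1
  set.seed(9)
  em2 <- make_expr(matrix(runif(5 * 40), 5, 40))
  for (g in rownames(em2$values)) {
    z <- zscore_signature_score(em2, g)$score
    expect_equal(mean(z), 0, tolerance = 1e-10)
    expect_equal(sd(z), 1, tolerance = 1e-10)
  }

  # zero-variance genes dropped; all-constant signature errors
  em3 <- make_expr(rbind(c(1, 3), c(2, 2)), genes = c("gA", "gB"))
  expect_warning(sc3 <- zscore_signature_score(em3, c("gA", "gB")), "gB")
  expect_equal(sc3$score, c(-1, 1) / sqrt(2), tolerance = 1e-10)
  expect_error(suppressWarnings(zscore_signature_score(em3, "gB")),
               "nonzero variance")
})

test_that("capped-rank score reproduces the worked examples", {
  em <- make_expr(matrix(c(5, 4, 3, 2, 1), 5, 1),
                  genes = sprintf("g%d", 1:5))
  p <- score_params(max_rank = 5, cutoff = 0.4)
  # signature = the two top-ranked genes: U' = 0, score 1
  expect_equal(rank_signature_score(em, c("g1", "g2"), p)$score, 1)
  # ranks {1, 3}: U' = 4 - 3 = 1, score = 1 - 1/10 = 0.9
  expect_equal(rank_signature_score(em, c("g1", "g3"), p)$score, 0.9)
  # single gene beyond max_rank: capped to r_max + 1, score 0
  em6 <- make_expr(matrix(6:1, 6, 1), genes = sprintf("g%d", 1:6))
  expect_equal(rank_signature_score(em6, "g6", p)$score, 0)

  expect_error(rank_signature_score(em, sprintf("g%d", 1:5),
                                    score_params(max_rank = 4)),
               "exceeds max_rank")
  expect_error(suppressWarnings(rank_signature_score(em, "nope", p)),
               "no signature gene")
})

test_that("zero-expression ties share one capped average rank", {
  # 6 genes: one expressed, five tied at zero. Zeros get average rank
  # (2+...+6)/5 = 4; with max_rank = 3 they all cap to 4.
  em <- make_expr(matrix(c(9, 0, 0, 0, 0, 0), 6, 1),
                  genes = sprintf("g%d", 1:6))
  p <- score_params(max_rank = 3)
  expect_equal(rank_signature_score(em, "g2", p)$score, 0)
  # mixed signature: ranks (1, 4) -> U' = 5 - 3 = 2, score = 1 - 2/6
  expect_equal(rank_signature_score(em, c("g1", "g2"), p)$score, 1 - 2 / 6)
})

test_that("rank score is invariant to strictly monotone transforms", {
  set.seed(13)
  m <- matrix(rexp(50 * 8), 50, 8)
  em <- make_expr(m)
  sig <- sample(rownames(em$values), 10)
  p <- score_params(max_rank = 30)
  base <- rank_signature_score(em, sig, p)$score
  for (f in list(function(x) 2 * x + 1, function(x) x^3, log1p)) {
    emt <- make_expr(f(as.matrix(em$values)),
                     genes = rownames(em$values), cells = colnames(em$values))
    expect_equal(rank_signature_score(emt, sig, p)$score, base)
  }
  expect_true(all(base >= 0 & base <= 1))
})

test_that("thresholding flags cells inclusively at the cutoff", {
  em <- make_expr(matrix(runif(30 * 3), 30, 3))
  sc <- rank_signature_score(em, rownames(em$values)[1:5],
                             score_params(max_rank = 20))
  sc$score <- c(0.39, 0.40, 0.41)
  out <- threshold_cells(sc, 0.4)
  expect_equal(out$high_flag, c(FALSE, TRUE, TRUE))
  expect_true(all(threshold_cells(sc, 0)$high_flag))

  ann <- make_ann(sc$cell_id, cluster = c("a", "a", "b"))
  out2 <- threshold_cells(sc, 0.4, ann)
  expect_equal(attr(out2, "group_high_fraction"), c(a = 0.5, b = 1))
  expect_equal(attr(out2, "group_high_count"), c(a = 1L, b = 1L))
})
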