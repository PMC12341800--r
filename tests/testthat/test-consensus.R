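# Marker filtering, gene-list similarity/clustering, intersections,
# k-of-n consensus.

test_that("filter applies strict FC and p thresholds on every scale", {
  tbl <- mixed_scale_table()
  out <- filter_markers(tbl)
  # linear: 1.6 passes, 1.5 exactly fails (strict), p_adj 0.06 fails
  # log2: 0.7 passes (2^0.7 ~ 1.62 > 1.5), 0.5 fails (2^0.5 ~ 1.41)
  # ln study: 0.3 > 0.25 passes, 0.2 fails
  expect_setequal(out$gene, c("A", "D", "F"))
  # order preserved
  expect_equal(out$gene, c("A", "D", "F"))

  # missing p_adj conservatively fails any p-threshold
  tbl2 <- marker_table("s1", "RGL", "NSC", c("X", "Y"),
                       fc = 3, p_adj = c(NA, 0.01))
  expect_equal(filter_markers(tbl2)$gene, "Y")

  # p_adj exactly at the ceiling fails (strict "<")
  tbl3 <- marker_table("s1", "RGL", "NSC", "Z", fc = 3, p_adj = 0.05)
  expect_warning(out3 <- filter_markers(tbl3), "no records")
  expect_equal(nrow(out3), 0L)
})

test_that("gene lists per class honor the counting unit", {
  tbl <- bind_marker_tables(
    marker_table("s1", "cluA", "NSC", c("A", "B"), fc = 2, p_adj = 0.01),
    marker_table("s1", "cluB", "NSC", c("B", "C"), fc = 2, p_adj = 0.01),
    marker_table("s2", "cluA", "NSC", c("A"), fc = 2, p_adj = 0.01)
  )
  by_study <- gene_lists_by_class(tbl, "NSC", "study")
  expect_named(by_study, c("s1", "s2"))
  expect_setequal(by_study$s1, c("A", "B", "C"))

  by_cluster <- gene_lists_by_class(tbl, "NSC", "cluster")
  expect_length(by_cluster, 3L)
  expect_setequal(by_cluster[["s1:cluA"]], c("A", "B"))

  expect_warning(empty <- gene_lists_by_class(tbl, "NEUROBLAST"), "no NEUROBLAST")
  expect_length(empty, 0L)
})

test_that("pairwise similarity matches definitions and is symmetric", {
  lists <- list(L1 = c("A", "B", "C"), L2 = c("B", "C", "D"))
  expect_equal(pairwise_similarity(lists, "common_count")["L1", "L2"], 2)
  expect_equal(pairwise_similarity(lists, "jaccard")["L1", "L2"], 0.5)
  expect_equal(pairwise_similarity(lists, "overlap_coeff")["L1", "L2"], 2 / 3)
  # common-count diagonal = list sizes; jaccard diagonal = 1
  expect_equal(diag(pairwise_similarity(lists, "common_count")), c(L1 = 3, L2 = 3))
  expect_equal(diag(pairwise_similarity(lists, "jaccard")), c(L1 = 1, L2 = 1))

  ident <- list(a = c("X", "Y"), b = c("x", "y"))  # case-insensitive match
  expect_equal(pairwise_similarity(ident, "jaccard")["a", "b"], 1)
  disjoint <- list(a = "X", b = "Y")
  expect_equal(pairwise_similarity(disjoint, "jaccard")["a", "b"], 0)
  expect_warning(
    S <- pairwise_similarity(list(a = character(0), b = character(0),
                                  c = "X"), "jaccard"),
    "empty"
  )
  expect_equal(S["a", "b"], 0)

  # symmetry + permutation equivariance on random instances
  set.seed(11)
  for (i in 1:20) {
    lists <- random_lists(4, 15)
    S <- pairwise_similarity(lists, "jaccard")
    expect_identical(S, t(S))
    perm <- sample(names(lists))
    S2 <- pairwise_similarity(lists[perm], "jaccard")
    expect_equal(S2[names(lists), names(lists)], S, ignore_attr = TRUE)
  }
})

test_that("similarity-to-distance conversion respects the metric", {
  lists <- list(L1 = c("A", "B", "C"), L2 = c("B", "C", "D"))
  S <- pairwise_similarity(lists, "jaccard")
  D <- similarity_to_distance(S, "one_minus")
  expect_equal(D["L1", "L2"], 0.5)
  expect_equal(diag(D), c(L1 = 0, L2 = 0))

  Sc <- pairwise_similarity(lists, "common_count")
  Dc <- similarity_to_distance(Sc, "max_minus")
  expect_equal(Dc["L1", "L2"], max(Sc) - 2)
  expect_equal(diag(Dc), c(L1 = 0, L2 = 0))
  expect_true(all(Dc >= 0))

  expect_error(similarity_to_distance(Sc, "one_minus"), "max_minus")
})

test_that("hierarchical clustering agglomerates as hand-computed", {
  D <- matrix(c(0, 1, 5,
                1, 0, 5,
                5, 5, 0), 3, 3,
              dimnames = list(c("p1", "p2", "p3"), c("p1", "p2", "p3")))
  h <- hierarchical_cluster(D, "complete")
  expect_equal(h$height, c(1, 5))
  expect_setequal(h$labels, c("p1", "p2", "p3"))

  # duplicated lists merge at height zero
  lists <- rep(list(c("A", "B")), 4)
  names(lists) <- sprintf("L%d", 1:4)
  S <- pairwise_similarity(lists, "jaccard")
  h0 <- hierarchical_cluster(similarity_to_distance(S, "one_minus"))
  expect_equal(h0$height, rep(0, 3))

  expect_error(hierarchical_cluster(matrix(0, 1, 1)), "at least 2")
  expect_error(hierarchical_cluster(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")

  # Newick export keeps all leaves
  nwk <- dendrogram_to_newick(h)
  expect_true(all(vapply(c("p1", "p2", "p3"), grepl, logical(1), x = nwk)))
})

test_that("exclusive intersections partition the union", {
  tab <- exclusive_intersections(list(L1 = c("A", "B"), L2 = c("B", "C")))
  expect_setequal(tab$pattern, c("L1", "L1&L2", "L2"))
  expect_equal(tab$count[match(c("L1", "L1&L2", "L2"), tab$pattern)],
               c(1L, 1L, 1L))
  expect_equal(sort(unlist(tab$genes)), c("A", "B", "C"))

  # conservation + uniqueness on random instances
  set.seed(21)
  for (i in 1:25) {
    lists <- random_lists(sample(2:5, 1), 25)
    tab <- exclusive_intersections(lists)
    union_size <- length(unique(toupper(unlist(lists))))
    expect_equal(sum(tab$count), union_size)
    expect_equal(anyDuplicated(toupper(unlist(tab$genes))), 0L)
    expect_equal(anyDuplicated(tab$pattern), 0L)
  }
})

test_that("consensus signature thresholds, orders and nests correctly", {
  lists <- c(
    lapply(1:5, function(i) c("Fabp7", "Hopx")),
    lapply(6:7, function(i) c("Hopx", "Tnc"))
  )
  names(lists) <- sprintf("s%d", 1:7)
  # Hopx in 7/7, Fabp7 in 5/7, Tnc in 2/7
  expect_setequal(consensus_signature(lists, 5)$genes, c("Fabp7", "Hopx"))
  expect_equal(consensus_signature(lists, 6)$genes, "Hopx")
  expect_equal(consensus_signature(lists, 7)$genes, "Hopx")
  # ordering: descending support then symbol
  sig5 <- consensus_signature(lists, 2)
  expect_equal(sig5$genes, c("Hopx", "Fabp7", "Tnc"))
  expect_equal(unname(attr(sig5, "support")), c(7L, 5L, 2L))
  # min_studies = 1 gives the union
  expect_setequal(consensus_signature(lists, 1)$genes,
                  c("Fabp7", "Hopx", "Tnc"))
  expect_error(consensus_signature(lists, 8), "1..7")

  # monotone nesting + brute-force agreement on random instances
  set.seed(31)
  for (i in 1:20) {
    lists <- random_lists(sample(3:8, 1), 40)
    prev <- NULL
    for (k in seq_along(lists)) {
      got <- suppressWarnings(consensus_signature(lists, k)$genes)
      expect_identical(sort(toupper(got)), brute_consensus(lists, k))
      if (!is.null(prev)) expect_true(all(got %in% prev))
      prev <- got
    }
  }
})

test_that("symbol matching is case-insensitive with first-seen spelling", {
  lists <- list(s1 = "Fabp7", s2 = "FABP7", s3 = "fabp7")
  sig <- consensus_signature(lists, 3)
  expect_equal(sig$genes, "Fabp7")
  tab <- exclusive_intersections(lists)
  expect_equal(tab$pattern, "s1&s2&s3")
  expect_equal(tab$genes[[1]], "Fabp7")
})
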