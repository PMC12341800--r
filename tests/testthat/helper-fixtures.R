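# Shared fixtures and independent oracles, all built in code.

# genes x cells expression matrix from a plain matrix definition
make_expr <- function(values, genes = NULL, cells = NULL, layer = "lognorm") {
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(values)))
  if (is.null(cells)) cells <- sprintf("c%d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, cells)
  expression_matrix(values, layer = layer)
}

make_ann <- function(cells, cluster = "all", pseudotime = NULL) {
  df <- data.frame(cell_id = cells, cluster = cluster,
                   stringsAsFactors = FALSE)
  if (!is.null(pseudotime)) df$pseudotime <- pseudotime
  cell_annotation(df)
}

# random named gene lists over a shared symbol pool
random_lists <- function(n_lists, max_genes, pool_size = max_genes * 2) {
  pool <- sprintf("g%03d", seq_len(pool_size))
  out <- lapply(seq_len(n_lists), function(i) {
    sample(pool, sample.int(max_genes, 1))
  })
  names(out) <- sprintf("L%d", seq_len(n_lists))
  out
}

# Brute-force oracle for exclusive intersections: enumerate every non-empty
# membership pattern and compute it by set algebra (intersection of the
# included lists minus union of the excluded ones).
brute_exclusive <- function(lists) {
  nm <- names(lists)
  keys <- lapply(lists, function(g) unique(toupper(trimws(g))))
  res <- list()
  for (mask in seq_len(2^length(nm) - 1)) {
    inc <- nm[bitwAnd(mask, 2^(seq_along(nm) - 1)) > 0]
    exc <- setdiff(nm, inc)
    g <- Reduce(intersect, keys[inc])
    if (length(exc)) g <- setdiff(g, Reduce(union, keys[exc]))
    if (length(g)) res[[paste(inc, collapse = "&")]] <- sort(g)
  }
  res
}

# Brute-force oracle for k-of-n consensus: per-gene membership count by
# direct looping over the union.
brute_consensus <- function(lists, k) {
  keys <- lapply(lists, function(g) unique(toupper(trimws(g))))
  uni <- sort(unique(unlist(keys)))
  cnt <- vapply(uni, function(g) {
    sum(vapply(keys, function(s) g %in% s, logical(1)))
  }, integer(1))
  sort(uni[cnt >= k])
}

# small marker table spanning the three fold-change scales
mixed_scale_table <- function() {
  bind_marker_tables(
    marker_table("sLin", "RGL", "NSC", c("A", "B", "C"),
                 fc = c(1.6, 1.5, 2.0), p_adj = c(0.01, 0.01, 0.06),
                 fc_scale = "linear"),
    marker_table("sLog2", "RGL", "NSC", c("D", "E"),
                 fc = c(0.7, 0.5), p_adj = 0.01, fc_scale = "log2"),
    marker_table("sLn", "RGL", "NSC", c("F", "H"),
                 fc = c(0.3, 0.2), p_adj = 0.01, fc_scale = "ln")
  )
}
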