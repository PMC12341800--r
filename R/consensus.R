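# Stage 1-2: marker filtering, gene-list similarity/clustering, exclusive
# intersections, k-of-n consensus signatures.

#' Marker filtering parameters
#'
#' Defaults reproduce the selection criteria applied to the per-study marker
#' lists: linear fold change strictly greater than 1.5 and adjusted p-value
#' strictly below 0.05; studies reporting natural-log fold changes instead
#' use an ln threshold of 0.25.
#'
#' @param fc_min_linear linear fold-change threshold (> 1), strict.
#' @param p_adj_max adjusted p-value ceiling in (0, 1\], strict.
#' @param ln_fc_min ln fold-change threshold applied to studies whose scale
#'   is `"ln"`, strict.
#' @return a list of class `filter_params`.
#' @export
filter_params <- function(fc_min_linear = 1.5, p_adj_max = 0.05,
                          ln_fc_min = 0.25) {
  stopifnot(fc_min_linear > 1, p_adj_max > 0, p_adj_max <= 1)
  structure(list(fc_min_linear = fc_min_linear, p_adj_max = p_adj_max,
                 ln_fc_min = ln_fc_min), class = "filter_params")
}

#' Filter a marker table by fold change and adjusted p-value
#'
#' Retains records with linear fold change `> fc_min_linear` (log2 fold
#' changes are back-transformed with `2^fc` before comparison; natural-log
#' studies are instead thresholded at `fc > ln_fc_min`) AND
#' `p_adj < p_adj_max`. Both inequalities are strict. Records with missing
#' `p_adj` are conservatively dropped. Row order is preserved.
#'
#' @param table a [marker_table()].
#' @param params a [filter_params()].
#' @return the filtered [marker_table()] (possibly empty, with a warning).
#' @export
#' @examples
#' tbl <- marker_table("s1", "RGL", "NSC", c("Fabp7", "Hopx"),
#'                     fc = c(2.0, 1.2), p_adj = 0.01)
#' filter_markers(tbl)$gene
filter_markers <- function(table, params = filter_params()) {
  stopifnot(inherits(table, "marker_table"), inherits(params, "filter_params"))
  fc_pass <- switch_fc_pass(table$fc, table$fc_scale, params)
  p_pass <- !is.na(table$p_adj) & table$p_adj < params$p_adj_max
  out <- table[fc_pass & p_pass, , drop = FALSE]
  if (nrow(out) == 0L) {
    warning("filter_markers: no records pass the thresholds", call. = FALSE)
  }
  class(out) <- c("marker_table", "data.frame")
  out
}

switch_fc_pass <- function(fc, scale, params) {
  pass <- logical(length(fc))
  lin <- scale == "linear"
  l2 <- scale == "log2"
  ln <- scale == "ln"
  pass[lin] <- fc[lin] > params$fc_min_linear
  pass[l2] <- 2^fc[l2] > params$fc_min_linear
  pass[ln] <- fc[ln] > params$ln_fc_min
  pass
}

#' Per-unit gene lists for one cell class
#'
#' Collects, for each counting unit, the genes a (filtered) marker table
#' assigns to the given cell class. With `counting_unit = "study"` (the
#' default, matching consensus counting "in at least k studies") each
#' study contributes one list: the union over all of its clusters of that
#' class. With `"cluster"` every (study, population) pair is its own unit.
#'
#' @param table a filtered [marker_table()].
#' @param cell_class one of NSC, NP, NEUROBLAST, ASTROCYTE, OTHER.
#' @param counting_unit `"study"` or `"cluster"`.
#' @return named list of character vectors (first-seen symbol spellings,
#'   deduplicated case-insensitively). Empty (with a warning) if the class
#'   is absent.
#' @export
gene_lists_by_class <- function(table, cell_class,
                                counting_unit = c("study", "cluster")) {
  counting_unit <- match.arg(counting_unit)
  cell_class <- toupper(cell_class)
  sub <- table[table$cell_class == cell_class, , drop = FALSE]
  if (nrow(sub) == 0L) {
    warning(sprintf("gene_lists_by_class: no %s records", cell_class),
            call. = FALSE)
    return(stats::setNames(list(), character(0)))
  }
  unit <- if (counting_unit == "study") sub$study_id else
    paste(sub$study_id, sub$population_label, sep = ":")
  lists <- split(sub$gene, unit)
  lapply(lists, dedup_symbols, warn = FALSE)
}

#' Pairwise gene-list similarity
#'
#' Computes a square symmetric similarity matrix over named gene lists:
#' `common_count` is the number of shared genes (the literal similarity the
#' cross-study clustering was described with), `jaccard` is
#' intersection/union and `overlap_coeff` is intersection over the smaller
#' list. Gene matching is case-insensitive.
#'
#' @param lists named list (length >= 2) of character vectors.
#' @param metric `"jaccard"` (default), `"common_count"` or `"overlap_coeff"`.
#' @return a symmetric numeric matrix with the list names as dimnames and an
#'   attribute `metric`. Jaccard/overlap values lie in \[0, 1\] with diagonal
#'   1; the common-count diagonal is each list's size. A pair of empty lists
#'   is assigned similarity 0 with a warning.
#' @export
pairwise_similarity <- function(lists,
                                metric = c("jaccard", "common_count",
                                           "overlap_coeff")) {
  metric <- match.arg(metric)
  if (length(lists) < 2L) stop("pairwise_similarity: need at least 2 lists")
  if (is.null(names(lists)) || any(!nzchar(names(lists)))) {
    stop("pairwise_similarity: lists must be named")
  }
  keys <- lapply(lists, function(g) unique(sym_key(g)))
  sizes <- lengths(keys)
  if (any(sizes == 0L)) {
    warning("pairwise_similarity: empty gene list(s): ",
            paste(names(lists)[sizes == 0L], collapse = ", "), call. = FALSE)
  }
  n <- length(keys)
  S <- matrix(0, n, n, dimnames = list(names(lists), names(lists)))
  for (i in seq_len(n)) {
    for (j in i:n) {
      common <- length(intersect(keys[[i]], keys[[j]]))
      uni <- length(union(keys[[i]], keys[[j]]))
      s <- switch(metric,
        common_count = common,
        jaccard = if (uni == 0L) 0 else common / uni,
        overlap_coeff = if (min(sizes[i], sizes[j]) == 0L) 0 else
          common / min(sizes[i], sizes[j])
      )
      S[i, j] <- S[j, i] <- s
    }
  }
  attr(S, "metric") <- metric
  S
}

#' Convert a similarity matrix to a distance matrix
#'
#' `one_minus` (`d = 1 - s`) applies to the \[0, 1\] metrics (jaccard,
#' overlap); `max_minus` (`d = max(S) - s`) applies to raw common-gene
#' counts. The diagonal is forced to zero.
#'
#' @param S similarity matrix from [pairwise_similarity()].
#' @param method `"one_minus"` or `"max_minus"`.
#' @return a symmetric non-negative distance matrix with zero diagonal.
#' @export
similarity_to_distance <- function(S, method = c("one_minus", "max_minus")) {
  method <- match.arg(method)
  metric <- attr(S, "metric") %||% "jaccard"
  if (method == "one_minus" && metric == "common_count") {
    stop("similarity_to_distance: one_minus is invalid for common_count ",
         "similarities (distances would go negative); use max_minus")
  }
  D <- switch(method,
    one_minus = 1 - S,
    max_minus = max(S) - S
  )
  diag(D) <- 0
  attr(D, "metric") <- NULL
  D
}

#' Hierarchically cluster populations from a distance matrix
#'
#' Agglomerative clustering of gene-list distances via [stats::hclust()]
#' (the routine the cross-study dendrogram was built with). Leaf labels are
#' sorted lexicographically before clustering so that equal-height merges
#' resolve deterministically by label order.
#'
#' @param D symmetric distance matrix with zero diagonal, >= 2 leaves.
#' @param linkage `"complete"` (default), `"average"` or `"single"`.
#' @return an [stats::hclust] object.
#' @export
hierarchical_cluster <- function(D, linkage = c("complete", "average",
                                                "single")) {
  linkage <- match.arg(linkage)
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be a square matrix")
  if (nrow(D) < 2L) stop("hierarchical_cluster: need at least 2 leaves")
  if (max(abs(D - t(D))) > 1e-12 || any(abs(diag(D)) > 1e-12)) {
    stop("hierarchical_cluster: D must be symmetric with zero diagonal")
  }
  ord <- c_order(rownames(D) %||% as.character(seq_len(nrow(D))))
  D <- D[ord, ord, drop = FALSE]
  stats::hclust(stats::as.dist(D), method = linkage)
}

#' Export a dendrogram as Newick
#'
#' Branch lengths carry the merge heights (via [ape::as.phylo()]).
#'
#' @param h an [stats::hclust] object.
#' @param path optional output file; if `NULL` the Newick string is returned.
#' @return the Newick string, invisibly when written to `path`.
#' @export
dendrogram_to_newick <- function(h, path = NULL) {
  phy <- ape::as.phylo(h)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Exclusive intersections across gene lists
#'
#' Assigns every gene of the union to exactly one membership pattern: the
#' exact subset of lists containing it (the quantity UpSet plots display).
#' Counts over all patterns therefore sum to the union size.
#'
#' @param lists named list (length >= 1) of character vectors.
#' @return data frame of class `intersection_table` with columns `pattern`
#'   (list names joined by `&`), `degree`, `count` and a list-column `genes`
#'   (first-seen spellings), ordered by decreasing count then pattern.
#' @export
exclusive_intersections <- function(lists) {
  if (length(lists) < 1L) stop("exclusive_intersections: need at least 1 list")
  if (is.null(names(lists)) || any(!nzchar(names(lists)))) {
    stop("exclusive_intersections: lists must be named")
  }
  keys <- lapply(lists, function(g) unique(sym_key(g)))
  # first-seen spelling for every union gene
  all_genes <- unlist(lists, use.names = FALSE)
  all_keys <- sym_key(all_genes)
  spell <- all_genes[!duplicated(all_keys)]
  names(spell) <- all_keys[!duplicated(all_keys)]
  union_keys <- names(spell)
  membership <- vapply(union_keys, function(k) {
    paste(names(lists)[vapply(keys, function(s) k %in% s, logical(1))],
          collapse = "&")
  }, character(1))
  grp <- split(unname(spell), membership)
  out <- data.frame(
    pattern = names(grp),
    degree = lengths(strsplit(names(grp), "&", fixed = TRUE)),
    count = lengths(grp),
    stringsAsFactors = FALSE
  )
  out$genes <- unname(grp)
  ord <- order(-out$count, out$pattern)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("intersection_table", "data.frame")
  out
}

#' Write an intersection table as TSV
#'
#' Genes within a pattern are joined by commas.
#' @param tab an [exclusive_intersections()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_intersection_table <- function(tab, path) {
  out <- data.frame(
    pattern = tab$pattern, degree = tab$degree, count = tab$count,
    genes = vapply(tab$genes, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Extract a k-of-n consensus signature
#'
#' Genes present in at least `min_studies` distinct units (studies, by
#' default). With the seven hippocampal studies this is the operation that
#' yields the 28-gene NSC signature at k = 5, the 62-gene NP signature at
#' k = 3, and the two universally shared NSC genes (Fabp7, Hopx) at k = 7.
#'
#' @param lists named list of character vectors, one per counting unit.
#' @param min_studies minimum number of distinct units a gene must appear in.
#' @param name name for the resulting gene set.
#' @return a [gene_set()] ordered by decreasing unit count then symbol, with
#'   an attribute `support` (named integer vector of per-gene unit counts).
#' @export
consensus_signature <- function(lists, min_studies,
                                name = sprintf("consensus_k%d", min_studies)) {
  if (length(lists) < 1L) stop("consensus_signature: no lists supplied")
  min_studies <- as.integer(min_studies)
  if (min_studies < 1L || min_studies > length(lists)) {
    stop(sprintf("consensus_signature: min_studies (%d) must be in 1..%d",
                 min_studies, length(lists)))
  }
  keys <- lapply(lists, function(g) unique(sym_key(g)))
  all_genes <- unlist(lists, use.names = FALSE)
  all_keys <- sym_key(all_genes)
  spell <- all_genes[!duplicated(all_keys)]
  names(spell) <- all_keys[!duplicated(all_keys)]
  counts <- table(unlist(keys, use.names = FALSE))
  counts <- stats::setNames(as.integer(counts), names(counts))
  hit <- counts[counts >= min_studies]
  if (length(hit) == 0L) {
    warning(sprintf("consensus_signature: no gene reaches %d units",
                    min_studies), call. = FALSE)
    out <- structure(list(name = name, description = "",
                          genes = character(0), subset_label = NULL),
                     class = "gene_set")
    attr(out, "support") <- stats::setNames(integer(0), character(0))
    return(out)
  }
  genes <- unname(spell[names(hit)])
  ord <- c_order(-hit, genes)
  out <- gene_set(name, genes[ord])
  attr(out, "support") <- stats::setNames(unname(hit[ord]), genes[ord])
  out
}
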