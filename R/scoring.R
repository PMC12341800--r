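# Stage 3: per-cluster expression summaries and per-cell signature scores.

#' Signature scoring parameters
#'
#' @param max_rank rank ceiling for the capped-rank module score. Genes
#'   ranking below it are treated as tied at `max_rank + 1`, which makes the
#'   score robust to the long tail of unexpressed genes in sparse single-cell
#'   data. Default 1500, the published default of the rank-score tool the
#'   senescence analysis used.
#' @param cutoff high-score threshold in \[0, 1\]; cells with
#'   `score >= cutoff` are flagged (default 0.4, the stringent senescence
#'   cutoff).
#' @return a list of class `score_params`.
#' @export
score_params <- function(max_rank = 1500L, cutoff = 0.4) {
  max_rank <- as.integer(max_rank)
  stopifnot(max_rank >= 2L, cutoff >= 0, cutoff <= 1)
  structure(list(max_rank = max_rank, cutoff = cutoff), class = "score_params")
}

# Match signature genes to matrix rows case-insensitively; warn about and
# drop the unmatched ones.
match_signature <- function(expr, sig) {
  genes <- as_gene_vector(sig)
  idx <- match(sym_key(genes), sym_key(rownames(expr$values)))
  if (anyNA(idx)) {
    warning(sprintf("%d signature gene(s) absent from the matrix: %s",
                    sum(is.na(idx)),
                    paste(genes[is.na(idx)], collapse = ", ")), call. = FALSE)
  }
  idx[!is.na(idx)]
}

#' Per-cluster expression summaries (dot-plot statistics)
#'
#' For every (gene, cluster) pair: the percentage of the cluster's cells
#' with nonzero expression (dot size) and the mean expression over all of
#' the cluster's cells, zeros included (dot color).
#'
#' @param expr an [expression_matrix()].
#' @param ann a [cell_annotation()] with a `cluster` column covering exactly
#'   the matrix cells.
#' @param genes a [gene_set()] or character vector; genes absent from the
#'   matrix are skipped and reported in the `missing_genes` attribute.
#' @return data frame of class `cluster_summary` with columns `gene`,
#'   `cluster`, `pct_expressed` (in \[0, 100\]) and `mean_expr`.
#' @export
summarize_by_cluster <- function(expr, ann, genes) {
  stopifnot(inherits(expr, "expression_matrix"))
  ann <- align_annotation(expr, ann)
  if (!"cluster" %in% names(ann)) stop("annotation lacks a 'cluster' column")
  requested <- as_gene_vector(genes)
  idx <- match(sym_key(requested), sym_key(rownames(expr$values)))
  missing <- requested[is.na(idx)]
  if (length(missing)) {
    warning("summarize_by_cluster: genes absent from matrix skipped: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  keep <- requested[!is.na(idx)]
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L) stop("summarize_by_cluster: no requested gene found")
  vals <- as.matrix(expr$values[idx, , drop = FALSE])
  rownames(vals) <- keep
  clusters <- c_sort(unique(as.character(ann$cluster)))
  res <- do.call(rbind, lapply(clusters, function(cl) {
    cols <- which(ann$cluster == cl)
    sub <- vals[, cols, drop = FALSE]
    data.frame(
      gene = keep,
      cluster = cl,
      pct_expressed = 100 * rowMeans(sub > 0),
      mean_expr = rowMeans(sub),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }))
  attr(res, "missing_genes") <- missing
  class(res) <- c("cluster_summary", "data.frame")
  res
}

#' Marker specificity of a gene for a target cluster
#'
#' Difference between the percent-expressed in the target cluster and the
#' maximum percent-expressed in any other cluster; +100 for a perfectly
#' exclusive marker, 0 for a uniformly expressed gene. Quantifies the
#' "restricted expression profile" argument behind proposing Ecrg4/Tnc as
#' NSC markers.
#'
#' @param summary a [summarize_by_cluster()] result.
#' @param gene gene symbol (case-insensitive).
#' @param target_cluster cluster label present in `summary`.
#' @return a number in \[-100, 100\].
#' @export
marker_specificity <- function(summary, gene, target_cluster) {
  rows <- summary[sym_key(summary$gene) == sym_key(gene), , drop = FALSE]
  if (nrow(rows) == 0L) stop("marker_specificity: gene not in summary: ", gene)
  if (!target_cluster %in% rows$cluster) {
    stop("marker_specificity: unknown cluster: ", target_cluster)
  }
  target <- rows$pct_expressed[rows$cluster == target_cluster]
  others <- rows$pct_expressed[rows$cluster != target_cluster]
  target - if (length(others)) max(others) else 0
}

score_vector <- function(cell_id, score, method, signature, high_flag = NULL) {
  df <- data.frame(cell_id = cell_id, score = score,
                   stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(high_flag)) df$high_flag <- high_flag
  attr(df, "method") <- method
  attr(df, "signature") <- signature
  class(df) <- c("score_vector", "data.frame")
  df
}

#' Z-score signature score
#'
#' Each signature gene's expression is z-scored across cells (sample
#' standard deviation, n-1 denominator); a cell's score is the mean z over
#' the retained signature genes. This is the statistic used to profile the
#' NSC/NP consensus signatures along pseudotime. Zero-variance genes are
#' dropped with a warning. Scores are computed on the log-normalized layer
#' (raw counts are normalized first, with a message).
#'
#' @param expr an [expression_matrix()].
#' @param sig a [gene_set()] or character vector of symbols.
#' @return a data frame of class `score_vector` with columns `cell_id` and
#'   `score`; attributes `method = "zscore_mean"`, `signature`, and
#'   `dropped_genes` (zero-variance).
#' @export
zscore_signature_score <- function(expr, sig) {
  stopifnot(inherits(expr, "expression_matrix"))
  expr <- ensure_lognorm(expr)
  idx <- match_signature(expr, sig)
  if (length(idx) == 0L) stop("zscore_signature_score: no signature gene matched")
  vals <- as.matrix(expr$values[idx, , drop = FALSE])
  mu <- rowMeans(vals)
  sdv <- apply(vals, 1L, stats::sd)
  zero <- sdv == 0 | !is.finite(sdv)
  dropped <- rownames(expr$values)[idx][zero]
  if (any(zero)) {
    warning("zscore_signature_score: zero-variance gene(s) dropped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (all(zero)) stop("zscore_signature_score: no gene with nonzero variance")
  z <- (vals[!zero, , drop = FALSE] - mu[!zero]) / sdv[!zero]
  out <- score_vector(colnames(expr$values), colMeans(z),
                      method = "zscore_mean", signature = sig_name(sig))
  attr(out, "dropped_genes") <- dropped
  out
}

#' Capped-rank (Mann-Whitney U) signature score
#'
#' For each cell, all genes are ranked by decreasing expression (ties get
#' average ranks); ranks beyond `max_rank` are truncated to `max_rank + 1`,
#' so the bulk of unexpressed genes collapses onto the ceiling. With
#' signature ranks \eqn{r_g} and signature size \eqn{n_s}, the relative
#' Mann-Whitney U statistic gives the score
#' \deqn{1 - \frac{\sum_g r_g - n_s(n_s+1)/2}{n_s \, r_{max}},}
#' clipped to \[0, 1\]: 1 when the signature occupies the top ranks, 0 when
#' every signature gene is at or beyond the ceiling. Being rank-based, the
#' score is invariant to any strictly monotone per-cell transform of the
#' expression values. Cells with `score >= cutoff` are flagged high-scoring.
#'
#' @param expr an [expression_matrix()] (scored on the log-normalized layer;
#'   raw counts are normalized first, which cannot change the ranks).
#' @param sig a [gene_set()] or character vector of symbols.
#' @param params a [score_params()].
#' @return data frame of class `score_vector` with columns `cell_id`,
#'   `score`, `high_flag`; attributes `method = "rank_u"`, `signature`,
#'   `max_rank`, `cutoff` and `n_clipped` (count of clipping events).
#' @export
rank_signature_score <- function(expr, sig, params = score_params()) {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(params, "score_params"))
  expr <- ensure_lognorm(expr)
  idx <- match_signature(expr, sig)
  n_s <- length(idx)
  if (n_s == 0L) stop("rank_signature_score: no signature gene matched")
  if (n_s > params$max_rank) {
    stop(sprintf("rank_signature_score: signature size (%d) exceeds max_rank (%d)",
                 n_s, params$max_rank))
  }
  vals <- as.matrix(expr$values)
  r_max <- params$max_rank
  offset <- n_s * (n_s + 1) / 2
  n_clipped <- 0L
  raw <- vapply(seq_len(ncol(vals)), function(j) {
    r <- rank(-vals[, j], ties.method = "average")
    r[r > r_max] <- r_max + 1
    1 - (sum(r[idx]) - offset) / (n_s * r_max)
  }, numeric(1))
  score <- pmin(1, pmax(0, raw))
  n_clipped <- sum(raw < 0 | raw > 1)
  out <- score_vector(colnames(vals), score, method = "rank_u",
                      signature = sig_name(sig),
                      high_flag = score >= params$cutoff)
  attr(out, "max_rank") <- r_max
  attr(out, "cutoff") <- params$cutoff
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Flag high-scoring cells at a cutoff
#'
#' Re-thresholds a rank-based score vector (`high_flag = score >= cutoff`,
#' inclusive) and, when annotation is supplied, tabulates the fraction of
#' high-scoring cells per annotation group.
#'
#' @param scores a `score_vector` from [rank_signature_score()].
#' @param cutoff threshold in \[0, 1\].
#' @param ann optional [cell_annotation()]; `group` names one of its columns.
#' @param group annotation column to tabulate by (default `"cluster"`).
#' @return `scores` with an updated `high_flag` and, if `ann` was given, an
#'   attribute `group_high_fraction` (named numeric vector) and
#'   `group_high_count`.
#' @export
threshold_cells <- function(scores, cutoff, ann = NULL, group = "cluster") {
  stopifnot(inherits(scores, "score_vector"), cutoff >= 0, cutoff <= 1)
  if (!identical(attr(scores, "method"), "rank_u")) {
    stop("threshold_cells: expects rank-based scores")
  }
  scores$high_flag <- scores$score >= cutoff
  attr(scores, "cutoff") <- cutoff
  if (!is.null(ann)) {
    m <- match(scores$cell_id, ann$cell_id)
    if (anyNA(m)) stop("threshold_cells: cells missing from annotation")
    g <- as.character(ann[[group]][m])
    frac <- tapply(scores$high_flag, g, mean)
    cnt <- tapply(scores$high_flag, g, sum)
    attr(scores, "group_high_fraction") <- stats::setNames(as.numeric(frac),
                                                           names(frac))
    attr(scores, "group_high_count") <- stats::setNames(as.integer(cnt),
                                                        names(cnt))
  }
  scores
}

#' Write a per-cell score table as TSV
#' @param scores a `score_vector`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  utils::write.table(as.data.frame(scores), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
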