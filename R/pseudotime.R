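# Stage 4: signature profiles along pseudotime and module-overlap accounting.

#' Bin a signature score along pseudotime
#'
#' Cells with a pseudotime value are assigned to `n_bins` equal-width bins
#' spanning the observed pseudotime range; the profile is the per-bin mean
#' of the per-cell signature score. Empty bins propagate as `NA`, never as
#' zero. An optional centered rolling mean (window `smooth_window` bins,
#' partial windows at the edges) can smooth the bin means; it is off by
#' default because raw bin means are the reproducible primitive.
#'
#' @param scores a `score_vector` (any method).
#' @param ann a [cell_annotation()] with a `pseudotime` column.
#' @param n_bins number of bins (>= 3; default 50).
#' @param smooth_window optional odd integer window for the rolling mean.
#' @param population optional population/cluster label: profile only cells
#'   whose `cluster` equals it, and record it on the result.
#' @return data frame of class `pseudotime_profile` with columns
#'   `bin_center`, `mean_score`, `n_cells`; attributes `bin_edges`,
#'   `signature`, `population`.
#' @export
profile_signature <- function(scores, ann, n_bins = 50L, smooth_window = NULL,
                              population = NULL) {
  stopifnot(inherits(scores, "score_vector"))
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("profile_signature: n_bins must be >= 2")
  if (!"pseudotime" %in% names(ann)) stop("annotation lacks 'pseudotime'")
  m <- match(scores$cell_id, ann$cell_id)
  if (anyNA(m)) stop("profile_signature: cells missing from annotation")
  t <- ann$pseudotime[m]
  keep <- !is.na(t)
  if (!is.null(population)) {
    keep <- keep & as.character(ann$cluster[m]) == population
  }
  t <- t[keep]
  s <- scores$score[keep]
  if (length(t) == 0L) stop("profile_signature: no cell with pseudotime")
  if (length(t) < 2L) stop("profile_signature: need >= 2 cells with pseudotime")
  rng <- range(t)
  if (rng[1] == rng[2]) stop("profile_signature: constant pseudotime")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- findInterval(t, edges, rightmost.closed = TRUE)
  mean_score <- rep(NA_real_, n_bins)
  n_cells <- integer(n_bins)
  agg_mean <- tapply(s, bin, mean)
  agg_n <- tapply(s, bin, length)
  mean_score[as.integer(names(agg_mean))] <- as.numeric(agg_mean)
  n_cells[as.integer(names(agg_n))] <- as.integer(agg_n)
  if (!is.null(smooth_window)) {
    mean_score <- rolling_mean(mean_score, as.integer(smooth_window))
  }
  out <- data.frame(
    bin_center = (edges[-1] + edges[-length(edges)]) / 2,
    mean_score = mean_score,
    n_cells = n_cells,
    stringsAsFactors = FALSE
  )
  attr(out, "bin_edges") <- edges
  attr(out, "signature") <- attr(scores, "signature")
  attr(out, "population") <- population
  class(out) <- c("pseudotime_profile", "data.frame")
  out
}

# Centered rolling mean over non-NA neighbors; partial windows at the edges.
rolling_mean <- function(x, w) {
  stopifnot(w >= 1L)
  half <- w %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    win <- x[max(1L, i - half):min(n, i + half)]
    if (all(is.na(win))) NA_real_ else mean(win, na.rm = TRUE)
  }, numeric(1))
}

#' Trend statistics of a pseudotime profile
#'
#' Spearman correlation between bin centers and bin mean scores over the
#' non-empty bins, classified as DECREASING / INCREASING when
#' `|rho| >= 0.3` (FLAT otherwise). This is the statistic behind "NSC
#' signatures decline along the trajectory while NP signatures rise".
#'
#' @param profile a [profile_signature()] result with >= 3 non-empty bins.
#' @return list of class `trend_stats` with `spearman_rho`, `direction` and
#'   `n_bins_used`.
#' @export
trend <- function(profile) {
  stopifnot(inherits(profile, "pseudotime_profile"))
  ok <- !is.na(profile$mean_score)
  if (sum(ok) < 3L) stop("trend: need >= 3 non-empty bins")
  x <- profile$bin_center[ok]
  y <- profile$mean_score[ok]
  rho <- if (stats::sd(y) == 0) 0 else
    suppressWarnings(stats::cor(x, y, method = "spearman"))
  direction <- if (rho >= 0.3) "INCREASING" else
    if (rho <= -0.3) "DECREASING" else "FLAT"
  structure(list(spearman_rho = rho, direction = direction,
                 n_bins_used = sum(ok)), class = "trend_stats")
}

#' Overlap of a signature with a gene-module collection
#'
#' Counts how many signature genes fall in each module (case-insensitive
#' symbol match); genes in no module are reported as unassigned. When the
#' modules are disjoint the per-module counts plus the unassigned count
#' partition the signature exactly. Genes belonging to several
#' (non-disjoint) modules are counted in each and listed in
#' `multi_assigned`.
#'
#' @param sig a [gene_set()] or character vector.
#' @param modules a [gene_module_set()] or named list of character vectors.
#' @return list of class `module_overlap` with `counts` (named integer),
#'   `unassigned_count`, `unassigned_genes`, `multi_assigned` and
#'   `signature_size`.
#' @export
module_overlap <- function(sig, modules) {
  if (!inherits(modules, "gene_module_set")) {
    modules <- gene_module_set(modules)
  }
  genes <- dedup_symbols(as_gene_vector(sig), warn = FALSE)
  gkeys <- sym_key(genes)
  mkeys <- lapply(modules$modules, function(m) unique(sym_key(m)))
  inmat <- vapply(mkeys, function(k) gkeys %in% k,
                  logical(length(gkeys)))
  inmat <- matrix(inmat, nrow = length(gkeys),
                  dimnames = list(genes, names(mkeys)))
  counts <- colSums(inmat)
  n_hits <- rowSums(inmat)
  structure(list(
    counts = stats::setNames(as.integer(counts), colnames(inmat)),
    unassigned_count = sum(n_hits == 0L),
    unassigned_genes = genes[n_hits == 0L],
    multi_assigned = genes[n_hits > 1L],
    signature_size = length(genes)
  ), class = "module_overlap")
}

#' Write a pseudotime profile as TSV
#'
#' Columns: `bin_center`, `mean_score`, `n_cells`, `signature`,
#' `population`.
#' @param profile a [profile_signature()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  out <- as.data.frame(profile)
  out$signature <- attr(profile, "signature") %||% NA_character_
  out$population <- attr(profile, "population") %||% NA_character_
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
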