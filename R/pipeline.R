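# End-to-end orchestration: filter -> consensus -> score -> profile.

#' Run the consensus-signature pipeline from a configuration
#'
#' Executes the pipeline stages in order, skipping stages whose inputs are
#' absent from the configuration, and writes a JSON run manifest with
#' package version, parameters and input/output checksums sufficient to
#' re-run identically. All referenced input paths are checked before any
#' computation starts.
#'
#' Configuration (YAML file or equivalent nested list):
#' \preformatted{
#' out_dir: results/
#' markers:
#'   path: markers.tsv          # written by write_marker_table()
#' filter: {fc_min_linear: 1.5, p_adj_max: 0.05, ln_fc_min: 0.25}
#' consensus:
#'   counting_unit: study       # or cluster
#'   metric: jaccard            # jaccard | common_count | overlap_coeff
#'   distance: one_minus        # one_minus | max_minus
#'   linkage: complete
#'   classes:
#'     NSC: {min_studies: 5}
#'     NP:  {min_studies: 3}
#' expression:
#'   mtx: counts.mtx            # with genes/cells id files, or dense: x.tsv
#'   genes: genes.txt
#'   cells: cells.txt
#'   annotation: cells_meta.tsv
#' scoring:
#'   signature_gmt: sets.gmt
#'   method: rank               # rank | zscore
#'   max_rank: 1500
#'   cutoff: 0.4
#' profile: {n_bins: 50}
#' }
#'
#' @param config path to a YAML file or a nested list as above.
#' @return the run manifest (also written to `out_dir/manifest.json`),
#'   invisibly: a list with `package`, `version`, `config`, `inputs`
#'   (md5 checksums) and `outputs` (paths and md5 checksums).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  inputs <- pipeline_inputs(config)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing)) {
    stop("run_pipeline: missing input file(s): ",
         paste(missing, collapse = ", "))
  }
  outputs <- character(0)
  note <- function(path) outputs <<- c(outputs, path)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  if (!is.null(config$markers)) {
    stage("filter+consensus", {
      markers <- read_marker_table(config$markers$path,
                                   fc_scale = config$markers$fc_scale %||% "linear")
      fp <- do.call(filter_params, config$filter %||% list())
      filtered <- filter_markers(markers, fp)
      note(write_marker_table(filtered, file.path(out_dir, "markers_filtered.tsv")))
      cons <- config$consensus %||% list()
      unit <- cons$counting_unit %||% "study"
      metric <- cons$metric %||% "jaccard"
      dist_method <- cons$distance %||%
        if (metric == "common_count") "max_minus" else "one_minus"
      linkage <- cons$linkage %||% "complete"
      classes <- cons$classes %||% list(NSC = list(min_studies = 5L))
      for (cl in names(classes)) {
        lists <- gene_lists_by_class(filtered, cl, counting_unit = unit)
        if (length(lists) == 0L) next
        k <- classes[[cl]]$min_studies %||% length(lists)
        sig <- consensus_signature(lists, min_studies = k,
                                   name = sprintf("%s_consensus_k%d", cl, k))
        note(write_gmt(sig, file.path(out_dir, sprintf("%s_consensus.gmt", cl))))
        note(write_intersection_table(
          exclusive_intersections(lists),
          file.path(out_dir, sprintf("%s_upset.tsv", cl))))
        if (length(lists) >= 2L) {
          S <- pairwise_similarity(lists, metric = metric)
          h <- hierarchical_cluster(similarity_to_distance(S, dist_method),
                                    linkage = linkage)
          nwk <- file.path(out_dir, sprintf("%s_dendrogram.nwk", cl))
          dendrogram_to_newick(h, nwk)
          note(nwk)
        }
      }
    })
  }

  scores_by_sig <- list()
  if (!is.null(config$expression) && !is.null(config$scoring)) {
    stage("scoring", {
      ex <- config$expression
      expr <- if (!is.null(ex$dense)) {
        read_expression_dense(ex$dense, layer = ex$layer %||% "counts")
      } else {
        read_expression_mtx(ex$mtx, ex$genes, ex$cells,
                            layer = ex$layer %||% "counts")
      }
      ann <- read_cell_annotation(ex$annotation)
      sets <- read_gmt(config$scoring$signature_gmt)
      method <- config$scoring$method %||% "rank"
      sp <- score_params(max_rank = config$scoring$max_rank %||% 1500L,
                         cutoff = config$scoring$cutoff %||% 0.4)
      for (sig in sets) {
        sc <- if (method == "rank") {
          threshold_cells(rank_signature_score(expr, sig, sp), sp$cutoff, ann)
        } else {
          zscore_signature_score(expr, sig)
        }
        scores_by_sig[[sig$name]] <- sc
        note(write_scores(sc, file.path(out_dir,
                                        sprintf("scores_%s.tsv", sig$name))))
      }
    })
  }

  if (!is.null(config$profile) && length(scores_by_sig)) {
    stage("profile", {
      ann <- read_cell_annotation(config$expression$annotation)
      if (!"pseudotime" %in% names(ann) || all(is.na(ann$pseudotime))) {
        stop("profile stage requested but annotation carries no pseudotime")
      }
      n_bins <- config$profile$n_bins %||% 50L
      for (nm in names(scores_by_sig)) {
        prof <- profile_signature(scores_by_sig[[nm]], ann, n_bins = n_bins,
                                  smooth_window = config$profile$smooth_window)
        note(write_profile(prof, file.path(out_dir,
                                           sprintf("profile_%s.tsv", nm))))
      }
    })
  }

  manifest <- list(
    package = "consig",
    version = as.character(utils::packageVersion("consig")),
    config = config,
    inputs = as.list(tools::md5sum(inputs)),
    outputs = as.list(tools::md5sum(unique(outputs)))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

# All input paths a configuration references.
pipeline_inputs <- function(config) {
  paths <- c(
    config$markers$path,
    config$expression$mtx, config$expression$genes, config$expression$cells,
    config$expression$dense, config$expression$annotation,
    config$scoring$signature_gmt
  )
  unlist(paths, use.names = FALSE)
}
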