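# Synthetic marker lists and expression data with planted ground truth.

#' Configuration for simulated per-study marker lists
#'
#' Emulates the structure of the seven-study comparison: for each cell
#' class, a small core of genes shared by many studies and a large remainder
#' private to single studies, plus decoy records that fail the
#' fold-change/p-value filter. Defaults mirror the real comparison's scale:
#' 7 studies; a 28-gene NSC core carried by at least 5 studies of which 2
#' genes by all 7; a 62-gene NP core carried by at least 3 studies of which
#' 10 by all 7; a 20-gene neuroblast core; 200 private genes per study and
#' class.
#'
#' @param n_studies number of studies (default 7).
#' @param classes named list (names = cell classes) of per-class plans, each
#'   a list with `core_size`, `n_all` (core genes planted in every study),
#'   `presence_range` (length-2 integer range for the remaining core genes'
#'   study counts), and optionally `presence` (explicit per-gene study
#'   counts overriding the former two).
#' @param private_size private (study-exclusive) genes per study per class.
#' @param decoy_size decoy records per study per class, drawn to fail the
#'   default filter.
#' @param seed integer seed; identical seeds give byte-identical output.
#' @return a list of class `marker_sim_config`.
#' @export
marker_sim_config <- function(
    n_studies = 7L,
    classes = list(
      NSC = list(core_size = 28L, n_all = 2L, presence_range = c(5L, 6L)),
      NP = list(core_size = 62L, n_all = 10L, presence_range = c(3L, 6L)),
      NEUROBLAST = list(core_size = 20L, n_all = 4L, presence_range = c(3L, 6L))
    ),
    private_size = 200L,
    decoy_size = 60L,
    seed = 1L) {
  n_studies <- as.integer(n_studies)
  stopifnot(n_studies >= 1L, private_size >= 0L, decoy_size >= 0L)
  for (cl in names(classes)) {
    plan <- classes[[cl]]
    if (!is.null(plan[["presence"]])) {
      if (length(plan[["presence"]]) != plan$core_size) {
        stop("marker_sim_config: presence vector length != core_size for ", cl)
      }
      if (any(plan[["presence"]] > n_studies) || any(plan[["presence"]] < 1L)) {
        stop("marker_sim_config: presence outside 1..n_studies for ", cl)
      }
    } else {
      if (plan$n_all > plan$core_size) {
        stop("marker_sim_config: n_all > core_size for ", cl)
      }
      if (max(plan$presence_range) > n_studies) {
        stop("marker_sim_config: core presence exceeds n_studies for ", cl)
      }
    }
  }
  structure(list(n_studies = n_studies, classes = classes,
                 private_size = as.integer(private_size),
                 decoy_size = as.integer(decoy_size),
                 seed = as.integer(seed)),
            class = "marker_sim_config")
}

#' Simulate per-study marker lists with a planted shared core
#'
#' Generates a [marker_table()] over `n_studies` synthetic studies. Core
#' genes are planted in exactly their configured number of studies; private
#' genes appear in exactly one study; decoy records carry fold changes or
#' adjusted p-values that fail the default [filter_params()]. Planted (core
#' and private) records are drawn to pass it. One study reports natural-log
#' fold changes and one reports log2 fold changes, exercising the scale
#' handling; the rest are linear. Deterministic given `cfg$seed`.
#'
#' @param cfg a [marker_sim_config()].
#' @return list with `markers` (a [marker_table()]) and `truth`, a list with
#'   per-class data frames (`gene`, `presence`, `studies`) describing the
#'   planted cores and the per-study private gene lists.
#' @export
simulate_marker_lists <- function(cfg = marker_sim_config()) {
  stopifnot(inherits(cfg, "marker_sim_config"))
  set.seed(cfg$seed)
  studies <- sprintf("study%d", seq_len(cfg$n_studies))
  scales <- rep("linear", cfg$n_studies)
  if (cfg$n_studies >= 1L) scales[1L] <- "ln"
  if (cfg$n_studies >= 2L) scales[2L] <- "log2"
  names(scales) <- studies

  gene_counter <- 0L
  next_genes <- function(n) {
    ids <- sprintf("G%06d", gene_counter + seq_len(n))
    gene_counter <<- gene_counter + n
    ids
  }
  passing_fc <- function(scale, n) {
    switch(scale,
      linear = stats::runif(n, 1.6, 6),
      log2 = stats::runif(n, log2(1.7), 3),
      ln = stats::runif(n, 0.3, 2))
  }
  failing_fc <- function(scale, n) {
    switch(scale,
      linear = stats::runif(n, 1.0, 1.49),
      log2 = stats::runif(n, 0, log2(1.49)),
      ln = stats::runif(n, 0, 0.24))
  }

  rows <- list()
  truth <- list(core = list(), private = list())
  add_rows <- function(study, class, genes, fc, p_adj) {
    rows[[length(rows) + 1L]] <<- data.frame(
      study_id = study,
      population_label = paste0(class, "_cluster"),
      cell_class = class, gene = genes, fc = fc, p_adj = p_adj,
      fc_scale = scales[[study]], stringsAsFactors = FALSE)
  }

  for (cl in names(cfg$classes)) {
    plan <- cfg$classes[[cl]]
    core <- next_genes(plan$core_size)
    presence <- plan[["presence"]] %||% c(
      rep(cfg$n_studies, plan$n_all),
      if (plan$core_size > plan$n_all)
        sample(seq(plan$presence_range[1], plan$presence_range[2]),
               plan$core_size - plan$n_all, replace = TRUE)
    )
    membership <- lapply(presence, function(k) sort(sample(cfg$n_studies, k)))
    truth$core[[cl]] <- data.frame(
      gene = core, presence = as.integer(presence),
      studies = vapply(membership, function(ix)
        paste(studies[ix], collapse = ";"), character(1)),
      stringsAsFactors = FALSE)
    for (s in seq_along(studies)) {
      planted <- core[vapply(membership, function(ix) s %in% ix, logical(1))]
      priv <- next_genes(cfg$private_size)
      truth$private[[paste(cl, studies[s], sep = ".")]] <- priv
      genes <- c(planted, priv)
      if (length(genes)) {
        add_rows(studies[s], cl, genes,
                 fc = passing_fc(scales[[s]], length(genes)),
                 p_adj = stats::runif(length(genes), 1e-6, 0.049))
      }
      if (cfg$decoy_size > 0L) {
        dec <- next_genes(cfg$decoy_size)
        n_lowfc <- ceiling(cfg$decoy_size / 2)
        fc <- c(failing_fc(scales[[s]], n_lowfc),
                passing_fc(scales[[s]], cfg$decoy_size - n_lowfc))
        p_adj <- c(stats::runif(n_lowfc, 1e-6, 0.049),
                   stats::runif(cfg$decoy_size - n_lowfc, 0.051, 1))
        add_rows(studies[s], cl, dec, fc, p_adj)
      }
    }
  }
  df <- do.call(rbind, rows)
  validate_marker_table(df)
  class(df) <- c("marker_table", "data.frame")
  list(markers = df, truth = truth)
}

#' Configuration for simulated expression data
#'
#' Emulates a linear differentiation trajectory: each cell carries a latent
#' pseudotime t ~ Uniform(0, 1); a "quiescence" program declines with t, an
#' "activation" program rises, and a senescence program (FLAT trend, reduced
#' baseline) is multiplicatively upregulated in a planted senescent
#' subpopulation. Counts are negative binomial with a single global
#' dispersion.
#'
#' @param n_cells,n_genes matrix dimensions (defaults 2000 x 2000).
#' @param programs list of program descriptors: `name`, `size`, `trend`
#'   (`"DECREASING"`, `"INCREASING"`, `"FLAT"`), `amplitude` (trend strength
#'   a; the per-gene mean is `baseline * (1 + a*(1-t))` for DECREASING,
#'   `baseline * (1 + a*t)` for INCREASING), and optional `baseline_factor`
#'   (multiplier on the global baseline mean; the senescence program
#'   defaults to 0.25, as SASP genes are largely silent outside senescent
#'   cells). Program gene sets are disjoint by construction.
#' @param nb_dispersion negative-binomial size parameter (> 0).
#' @param baseline_mean global baseline mean count (> 0).
#' @param senescent_fraction fraction of cells planted senescent in \[0, 1\].
#' @param senescence_shift multiplicative mean shift on senescence-program
#'   genes in senescent cells (> 0).
#' @param senescence_program name of the program treated as the senescence
#'   gene set.
#' @param seed integer seed.
#' @return a list of class `expr_sim_config`.
#' @export
expr_sim_config <- function(
    n_cells = 2000L, n_genes = 2000L,
    programs = list(
      list(name = "quiescence", size = 50L, trend = "DECREASING",
           amplitude = 5),
      list(name = "activation", size = 50L, trend = "INCREASING",
           amplitude = 5),
      list(name = "senescence", size = 125L, trend = "FLAT", amplitude = 0,
           baseline_factor = 0.25)
    ),
    nb_dispersion = 2, baseline_mean = 2,
    senescent_fraction = 0.2, senescence_shift = 4,
    senescence_program = "senescence", seed = 1L) {
  stopifnot(n_cells >= 1L, n_genes >= 1L, nb_dispersion > 0,
            baseline_mean > 0, senescent_fraction >= 0,
            senescent_fraction <= 1, senescence_shift > 0)
  total <- sum(vapply(programs, function(p) as.integer(p$size), integer(1)))
  if (total > n_genes) stop("expr_sim_config: program genes exceed n_genes")
  nm <- vapply(programs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("expr_sim_config: duplicate program names")
  for (p in programs) {
    if (!p$trend %in% c("DECREASING", "INCREASING", "FLAT")) {
      stop("expr_sim_config: unknown trend ", p$trend)
    }
  }
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 programs = programs, nb_dispersion = nb_dispersion,
                 baseline_mean = baseline_mean,
                 senescent_fraction = senescent_fraction,
                 senescence_shift = senescence_shift,
                 senescence_program = senescence_program,
                 seed = as.integer(seed)),
            class = "expr_sim_config")
}

#' Simulate an expression matrix with planted trajectory and senescence
#'
#' Draws per-cell pseudotime, assigns disjoint program gene sets, computes
#' per-gene per-cell negative-binomial means from the program trends,
#' multiplies senescence-program means by `senescence_shift` in the planted
#' senescent cells, and samples counts. A log1p-CP10K layer is emitted
#' alongside the counts. Deterministic given `cfg$seed`.
#'
#' @param cfg an [expr_sim_config()].
#' @return list with `counts` and `lognorm` ([expression_matrix()] objects),
#'   `annotation` (a [cell_annotation()] with `cluster` = SEN/NORM,
#'   `pseudotime`), and `truth` (program gene sets as a named list, the
#'   senescent flag vector, and the pseudotime vector).
#' @export
simulate_expression <- function(cfg = expr_sim_config()) {
  stopifnot(inherits(cfg, "expr_sim_config"))
  set.seed(cfg$seed)
  genes <- sprintf("G%06d", seq_len(cfg$n_genes))
  cells <- sprintf("cell%05d", seq_len(cfg$n_cells))
  t <- stats::runif(cfg$n_cells)
  n_sen <- floor(cfg$senescent_fraction * cfg$n_cells)
  senescent <- logical(cfg$n_cells)
  if (n_sen > 0L) senescent[sample(cfg$n_cells, n_sen)] <- TRUE

  # assign disjoint program gene blocks from the front of the gene list
  program_genes <- list()
  cursor <- 0L
  for (p in cfg$programs) {
    program_genes[[p$name]] <- genes[cursor + seq_len(p$size)]
    cursor <- cursor + p$size
  }

  # per-gene per-cell mean matrix
  mu <- matrix(cfg$baseline_mean, nrow = cfg$n_genes, ncol = cfg$n_cells,
               dimnames = list(genes, cells))
  for (p in cfg$programs) {
    idx <- match(program_genes[[p$name]], genes)
    fac <- switch(p$trend,
      DECREASING = 1 + p$amplitude * (1 - t),
      INCREASING = 1 + p$amplitude * t,
      FLAT = rep(1, cfg$n_cells))
    base <- cfg$baseline_mean * (p$baseline_factor %||% 1)
    mu[idx, ] <- base * matrix(fac, nrow = length(idx), ncol = cfg$n_cells,
                               byrow = TRUE)
  }
  sen_genes <- program_genes[[cfg$senescence_program]]
  if (!is.null(sen_genes) && any(senescent)) {
    idx <- match(sen_genes, genes)
    mu[idx, senescent] <- mu[idx, senescent] * cfg$senescence_shift
  }

  counts <- matrix(
    stats::rnbinom(length(mu), mu = as.vector(mu), size = cfg$nb_dispersion),
    nrow = cfg$n_genes, dimnames = list(genes, cells))
  em <- expression_matrix(counts, layer = "counts")
  ann <- cell_annotation(data.frame(
    cell_id = cells,
    cluster = ifelse(senescent, "SEN", "NORM"),
    study_id = "simulated",
    pseudotime = t,
    stringsAsFactors = FALSE))
  list(
    counts = em,
    lognorm = suppressMessages(normalize_log1p_cpm(em)),
    annotation = ann,
    truth = list(programs = program_genes, senescent = senescent,
                 pseudotime = t)
  )
}
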