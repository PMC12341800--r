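# Per-study differential-expression marker tables.

CELL_CLASSES <- c("NSC", "NP", "NEUROBLAST", "ASTROCYTE", "OTHER")
FC_SCALES <- c("linear", "log2", "ln")

#' Construct a marker table
#'
#' A marker table holds per-study differential-expression records: one row
#' per (study, population, gene) with a fold change on a declared scale and
#' an adjusted p-value. It is the raw material of the cross-study comparison.
#'
#' @param study_id,population_label,cell_class,gene,fc,p_adj,fc_scale
#'   equal-length vectors (recycled scalars allowed). `cell_class` must be one
#'   of `r paste(CELL_CLASSES, collapse = ", ")` (case-insensitive);
#'   `fc_scale` one of linear/log2/ln, constant within each study; `p_adj`
#'   in \[0, 1\] or `NA`.
#' @return a data frame of class `marker_table` with those seven columns.
#' @export
marker_table <- function(study_id, population_label, cell_class, gene,
                         fc, p_adj = NA_real_, fc_scale = "linear") {
  df <- data.frame(
    study_id = as.character(study_id),
    population_label = as.character(population_label),
    cell_class = toupper(as.character(cell_class)),
    gene = trimws(as.character(gene)),
    fc = as.numeric(fc),
    p_adj = as.numeric(p_adj),
    fc_scale = tolower(as.character(fc_scale)),
    stringsAsFactors = FALSE
  )
  validate_marker_table(df)
  class(df) <- c("marker_table", "data.frame")
  df
}

validate_marker_table <- function(df) {
  if (any(!nzchar(df$gene))) stop("marker_table: empty gene symbol")
  if (any(!nzchar(df$study_id))) stop("marker_table: empty study_id")
  bad_class <- setdiff(unique(df$cell_class), CELL_CLASSES)
  if (length(bad_class)) {
    stop("marker_table: unknown cell_class: ", paste(bad_class, collapse = ", "))
  }
  bad_scale <- setdiff(unique(df$fc_scale), FC_SCALES)
  if (length(bad_scale)) {
    stop("marker_table: unknown fc_scale: ", paste(bad_scale, collapse = ", "))
  }
  # one fold-change scale per study
  per_study <- tapply(df$fc_scale, df$study_id, function(x) length(unique(x)))
  if (any(per_study > 1L)) {
    stop("marker_table: mixed fc_scale within study: ",
         paste(names(per_study)[per_study > 1L], collapse = ", "))
  }
  key <- paste(df$study_id, df$population_label, sym_key(df$gene), sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), , drop = FALSE]
    stop("marker_table: duplicate (study, population, gene) records, e.g. ",
         paste(dup$study_id[1], dup$population_label[1], dup$gene[1]))
  }
  if (any(!is.na(df$p_adj) & (df$p_adj < 0 | df$p_adj > 1))) {
    stop("marker_table: p_adj outside [0, 1]")
  }
  if (any(!is.finite(df$fc))) stop("marker_table: non-finite fold change")
  invisible(df)
}

#' Read a marker table from delimited text
#'
#' Expects a header with columns for study, population, cell class, gene,
#' fold change and adjusted p-value; names are configurable through
#' `col_map`. Rows whose fold change cannot be parsed as a number are
#' rejected with their line numbers reported; a missing/`NA` adjusted
#' p-value is kept as `NA` with a warning (such records fail every
#' p-threshold during filtering).
#'
#' @param path delimited text file.
#' @param fc_scale scale of the fold-change column for every record in the
#'   file ("linear", "log2" or "ln"). Ignored (with per-row values used
#'   instead) when the file itself carries an `fc_scale` column, as files
#'   written by [write_marker_table()] do.
#' @param delim field delimiter (default tab).
#' @param col_map named list mapping the canonical names `study`,
#'   `population`, `class`, `gene`, `fc`, `p_adj` to header names in the file.
#' @return a [marker_table()].
#' @export
read_marker_table <- function(path, fc_scale = "linear", delim = "\t",
                              col_map = list()) {
  cmap <- utils::modifyList(
    list(study = "study", population = "population", class = "class",
         gene = "gene", fc = "fc", p_adj = "p_adj"),
    col_map
  )
  raw <- utils::read.delim(path, sep = delim, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", fileEncoding = "UTF-8")
  missing_cols <- setdiff(unlist(cmap), names(raw))
  if (length(missing_cols)) {
    stop(sprintf("read_marker_table: missing mandatory column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  fc_num <- suppressWarnings(as.numeric(raw[[cmap$fc]]))
  bad <- is.na(fc_num)
  if (any(bad)) {
    warning(sprintf(
      "read_marker_table: %d row(s) with unparseable fold change rejected (file lines: %s)",
      sum(bad), paste(which(bad) + 1L, collapse = ", ")), call. = FALSE)
    raw <- raw[!bad, , drop = FALSE]
    fc_num <- fc_num[!bad]
  }
  p_num <- suppressWarnings(as.numeric(raw[[cmap$p_adj]]))
  if (anyNA(p_num)) {
    warning(sprintf(
      "read_marker_table: %d record(s) with missing p_adj kept (treated as failing any p-threshold)",
      sum(is.na(p_num))), call. = FALSE)
  }
  scale_col <- if ("fc_scale" %in% names(raw)) raw$fc_scale else fc_scale
  marker_table(
    study_id = raw[[cmap$study]],
    population_label = raw[[cmap$population]],
    cell_class = raw[[cmap$class]],
    gene = raw[[cmap$gene]],
    fc = fc_num,
    p_adj = p_num,
    fc_scale = scale_col
  )
}

#' Write a marker table to tab-delimited text
#'
#' Writes all seven columns (including `fc_scale`), so that
#' [read_marker_table()] round-trips the table exactly.
#'
#' @param table a [marker_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_marker_table <- function(table, path) {
  cols <- c("study_id", "population_label", "cell_class", "gene",
            "fc", "p_adj", "fc_scale")
  out <- as.data.frame(table)[, cols]
  names(out) <- c("study", "population", "class", "gene", "fc", "p_adj",
                  "fc_scale")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Combine marker tables from several studies
#'
#' @param ... `marker_table` objects.
#' @return a single validated [marker_table()].
#' @export
bind_marker_tables <- function(...) {
  df <- do.call(rbind, lapply(list(...), as.data.frame))
  validate_marker_table(df)
  class(df) <- c("marker_table", "data.frame")
  df
}
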