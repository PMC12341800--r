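# Gene sets and gene-module collections (GMT I/O).

#' Construct a gene set
#'
#' A named, ordered collection of unique gene symbols, optionally carrying a
#' per-gene subset label (e.g. the SenMayo senescence list tags each of its
#' 125 genes as a SASP factor, a transmembrane protein or an intracellular
#' protein). Duplicate symbols (case-insensitive after trimming) are dropped
#' with a warning, keeping the first-seen spelling.
#'
#' @param name set name (non-empty string).
#' @param genes character vector of gene symbols (non-empty).
#' @param description free-text description (GMT column 2).
#' @param subset_label optional character vector, one tag per gene.
#' @return an object of class `gene_set` with elements `name`, `description`,
#'   `genes` and (optionally) `subset_label`.
#' @export
#' @examples
#' gene_set("NSC_core", c("Fabp7", "Hopx"))
gene_set <- function(name, genes, description = "", subset_label = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  genes <- trimws(as.character(genes))
  if (length(genes) == 0L || any(!nzchar(genes))) {
    stop("gene_set: 'genes' must be a non-empty vector of non-empty symbols")
  }
  if (!is.null(subset_label)) {
    stopifnot(length(subset_label) == length(genes))
    subset_label <- as.character(subset_label)
  }
  keep <- !duplicated(sym_key(genes))
  if (!all(keep)) {
    warning(sprintf("gene_set '%s': %d duplicate symbol(s) dropped", name,
                    sum(!keep)), call. = FALSE)
    genes <- genes[keep]
    if (!is.null(subset_label)) subset_label <- subset_label[keep]
  }
  structure(
    list(name = name, description = description, genes = genes,
         subset_label = subset_label),
    class = "gene_set"
  )
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$name, length(x$genes)))
  shown <- utils::head(x$genes, 10L)
  cat(" ", paste(shown, collapse = ", "),
      if (length(x$genes) > 10L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

# Accept either a gene_set or a bare character vector.
as_gene_vector <- function(sig) {
  if (inherits(sig, "gene_set")) sig$genes else trimws(as.character(sig))
}

sig_name <- function(sig, default = "signature") {
  if (inherits(sig, "gene_set")) sig$name else default
}

#' Construct a gene-module collection
#'
#' An ordered list of named gene sets (e.g. the age-conserved transcriptional
#' modules of NSC aging, Modules 1-4). When `disjoint = TRUE` the modules are
#' required to be pairwise non-overlapping (case-insensitive symbol match).
#'
#' @param modules named list of character vectors or `gene_set` objects.
#' @param disjoint logical; enforce that no gene appears in two modules.
#' @return an object of class `gene_module_set`.
#' @export
gene_module_set <- function(modules, disjoint = FALSE) {
  stopifnot(is.list(modules), length(modules) >= 1L)
  nm <- names(modules)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm)) {
    stop("gene_module_set: modules must have unique non-empty names")
  }
  modules <- lapply(modules, as_gene_vector)
  if (disjoint) {
    keys <- unlist(lapply(modules, sym_key), use.names = FALSE)
    if (anyDuplicated(keys)) {
      stop("gene_module_set: modules are not disjoint (shared gene symbols)")
    }
  }
  structure(list(modules = modules, disjoint = disjoint),
            class = "gene_module_set")
}

#' Read gene sets from a GMT file
#'
#' Standard Broad-dialect GMT: one set per line, tab-separated
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a
#' set are deduplicated with a warning.
#'
#' @param path path to a GMT file.
#' @return named list of [gene_set()] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop(sprintf("read_gmt: line %d has %d field(s); at least 3 required",
                   i, length(fields)))
    }
    sets[[i]] <- gene_set(fields[[1]], fields[-(1:2)],
                          description = fields[[2]])
  }
  names(sets) <- vapply(sets, function(s) s$name, character(1))
  sets
}

#' Write gene sets to a GMT file
#'
#' Inverse of [read_gmt()]: writing then reading is the identity on set
#' names and gene order.
#'
#' @param sets a `gene_set` or list of `gene_set` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s) {
    paste(c(s$name, s$description %||% "", s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
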