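# Shared helpers.

#' Normalize gene symbols for matching
#'
#' Symbols are matched case-insensitively after trimming whitespace, but
#' stored and reported with their first-seen spelling. No alias or ortholog
#' resolution is performed: cross-study comparisons are on symbols verbatim,
#' so aliasing would silently change intersection counts.
#'
#' @param x character vector of gene symbols.
#' @return character vector of normalized matching keys.
#' @keywords internal
sym_key <- function(x) toupper(trimws(as.character(x)))

# Deduplicate symbols case-insensitively, keeping first-seen spelling.
# Returns the deduplicated vector; warns via `context` when symbols merge.
dedup_symbols <- function(x, context = NULL, warn = TRUE) {
  x <- trimws(as.character(x))
  key <- sym_key(x)
  dup <- duplicated(key)
  if (any(dup) && warn) {
    warning(sprintf(
      "%sduplicate gene symbols merged case-insensitively: %s",
      if (is.null(context)) "" else paste0(context, ": "),
      paste(unique(x[dup]), collapse = ", ")
    ), call. = FALSE)
  }
  x[!dup]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable lexicographic sort independent of the user's locale.
c_sort <- function(x, decreasing = FALSE) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
  Sys.setlocale("LC_COLLATE", "C")
  sort(x, decreasing = decreasing)
}

c_order <- function(...) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
  Sys.setlocale("LC_COLLATE", "C")
  order(...)
}
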