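#' Read pathway gene sets in GMT format
#'
#' One pathway per line: name, description/source id, then gene symbols,
#' tab-separated. Duplicate symbols within a set are collapsed with a
#' warning; empty sets are an error.
#'
#' @param path GMT file.
#' @return named list of pathway sets; each element is a character vector of
#'   gene symbols with a `source` attribute holding the description field.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT set '", f[1], "' has no genes")
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("GMT set '", f[1], "' has no genes")
    if (anyDuplicated(genes)) {
      warning("duplicate genes in set '", f[1], "' collapsed")
      genes <- unique(genes)
    }
    out[[f[1]]] <- structure(genes, source = f[2])
  }
  out
}

#' Write pathway gene sets in GMT format
#'
#' @param sets named list of character vectors (optionally with a `source`
#'   attribute, written as the description field).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    src <- attr(sets[[nm]], "source")
    if (is.null(src)) src <- nm
    paste(c(nm, src, as.character(sets[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
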