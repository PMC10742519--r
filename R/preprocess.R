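#' Remove unreliable probes from a probe table
#'
#' A hybridized spot whose foreground fluorescence is less than `ratio` times
#' its background in *any* profiled sample is eliminated from the analysis of
#' all samples, so that every sample retains the identical probe set. Genes
#' losing all of their probes are dropped entirely.
#'
#' @param raw probe table data.frame (see [read_probe_table()]).
#' @param ratio quality threshold on fg/bg; the conventional value is 2.
#' @return the filtered probe table.
#' @export
filter_probes <- function(raw, ratio = 2.0) {
  stopifnot(is.data.frame(raw),
            all(c("probe_id", "gene", "condition", "replica", "fg", "bg")
                %in% names(raw)))
  bad <- unique(raw$probe_id[raw$fg < ratio * raw$bg])
  out <- raw[!(raw$probe_id %in% bad), , drop = FALSE]
  if (nrow(out) == 0L)
    stop("no probes survive the fg >= ", ratio, " x bg filter")
  rownames(out) <- NULL
  out
}

#' Normalize a filtered probe table to the median gene of each sample
#'
#' For every sample (condition x replica), net fluorescence `fg - bg` is
#' floored at a small positive value, summed over the redundant spots of each
#' gene, and the per-sample scale is chosen so that the median of the
#' gene-level values equals 1. Values above 1 therefore mark genes expressed
#' above the sample's median gene. Spot-level normalized values are retained
#' (divided by the same scale) because the variability estimator pools them.
#'
#' @param filtered probe table that passed [filter_probes()].
#' @return an object of class `gfp_eset` with components:
#'   \describe{
#'     \item{a}{numeric matrix, genes x samples, of aggregated normalized
#'       expression.}
#'     \item{spots}{list per gene: matrix (spots x samples) of normalized
#'       net spot values.}
#'     \item{samples}{data.frame with `condition` and `replica` per column
#'       of `a`.}
#'     \item{upsilon}{named integer vector of spot counts per gene.}
#'   }
#' @export
normalize_probes <- function(filtered) {
  samp_key <- paste(filtered$condition, filtered$replica, sep = ".")
  samples <- unique(filtered[c("condition", "replica")])
  samples <- samples[order(match(samples$condition,
                                 unique(filtered$condition)),
                           samples$replica), , drop = FALSE]
  rownames(samples) <- NULL
  skeys <- paste(samples$condition, samples$replica, sep = ".")

  genes <- sort(unique(filtered$gene))
  if (length(genes) < 2L)
    stop("need at least 2 genes per sample to define the median gene")
  ups <- tapply(filtered$probe_id, filtered$gene,
                function(p) length(unique(p)))
  ups <- as.integer(ups[genes])
  names(ups) <- genes

  a <- matrix(NA_real_, length(genes), length(skeys),
              dimnames = list(genes, skeys))
  spot_store <- lapply(seq_along(genes), function(i)
    matrix(NA_real_, ups[i], length(skeys),
           dimnames = list(NULL, skeys)))
  names(spot_store) <- genes

  for (s in seq_along(skeys)) {
    sub <- filtered[samp_key == skeys[s], , drop = FALSE]
    sub <- sub[order(sub$gene, sub$probe_id), , drop = FALSE]
    net <- sub$fg - sub$bg
    floor_eps <- 1e-6 * stats::median(net[net > 0])
    net <- pmax(net, floor_eps)
    agg <- tapply(net, sub$gene, sum)[genes]
    scale <- stats::median(agg)
    a[, s] <- agg / scale
    net_by_gene <- split(net / scale, sub$gene)
    for (g in genes) spot_store[[g]][, s] <- net_by_gene[[g]]
  }

  structure(list(a = a, spots = spot_store, samples = samples,
                 upsilon = ups),
            class = "gfp_eset")
}

#' @export
print.gfp_eset <- function(x, ...) {
  cat("Normalized expression set:", nrow(x$a), "genes x",
      ncol(x$a), "samples\n")
  cat("Conditions:", paste(unique(x$samples$condition), collapse = ", "),
      sprintf("(%d replicas each)\n",
              nrow(x$samples) / length(unique(x$samples$condition))))
  cat("Spots per gene:", paste(sort(unique(x$upsilon)), collapse = "/"), "\n")
  invisible(x)
}

#' Extract the replica-aggregated expression matrix of one condition
#'
#' @param es a `gfp_eset`.
#' @param condition condition label.
#' @return genes x replicas numeric matrix.
#' @export
condition_matrix <- function(es, condition) {
  stopifnot(inherits(es, "gfp_eset"))
  sel <- es$samples$condition == condition
  if (!any(sel)) stop("unknown condition: ", condition)
  es$a[, sel, drop = FALSE]
}

#' Pooled spot-level values of one gene in one condition
#'
#' Returns all `upsilon * n` normalized spot values, the sample on which the
#' variability estimator operates.
#'
#' @inheritParams condition_matrix
#' @param gene gene symbol.
#' @return numeric vector of length `upsilon[gene] * n_replicas`.
#' @export
spot_values <- function(es, gene, condition) {
  stopifnot(inherits(es, "gfp_eset"))
  m <- es$spots[[gene]]
  if (is.null(m)) stop("unknown gene: ", gene)
  as.vector(m[, es$samples$condition == condition, drop = FALSE])
}

#' Write a normalized expression set as TSV
#'
#' One row per (gene, condition, replica) with the aggregated value `a` and
#' the spot-level values joined by ';'.
#'
#' @param es a `gfp_eset`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_eset <- function(es, path) {
  stopifnot(inherits(es, "gfp_eset"))
  rows <- list()
  for (s in seq_len(nrow(es$samples))) {
    rows[[s]] <- data.frame(
      gene = rownames(es$a),
      condition = es$samples$condition[s],
      replica = es$samples$replica[s],
      a = es$a[, s],
      spot_values = vapply(rownames(es$a), function(g)
        paste(sprintf("%.10g", es$spots[[g]][, s]), collapse = ";"),
        character(1)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
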