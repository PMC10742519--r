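#' Regulation of expression control
#'
#' The change of a gene's homeostatic expression control between a cancer
#' condition and the reference, measured as the difference of the REV
#' inverses: `delta_control = 100/REV_cancer - 100/REV_ref`. Positive values
#' mean the transcript's abundance became more tightly controlled in cancer.
#' (Reported in the source literature under the synonym "delta REC"; the
#' median-offset terms of REC cancel only within one condition, so the
#' cross-condition change is defined on the raw control scale.)
#'
#' @param rev_cancer,rev_ref REVs in percent, > 0; vectorized.
#' @return signed change(s) in expression control.
#' @export
delta_control <- function(rev_cancer, rev_ref) {
  if (any(rev_cancer <= 0) || any(rev_ref <= 0))
    stop("REV must be positive")
  100 / rev_cancer - 100 / rev_ref
}

#' Transcriptomic distance of an individual gene
#'
#' Total per-gene transcriptomic alteration: the Euclidean distance from the
#' origin of the 3-dimensional space whose orthogonal, unnormalized axes are
#' the weighted individual regulation (expression level), the regulation of
#' expression control, and the regulation of expression coordination:
#' `TDI = sqrt(WIR^2 + delta_control^2 + delta_cor^2)`.
#'
#' @param wir,delta_control,delta_cor the three signed components;
#'   vectorized.
#' @return TDI >= 0, zero only when all three components are zero.
#' @export
tdi <- function(wir, delta_control, delta_cor) {
  sqrt(wir^2 + delta_control^2 + delta_cor^2)
}

#' Gene commanding height scores
#'
#' Ranks the genes of one condition by combining tight homeostatic control
#' (low REV relative to the condition median) with strong expression
#' coordination with the other quantified genes:
#' `GCH_i = (median(REV) / REV_i) * exp(4 * mean_{j != i} COR_ij^2)`.
#' A gene at the median REV with no coordination scores 1; halving a gene's
#' REV doubles its score at fixed coordination.
#'
#' @param rev named numeric vector of REVs (percent) for all quantified
#'   genes of the condition.
#' @param cormat gene x gene correlation matrix of the same condition
#'   (rownames matching `names(rev)`).
#' @return named numeric vector of GCH scores; genes with REV = 0 get `NA`.
#' @export
gch_scores <- function(rev, cormat) {
  genes <- names(rev)
  if (is.null(genes) || !all(genes %in% rownames(cormat)))
    stop("rev must be named and covered by cormat")
  cm <- cormat[genes, genes, drop = FALSE]^2
  diag(cm) <- NA
  mean_cor2 <- rowMeans(cm, na.rm = TRUE)
  med <- stats::median(rev[rev > 0])
  out <- ifelse(rev > 0, (med / rev) * exp(4 * mean_cor2), NA_real_)
  names(out) <- genes
  out
}

#' Gene master regulator of a condition
#'
#' The top-ranked gene by GCH. Ties are broken lexicographically by symbol,
#' with a warning.
#'
#' @param gch named numeric vector of GCH scores (see [gch_scores()]).
#' @return the GMR gene symbol.
#' @export
gmr <- function(gch) {
  gch <- gch[!is.na(gch)]
  if (!length(gch)) stop("no defined GCH scores")
  top <- names(gch)[gch == max(gch)]
  if (length(top) > 1) {
    warning("GCH tie broken lexicographically among: ",
            paste(top, collapse = ", "))
    top <- sort(top)
  }
  top[1]
}
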