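#' Mid-chi-square correction factor for the coefficient of variation
#'
#' With few replicas the plain sample CV badly understates the population
#' CV; the mid-point of its central chi-square confidence interval is used
#' instead. For `r` degrees of freedom and confidence `ci` the factor is
#' `0.5 * (sqrt(r / qchisq((1-ci)/2, r)) + sqrt(r / qchisq((1+ci)/2, r)))`,
#' which multiplies the sample CV. It is > 1 for finite `r` and decreases
#' monotonically to 1 as `r` grows.
#'
#' @param r degrees of freedom (pooled sample size minus 1), >= 1.
#' @param ci central confidence level of the interval (default 0.95).
#' @return the multiplicative correction factor.
#' @export
rev_factor <- function(r, ci = 0.95) {
  if (any(r < 1)) stop("degrees of freedom must be >= 1")
  lo <- stats::qchisq((1 - ci) / 2, r)
  hi <- stats::qchisq((1 + ci) / 2, r)
  0.5 * (sqrt(r / lo) + sqrt(r / hi))
}

#' Relative expression variability of a pooled sample
#'
#' The REV of a gene in one condition: the mid-chi-square interval estimate
#' of the coefficient of variation of all its `upsilon * n` normalized spot
#' values, in percent. Low REV marks a tightly (homeostatically) controlled
#' transcript.
#'
#' @param values numeric vector of pooled spot-level normalized expressions
#'   (length >= 2, positive mean).
#' @param ci confidence level passed to [rev_factor()].
#' @return REV in percent (>= 0).
#' @export
rev_cv <- function(values, ci = 0.95) {
  r <- length(values) - 1L
  if (r < 1L) stop("need at least 2 values to estimate variability")
  mu <- mean(values)
  if (mu <= 0) stop("mean expression must be positive")
  rev_factor(r, ci) * stats::sd(values) / mu * 100
}

#' Per-gene, per-condition expression descriptors
#'
#' Computes for every gene in every condition:
#' \describe{
#'   \item{AVE}{arithmetic mean of the aggregated normalized expression
#'     over the biological replicas.}
#'   \item{REV}{relative expression variability (percent), pooled over all
#'     `upsilon * n` spot values, see [rev_cv()].}
#'   \item{control}{expression control 100/REV; large values mark strongly
#'     controlled genes.}
#'   \item{REC}{relative expression control: `control` minus the condition's
#'     median control, so the median gene sits at 0 and tightly controlled
#'     (low-REV) genes are positive.}
#' }
#'
#' @param es a `gfp_eset` from [normalize_probes()].
#' @param ci confidence level for the REV interval estimate.
#' @return data.frame with columns `gene`, `condition`, `AVE`, `REV`,
#'   `control`, `REC`. Genes with REV numerically 0 get `control = Inf` and
#'   are excluded from the median defining REC.
#' @export
gene_stats <- function(es, ci = 0.95) {
  stopifnot(inherits(es, "gfp_eset"))
  conds <- unique(es$samples$condition)
  genes <- rownames(es$a)
  out <- vector("list", length(conds))
  for (j in seq_along(conds)) {
    cm <- condition_matrix(es, conds[j])
    ave <- rowMeans(cm)
    rev <- vapply(genes, function(g)
      rev_cv(spot_values(es, g, conds[j]), ci = ci), numeric(1))
    control <- ifelse(rev > 0, 100 / rev, Inf)
    med_ctrl <- stats::median(control[is.finite(control)])
    rec <- control - med_ctrl
    out[[j]] <- data.frame(gene = genes, condition = conds[j],
                           AVE = ave, REV = rev, control = control,
                           REC = rec, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
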