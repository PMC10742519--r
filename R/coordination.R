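#' Critical Pearson magnitude for significant coordination
#'
#' The two-tailed p < `alpha` significance threshold on |COR| for `m` paired
#' values, obtained by inverting the t-transform of the correlation
#' coefficient: `r* = t* / sqrt(t*^2 + m - 2)` with `t*` the
#' `1 - alpha/2` quantile of Student's t on `m - 2` degrees of freedom.
#' With 4 replicas (m = 4) the cut-off is 0.95; it decreases as redundant
#' spots raise the paired-value count (0.71 at m = 8, 0.58 at m = 12).
#'
#' @param m number of paired values (>= 3).
#' @param alpha two-tailed significance level.
#' @return critical |COR| in (0, 1).
#' @export
critical_cor <- function(m, alpha = 0.05) {
  if (any(m < 3)) stop("need at least 3 paired values")
  tstar <- stats::qt(1 - alpha / 2, df = m - 2)
  tstar / sqrt(tstar^2 + m - 2)
}

#' Two-tailed p-value of a Pearson correlation
#'
#' Uses the exact-under-normality t-transform
#' `t = |r| * sqrt((m - 2) / (1 - r^2))` on `m - 2` degrees of freedom.
#'
#' @param r Pearson coefficient(s) in \[-1, 1\].
#' @param m number of paired values (>= 3).
#' @return two-tailed p-value(s); 0 when |r| = 1.
#' @export
cor_pvalue <- function(r, m) {
  if (any(m < 3)) stop("need at least 3 paired values")
  p <- ifelse(abs(r) >= 1, 0, {
    tt <- abs(r) * sqrt((m - 2) / pmax(1 - r^2, .Machine$double.eps))
    2 * stats::pt(-tt, df = m - 2)
  })
  unname(p)
}

#' Expression correlation of two genes in one condition
#'
#' Pearson correlation of the log2 normalized expressions of two genes
#' across the replicas of the same condition, with its paired-value count
#' and two-tailed p-value.
#'
#' @param x_i,x_j positive replicate expression profiles of the two genes
#'   (same length m >= 3, same replica order).
#' @param log2_transform correlate log2 values (the default and the
#'   definition); set FALSE only if the inputs are already logged.
#' @return list with elements `COR`, `m`, `p`. If either profile has zero
#'   variance `COR` and `p` are `NA` and the pair is flagged
#'   (`undefined = TRUE`).
#' @export
cor_pair <- function(x_i, x_j, log2_transform = TRUE) {
  if (length(x_i) != length(x_j)) stop("profiles must have equal length")
  m <- length(x_i)
  if (m < 3) stop("need at least 3 paired values")
  if (log2_transform) {
    if (any(x_i <= 0) || any(x_j <= 0))
      stop("expressions must be positive for the log2 transform")
    x_i <- log2(x_i); x_j <- log2(x_j)
  }
  if (stats::sd(x_i) == 0 || stats::sd(x_j) == 0)
    return(list(COR = NA_real_, m = m, p = NA_real_, undefined = TRUE))
  r <- stats::cor(x_i, x_j)
  list(COR = r, m = m, p = cor_pvalue(r, m), undefined = FALSE)
}

#' Classify a gene pair as synergistic, antagonistic, or independent
#'
#' SYN: COR at or above the critical value for its paired-value count;
#' ANT: at or below the negated critical value; IND: |COR| at or below
#' `ind_cut` (near-zero correlation, a positive claim of independence);
#' NONE otherwise, including undefined correlations.
#'
#' @param cor Pearson coefficient(s); NA allowed (classified NONE).
#' @param m paired-value count (scalar or vector).
#' @param alpha significance level for the SYN/ANT threshold.
#' @param ind_cut |COR| threshold for independence (default 0.05).
#' @return character vector over `c("SYN","ANT","IND","NONE")`.
#' @export
classify_pair <- function(cor, m, alpha = 0.05, ind_cut = 0.05) {
  thr <- critical_cor(m, alpha)
  out <- rep("NONE", length(cor))
  out[!is.na(cor) & cor >= thr] <- "SYN"
  out[!is.na(cor) & cor <= -thr] <- "ANT"
  out[!is.na(cor) & abs(cor) <= ind_cut] <- "IND"
  out
}

#' Per-condition correlation matrices of an expression set
#'
#' Computes the full gene x gene Pearson correlation matrix of log2
#' normalized expressions for each condition. By default genes are paired by
#' replica on the aggregated values (m = n); the `"spot"` mode pairs the
#' k-th spot of each gene and is available when all genes share the same
#' spot count (m = upsilon * n), the regime in which redundant spots lower
#' the significance threshold.
#'
#' @param es a `gfp_eset`.
#' @param mode `"aggregate"` (default) or `"spot"`.
#' @return named list (by condition) of correlation matrices with an `m`
#'   attribute giving the paired-value count.
#' @export
cor_matrices <- function(es, mode = c("aggregate", "spot")) {
  stopifnot(inherits(es, "gfp_eset"))
  mode <- match.arg(mode)
  conds <- unique(es$samples$condition)
  out <- vector("list", length(conds))
  names(out) <- conds
  for (cond in conds) {
    if (mode == "aggregate") {
      x <- t(log2(condition_matrix(es, cond)))
    } else {
      if (length(unique(es$upsilon)) != 1L)
        stop("spot mode requires an equal spot count for all genes")
      sel <- es$samples$condition == cond
      x <- do.call(cbind, lapply(es$spots, function(s)
        as.vector(s[, sel, drop = FALSE])))
      colnames(x) <- names(es$spots)
      x <- log2(x)
    }
    cm <- suppressWarnings(stats::cor(x))
    attr(cm, "m") <- nrow(x)
    out[[cond]] <- cm
  }
  out
}

#' Pathway coordination score
#'
#' Summarizes the coordination state of a pathway in one condition as
#' `COORD = %SYN + %ANT - %IND`, the percentages being taken over all
#' unordered gene pairs of the pathway (undefined pairs stay in the
#' denominator as NONE). A large COORD marks a tightly inter-coordinated
#' (synergistically and/or antagonistically wired) pathway; a negative one a
#' pathway dominated by independently expressed pairs.
#'
#' Either supply `cls`, the pair classifications (from [classify_pair()]),
#' or `pct`, already-computed percentages `c(syn, ant, ind)` — the latter is
#' how published pair percentages can be turned into the score directly.
#'
#' @param cls character vector of pair classes for all pathway pairs.
#' @param pct numeric length-3 vector (syn, ant, ind) of percentages.
#' @return list with `pct_syn`, `pct_ant`, `pct_ind`, `n_pairs`, `COORD`.
#' @export
coord_score <- function(cls = NULL, pct = NULL) {
  if (is.null(cls) == is.null(pct))
    stop("supply exactly one of cls or pct")
  if (!is.null(cls)) {
    n <- length(cls)
    if (n < 1) stop("a pathway needs at least one gene pair")
    pct <- c(100 * sum(cls == "SYN") / n,
             100 * sum(cls == "ANT") / n,
             100 * sum(cls == "IND") / n)
  } else {
    if (length(pct) != 3 || any(pct < 0))
      stop("pct must be three non-negative percentages (syn, ant, ind)")
    n <- NA_integer_
  }
  list(pct_syn = pct[[1]], pct_ant = pct[[2]], pct_ind = pct[[3]],
       n_pairs = n, COORD = pct[[1]] + pct[[2]] - pct[[3]])
}

# pair classes of all unordered pairs of `genes` in one condition
pair_classes <- function(cormat, genes, alpha = 0.05, ind_cut = 0.05) {
  genes <- intersect(genes, rownames(cormat))
  if (length(genes) < 2) stop("a pathway needs at least 2 quantified genes")
  sub <- cormat[genes, genes, drop = FALSE]
  r <- sub[upper.tri(sub)]
  classify_pair(r, attr(cormat, "m"), alpha, ind_cut)
}

#' Significant coordination partners of one gene within a pathway
#'
#' Lists the pathway genes whose expression correlation with `gene` is
#' significant in `condition`: synergistic, antagonistic, or (positively)
#' independent. Non-significant partners are omitted, as is the gene itself.
#'
#' @param fit a fitted [gfp()] object.
#' @param gene gene symbol.
#' @param genes character vector of pathway gene symbols (the gene's
#'   reference set).
#' @param condition condition label.
#' @param alpha,ind_cut classification thresholds (default from the fit).
#' @return data.frame with columns `partner`, `COR`, `class`
#'   (SYN/ANT/IND only), possibly with zero rows.
#' @export
coordination_profile <- function(fit, gene, genes, condition,
                                 alpha = fit$params$alpha,
                                 ind_cut = fit$params$ind_cut) {
  stopifnot(inherits(fit, "gfp"))
  cm <- fit$cor[[condition]]
  if (is.null(cm)) stop("unknown condition: ", condition)
  if (!gene %in% rownames(cm)) stop("gene not quantified: ", gene)
  partners <- setdiff(intersect(genes, rownames(cm)), gene)
  r <- cm[gene, partners]
  cls <- classify_pair(r, attr(cm, "m"), alpha, ind_cut)
  keep <- cls != "NONE"
  data.frame(partner = partners[keep], COR = unname(r[keep]),
             class = cls[keep], stringsAsFactors = FALSE)
}

#' Coordination regulation of a gene with respect to a gene set
#'
#' The net change, between a cancer condition and the reference, of the
#' gene's absolute coordination with every other gene of the set:
#' `sum_j (|COR_ij^cancer| - |COR_ij^ref|)`. Positive values mean an overall
#' gain of expression coordination in cancer. Pairs with an undefined
#' correlation in either condition are skipped; their count is attached as
#' the `n_skipped` attribute.
#'
#' @param fit a fitted [gfp()] object.
#' @param gene gene symbol.
#' @param cancer cancer condition label.
#' @param reference reference condition label (default the fit's reference).
#' @param genes gene set defining the partners; default all quantified genes.
#' @return signed numeric scalar with attribute `n_skipped`.
#' @export
delta_cor <- function(fit, gene, cancer, reference = fit$reference,
                      genes = NULL) {
  stopifnot(inherits(fit, "gfp"))
  cc <- fit$cor[[cancer]]; cr <- fit$cor[[reference]]
  if (is.null(cc) || is.null(cr)) stop("unknown condition label")
  if (!gene %in% rownames(cc)) stop("gene not quantified: ", gene)
  if (is.null(genes)) genes <- rownames(cc)
  partners <- setdiff(intersect(genes, rownames(cc)), gene)
  d <- abs(cc[gene, partners]) - abs(cr[gene, partners])
  skipped <- sum(is.na(d))
  structure(sum(d, na.rm = TRUE), n_skipped = skipped)
}

# vectorized all-gene delta_cor for every gene at once (used by gfp())
delta_cor_all <- function(cor_cancer, cor_ref) {
  d <- abs(cor_cancer) - abs(cor_ref)
  diag(d) <- NA
  rowSums(d, na.rm = TRUE)
}
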