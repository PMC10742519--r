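#' Fit the genomic-fabric descriptors of a replicated expression experiment
#'
#' The one-stop analysis: starting from a probe-level fluorescence table (or
#' an already-normalized expression set), it filters unreliable spots,
#' normalizes each sample to its median gene, and computes
#' \itemize{
#'   \item per-gene, per-condition descriptors AVE, REV, control, REC;
#'   \item per-condition gene x gene correlation (coordination) matrices of
#'     the log2 expressions;
#'   \item for every cancer condition versus the reference: the signed fold
#'     change `x`, the gene-specific cut-off CUT, the heteroscedastic
#'     p-value, the regulome call, the weighted regulation WIR, the control
#'     regulation `delta_control`, the coordination regulation `delta_cor`
#'     (over all quantified genes), and the transcriptomic distance TDI;
#'   \item per-condition gene commanding heights (GCH) and the gene master
#'     regulator (GMR);
#'   \item when pathway sets are supplied, per-pathway coordination
#'     summaries (pair percentages and the COORD score) for every condition
#'     and regulation summaries (% up, % down among quantified genes, WPR)
#'     for every contrast.
#' }
#'
#' @param x a probe table data.frame (columns `probe_id`, `gene`,
#'   `condition`, `replica`, `fg`, `bg`) or a `gfp_eset` from
#'   [normalize_probes()].
#' @param reference label of the reference (normal tissue) condition.
#' @param pathways optional named list of gene sets (see [read_gmt()]).
#' @param alpha significance level for correlation classification and the
#'   regulome p-value threshold.
#' @param ind_cut |COR| threshold below which a pair is called
#'   independently expressed.
#' @param ci confidence level of the REV interval estimate.
#' @param filter_ratio fg/bg quality threshold of [filter_probes()]
#'   (ignored when `x` is already a `gfp_eset`).
#' @param uniform_cut uniform fold-change threshold used by the false-hit
#'   audit columns.
#' @param cor_mode `"aggregate"` (pair genes by replica) or `"spot"` (pair
#'   by spot, equal spot counts only); see [cor_matrices()].
#' @return an object of class `gfp`; see Details for components. Methods:
#'   [print.gfp()], [summary.gfp()], [coef.gfp()], [plot.gfp()].
#' @examples
#' cfg <- gfp_sim_config(n_genes = 40, conditions = c("NOR", "TUM"),
#'                       planted_folds = data.frame(gene = "G0001",
#'                         condition = "TUM", fold = 3),
#'                       cv_range = c(0.05, 0.3), seed = 7)
#' fit <- gfp(gfp_simulate(cfg)$probes, reference = "NOR")
#' fit
#' subset(fit$regulation, significant)
#' @export
gfp <- function(x, reference, pathways = NULL, alpha = 0.05,
                ind_cut = 0.05, ci = 0.95, filter_ratio = 2.0,
                uniform_cut = 1.5, cor_mode = "aggregate") {
  es <- if (inherits(x, "gfp_eset")) x else
    normalize_probes(filter_probes(x, ratio = filter_ratio))
  conds <- unique(es$samples$condition)
  if (!reference %in% conds)
    stop("reference condition '", reference, "' not among: ",
         paste(conds, collapse = ", "))
  cancers <- setdiff(conds, reference)

  stats_df <- gene_stats(es, ci = ci)
  cors <- cor_matrices(es, mode = cor_mode)
  genes <- rownames(es$a)

  stat_of <- function(cond, col) {
    s <- stats_df[stats_df$condition == cond, ]
    structure(s[[col]], names = s$gene)[genes]
  }

  reg <- vector("list", length(cancers))
  ref_mat <- condition_matrix(es, reference)
  ave_ref <- stat_of(reference, "AVE")
  rev_ref <- stat_of(reference, "REV")
  for (i in seq_along(cancers)) {
    cc <- cancers[i]
    cmat <- condition_matrix(es, cc)
    ave_c <- stat_of(cc, "AVE")
    rev_c <- stat_of(cc, "REV")
    xfc <- fold_change(ave_c, ave_ref)
    cut <- cut_value(rev_c, rev_ref)
    p <- vapply(genes, function(g)
      regulation_test(cmat[g, ], ref_mat[g, ]), numeric(1))
    w <- wir(ave_ref, xfc, p)
    dctrl <- delta_control(rev_c, rev_ref)
    dcor <- delta_cor_all(cors[[cc]], cors[[reference]])[genes]
    rec <- data.frame(gene = genes,
                      contrast = paste0(cc, "->", reference),
                      x = xfc, CUT = cut, p = p, WIR = w,
                      delta_control = dctrl, delta_cor = dcor,
                      TDI = tdi(w, dctrl, dcor),
                      stringsAsFactors = FALSE)
    reg[[i]] <- false_hit_audit(call_regulome(rec, p_cut = alpha),
                                uniform_cut = uniform_cut)
  }
  regulation <- do.call(rbind, reg)
  rownames(regulation) <- NULL

  gch <- sapply(conds, function(cond)
    gch_scores(stat_of(cond, "REV"), cors[[cond]]))
  rownames(gch) <- genes
  gmrs <- vapply(conds, function(cond) gmr(gch[, cond]), character(1))

  pw <- NULL
  if (!is.null(pathways)) {
    pw <- summarize_pathways(pathways, cors, regulation,
                             quantified = genes,
                             alpha = alpha, ind_cut = ind_cut)
    pw$sets <- pathways
  }

  structure(list(
    eset = es, reference = reference, conditions = conds,
    contrasts = paste0(cancers, "->", reference),
    stats = stats_df, cor = cors, regulation = regulation,
    gch = gch, gmr = gmrs, pathways = pw,
    params = list(alpha = alpha, ind_cut = ind_cut, ci = ci,
                  filter_ratio = filter_ratio, uniform_cut = uniform_cut,
                  cor_mode = cor_mode),
    call = match.call()
  ), class = "gfp")
}

# pathway-level coordination and regulation tables
summarize_pathways <- function(sets, cors, regulation, quantified,
                               alpha, ind_cut) {
  coord_rows <- list()
  reg_rows <- list()
  for (nm in names(sets)) {
    full <- sets[[nm]]
    quant <- intersect(full, quantified)
    if (length(quant) < 2) {
      warning("pathway '", nm, "' has fewer than 2 quantified genes; skipped")
      next
    }
    for (cond in names(cors)) {
      cls <- pair_classes(cors[[cond]], quant, alpha, ind_cut)
      cs <- coord_score(cls)
      coord_rows[[length(coord_rows) + 1L]] <- data.frame(
        pathway = nm, condition = cond,
        n_quantified = length(quant), n_total = length(full),
        pct_syn = cs$pct_syn, pct_ant = cs$pct_ant, pct_ind = cs$pct_ind,
        COORD = cs$COORD, stringsAsFactors = FALSE)
    }
    for (ctr in unique(regulation$contrast)) {
      sub <- regulation[regulation$contrast == ctr &
                          regulation$gene %in% quant, ]
      reg_rows[[length(reg_rows) + 1L]] <- data.frame(
        pathway = nm, contrast = ctr,
        n_quantified = length(quant), n_total = length(full),
        pct_up = 100 * sum(sub$significant & sub$x > 0) / length(quant),
        pct_down = 100 * sum(sub$significant & sub$x < 0) / length(quant),
        WPR = wpr(sub$WIR), stringsAsFactors = FALSE)
    }
  }
  list(coordination = do.call(rbind, coord_rows),
       regulation = do.call(rbind, reg_rows))
}

#' @export
print.gfp <- function(x, ...) {
  cat("Genomic fabric analysis\n")
  cat(sprintf("  %d genes, conditions: %s (reference %s)\n",
              nrow(x$eset$a), paste(x$conditions, collapse = ", "),
              x$reference))
  for (ctr in x$contrasts) {
    sub <- x$regulation[x$regulation$contrast == ctr, ]
    cat(sprintf("  %s: %d significantly regulated (%d up, %d down)\n",
                ctr, sum(sub$significant),
                sum(sub$significant & sub$x > 0),
                sum(sub$significant & sub$x < 0)))
  }
  cat("  Gene master regulators:",
      paste(sprintf("%s=%s", names(x$gmr), x$gmr), collapse = ", "), "\n")
  if (!is.null(x$pathways))
    cat("  Pathways analyzed:",
        paste(names(x$pathways$sets), collapse = ", "), "\n")
  invisible(x)
}

#' Summarize a genomic-fabric fit
#'
#' @param object a `gfp` fit.
#' @param top number of top-GCH genes to report per condition.
#' @param ... unused.
#' @return a `summary.gfp` list with the regulome sizes, median descriptor
#'   levels per condition, top-GCH table, and (if present) the pathway
#'   coordination and regulation tables.
#' @export
summary.gfp <- function(object, top = 5, ...) {
  med <- do.call(rbind, lapply(object$conditions, function(cond) {
    s <- object$stats[object$stats$condition == cond, ]
    data.frame(condition = cond, median_REV = stats::median(s$REV),
               median_control = stats::median(s$control[is.finite(s$control)]),
               stringsAsFactors = FALSE)
  }))
  topg <- do.call(rbind, lapply(object$conditions, function(cond) {
    g <- sort(object$gch[, cond], decreasing = TRUE)
    g <- g[!is.na(g)][seq_len(min(top, sum(!is.na(g))))]
    data.frame(condition = cond, gene = names(g), GCH = unname(g),
               rank = seq_along(g), stringsAsFactors = FALSE)
  }))
  reg <- do.call(rbind, lapply(object$contrasts, function(ctr) {
    sub <- object$regulation[object$regulation$contrast == ctr, ]
    data.frame(contrast = ctr, n_significant = sum(sub$significant),
               n_up = sum(sub$significant & sub$x > 0),
               n_down = sum(sub$significant & sub$x < 0),
               median_TDI = stats::median(sub$TDI),
               stringsAsFactors = FALSE)
  }))
  structure(list(medians = med, regulomes = reg, top_gch = topg,
                 gmr = object$gmr,
                 pathways = object$pathways[c("coordination", "regulation")]),
            class = "summary.gfp")
}

#' @export
print.summary.gfp <- function(x, ...) {
  cat("Per-condition descriptor medians:\n")
  print(x$medians, row.names = FALSE)
  cat("\nRegulomes (vs reference):\n")
  print(x$regulomes, row.names = FALSE)
  cat("\nGene master regulators:\n")
  print(x$gmr)
  cat("\nTop GCH genes:\n")
  print(x$top_gch, row.names = FALSE)
  if (!is.null(x$pathways$coordination)) {
    cat("\nPathway coordination (COORD = %syn + %ant - %ind):\n")
    print(x$pathways$coordination, row.names = FALSE, digits = 4)
    cat("\nPathway regulation:\n")
    print(x$pathways$regulation, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Extract per-gene mean expression levels
#'
#' @param object a `gfp` fit.
#' @param ... unused.
#' @return genes x conditions matrix of AVE values.
#' @export
coef.gfp <- function(object, ...) {
  out <- sapply(object$conditions, function(cond) {
    s <- object$stats[object$stats$condition == cond, ]
    structure(s$AVE, names = s$gene)[rownames(object$eset$a)]
  })
  rownames(out) <- rownames(object$eset$a)
  out
}

#' Diagnostic plots of a genomic-fabric fit
#'
#' `type = "descriptors"` draws AVE versus REV per condition (log x-axis);
#' `type = "regulation"` draws |x| against the gene-specific CUT for each
#' contrast, marking the significant genes; `type = "gch"` draws the sorted
#' GCH profiles per condition.
#'
#' @param x a `gfp` fit.
#' @param type one of `"descriptors"`, `"regulation"`, `"gch"`.
#' @param ... passed to the underlying plot call.
#' @return invisibly, `x`.
#' @export
plot.gfp <- function(x, type = c("descriptors", "regulation", "gch"), ...) {
  type <- match.arg(type)
  op <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(op))
  if (type == "descriptors") {
    nc <- length(x$conditions)
    graphics::par(mfrow = c(1, nc))
    for (cond in x$conditions) {
      s <- x$stats[x$stats$condition == cond, ]
      graphics::plot(s$AVE, s$REV, log = "x", xlab = "AVE",
                     ylab = "REV (%)", main = cond, pch = 20, ...)
    }
  } else if (type == "regulation") {
    nc <- length(x$contrasts)
    graphics::par(mfrow = c(1, nc))
    for (ctr in x$contrasts) {
      sub <- x$regulation[x$regulation$contrast == ctr, ]
      graphics::plot(abs(sub$x), sub$CUT, pch = 20,
                     col = ifelse(sub$significant, "red", "grey40"),
                     xlab = "|x|", ylab = "CUT", main = ctr, ...)
      graphics::abline(0, 1, lty = 2)
    }
  } else {
    graphics::matplot(apply(x$gch, 2, sort, decreasing = TRUE,
                            na.last = TRUE),
                      type = "l", lty = 1, xlab = "rank", ylab = "GCH", ...)
    graphics::legend("topright", legend = x$conditions, lty = 1,
                     col = seq_along(x$conditions))
  }
  invisible(x)
}

#' Write the result tables of a fit as TSV files
#'
#' Emits `descriptors.tsv`, `regulation.tsv`, `gch.tsv`, per-condition
#' correlation-class adjacency matrices `classes_<condition>.tsv`, and, when
#' pathways were supplied, `pathway_coordination.tsv` and
#' `pathway_regulation.tsv`. Rows are sorted and floating point is printed
#' at 6 significant digits so reruns diff cleanly.
#'
#' @param fit a `gfp` fit.
#' @param dir output directory, created if missing.
#' @return invisibly, the paths written.
#' @export
write_gfp_tables <- function(fit, dir) {
  stopifnot(inherits(fit, "gfp"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt_df <- function(df) {
    df[] <- lapply(df, function(col)
      if (is.double(col)) sprintf("%.6g", col) else col)
    df
  }
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(fmt_df(df), p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <<- c(paths, p)
  }
  s <- fit$stats[order(fit$stats$condition, fit$stats$gene), ]
  emit(s, "descriptors.tsv")
  r <- fit$regulation[order(fit$regulation$contrast, fit$regulation$gene), ]
  emit(r, "regulation.tsv")
  g <- data.frame(gene = rownames(fit$gch), fit$gch, check.names = FALSE)
  emit(g[order(g$gene), ], "gch.tsv")
  for (cond in fit$conditions) {
    cm <- fit$cor[[cond]]
    m <- attr(cm, "m")
    cls <- matrix(classify_pair(as.vector(cm), m, fit$params$alpha,
                                fit$params$ind_cut),
                  nrow(cm), dimnames = dimnames(cm))
    diag(cls) <- "SYN"
    emit(data.frame(gene = rownames(cls), cls, check.names = FALSE),
         paste0("classes_", cond, ".tsv"))
  }
  if (!is.null(fit$pathways)) {
    emit(fit$pathways$coordination, "pathway_coordination.tsv")
    emit(fit$pathways$regulation, "pathway_regulation.tsv")
  }
  invisible(paths)
}
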