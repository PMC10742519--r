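#' Configure a synthetic probe-level expression experiment
#'
#' Builds a validated configuration for [gfp_simulate()]. The generator
#' emulates the design of a replicated two-color-free microarray study:
#' several tissue conditions, a small number of biological replicas per
#' condition, one to three redundant spots per gene, lognormal expression
#' with a per-gene coefficient of variation, additive background
#' fluorescence, planted fold changes between conditions, and planted
#' correlation blocks in which genes share a per-replica latent factor.
#'
#' @param n_genes number of distinct genes to simulate.
#' @param conditions character vector of condition labels; the first label is
#'   conventionally the reference (normal) tissue.
#' @param n_replicas biological replicas per condition.
#' @param spots_per_gene spot redundancy per gene: a single integer in
#'   `1:3` recycled to all genes, or an integer vector of length `n_genes`.
#' @param baseline_mean median scale of the true gene means, in fluorescence
#'   units. Gene means are drawn lognormally around this value.
#' @param mean_sdlog log-scale standard deviation of the gene means
#'   (controls the dynamic range across genes).
#' @param cv_range length-2 numeric in (0, 2]: per-gene biological
#'   coefficients of variation are drawn uniformly from this interval.
#' @param cv_overrides optional named numeric vector fixing the biological
#'   CV of specific genes (values in (0, 2]), overriding the draw from
#'   `cv_range`; lets tests plant genes of known variability.
#' @param planted_folds `NULL`, or a data.frame with columns `gene`,
#'   `condition`, `fold` giving signed fold changes relative to the gene's
#'   baseline mean. `|fold| >= 1`; negative values mean down-regulation
#'   (the mean is divided by `|fold|`).
#' @param correlation_blocks `NULL`, or a list of blocks, each a list with
#'   `genes` (character vector, length >= 2), `loading` (single value in
#'   \[-1, 1\] shared by the block, or one signed loading per gene), and
#'   optionally `conditions` (labels the block applies to; default all).
#' @param background_level mean background fluorescence; each spot gets this
#'   value with 10% Gaussian jitter, truncated at zero.
#' @param spot_cv technical coefficient of variation of redundant spots
#'   around their gene's replicate value.
#' @param failing_spot_fraction fraction in \[0, 1) of probes planted to fail
#'   the foreground >= 2 x background quality filter in one random sample.
#' @param seed integer seed fixing all randomness of the generator.
#'
#' @return an object of class `gfp_sim_config` (a validated list).
#' @seealso [gfp_simulate()], [write_gfp_fixture()]
#' @export
gfp_sim_config <- function(n_genes,
                           conditions = c("NOR", "PTA", "PTB", "CWM"),
                           n_replicas = 4L,
                           spots_per_gene = 1L,
                           baseline_mean = 500,
                           mean_sdlog = 1,
                           cv_range = c(0.05, 0.5),
                           cv_overrides = NULL,
                           planted_folds = NULL,
                           correlation_blocks = NULL,
                           background_level = 20,
                           spot_cv = 0.05,
                           failing_spot_fraction = 0,
                           seed = 1L) {
  fail <- function(field, msg) {
    stop(sprintf("invalid configuration field '%s': %s", field, msg),
         call. = FALSE)
  }
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1)
    fail("n_genes", "must be a single positive count")
  n_genes <- as.integer(n_genes)
  if (!is.character(conditions) || length(conditions) < 1L ||
      anyDuplicated(conditions))
    fail("conditions", "must be distinct labels")
  if (!is.numeric(n_replicas) || length(n_replicas) != 1L || n_replicas < 2)
    fail("n_replicas", "must be a count >= 2")
  n_replicas <- as.integer(n_replicas)
  genes <- sprintf("G%04d", seq_len(n_genes))
  ups <- as.integer(rep_len(spots_per_gene, n_genes))
  if (any(is.na(ups)) || any(ups < 1L) || any(ups > 3L))
    fail("spots_per_gene", "spot counts must lie in {1, 2, 3}")
  if (!is.numeric(baseline_mean) || baseline_mean <= 0)
    fail("baseline_mean", "must be positive")
  if (!is.numeric(cv_range) || length(cv_range) != 2L ||
      any(cv_range <= 0) || any(cv_range > 2) || cv_range[1] > cv_range[2])
    fail("cv_range", "must be an interval within (0, 2]")
  if (!is.null(cv_overrides)) {
    if (is.null(names(cv_overrides)) || !all(names(cv_overrides) %in% genes))
      fail("cv_overrides", "must be named by known gene ids")
    if (any(cv_overrides <= 0) || any(cv_overrides > 2))
      fail("cv_overrides", "values must lie in (0, 2]")
  }
  if (!is.null(planted_folds)) {
    planted_folds <- as.data.frame(planted_folds)
    need <- c("gene", "condition", "fold")
    if (!all(need %in% names(planted_folds)))
      fail("planted_folds", "needs columns gene, condition, fold")
    if (any(abs(planted_folds$fold) < 1))
      fail("planted_folds", "|fold| must be >= 1")
    if (!all(planted_folds$gene %in% genes))
      fail("planted_folds", "unknown gene id (genes are named G0001..)")
    if (!all(planted_folds$condition %in% conditions))
      fail("planted_folds", "unknown condition label")
  }
  if (!is.null(correlation_blocks)) {
    for (b in correlation_blocks) {
      if (!is.list(b) || is.null(b$genes) || is.null(b$loading))
        fail("correlation_blocks", "each block needs $genes and $loading")
      if (length(b$genes) < 2L || !all(b$genes %in% genes))
        fail("correlation_blocks", ">= 2 known genes per block")
      if (!length(b$loading) %in% c(1L, length(b$genes)) ||
          any(abs(b$loading) > 1))
        fail("correlation_blocks",
             "loading must be scalar or per-gene, within [-1, 1]")
      if (!is.null(b$conditions) && !all(b$conditions %in% conditions))
        fail("correlation_blocks", "unknown condition label in block")
    }
  }
  if (!is.numeric(background_level) || background_level <= 0)
    fail("background_level", "must be positive")
  if (!is.numeric(spot_cv) || spot_cv < 0)
    fail("spot_cv", "must be >= 0")
  if (!is.numeric(failing_spot_fraction) || failing_spot_fraction < 0 ||
      failing_spot_fraction >= 1)
    fail("failing_spot_fraction", "must lie in [0, 1)")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    fail("seed", "must be a single integer")
  structure(list(
    n_genes = n_genes, genes = genes, conditions = conditions,
    n_replicas = n_replicas, spots_per_gene = ups,
    baseline_mean = baseline_mean, mean_sdlog = mean_sdlog,
    cv_range = cv_range, cv_overrides = cv_overrides,
    planted_folds = planted_folds,
    correlation_blocks = correlation_blocks,
    background_level = background_level, spot_cv = spot_cv,
    failing_spot_fraction = failing_spot_fraction,
    seed = as.integer(seed)
  ), class = "gfp_sim_config")
}

#' Simulate a probe-level expression dataset with known ground truth
#'
#' Draws a complete probe table (one row per gene x spot x condition x
#' replica) under the model described in [gfp_sim_config()]:
#' gene `i` has true mean `mu_i` (lognormal around `baseline_mean`) scaled by
#' any planted fold in condition `c`; its replicate value is
#' `mu * exp(sigma * z - sigma^2/2)` with `sigma` chosen so the lognormal
#' coefficient of variation equals the gene's drawn CV, and `z` a standard
#' normal that mixes a per-(condition, replica) block latent factor with an
#' independent term (`z = l*f + sqrt(1 - l^2)*e`), which plants pairwise
#' Pearson correlation of sign `sign(l_i * l_j)` on the log scale. Redundant
#' spots add independent technical noise at `spot_cv`. Foreground is the spot
#' value plus the recorded background.
#'
#' @param config a [gfp_sim_config()] object.
#' @return a list with components:
#'   \describe{
#'     \item{probes}{data.frame with columns `probe_id`, `gene`, `condition`,
#'       `replica`, `fg`, `bg` (the probe table consumed by
#'       [filter_probes()]).}
#'     \item{truth}{list with `folds` (data.frame `gene`, `condition`,
#'       `true_fold`, `true_cv` over the full grid, fold 1 where nothing was
#'       planted), `pair_signs` (data.frame `gene_i`, `gene_j`, `condition`,
#'       `sign` for within-block pairs), and `failing_probes` (character
#'       vector of probe ids planted to fail the quality filter).}
#'   }
#' @examples
#' cfg <- gfp_sim_config(n_genes = 10, seed = 42)
#' sim <- gfp_simulate(cfg)
#' head(sim$probes)
#' @export
gfp_simulate <- function(config) {
  if (!inherits(config, "gfp_sim_config"))
    stop("config must be created by gfp_sim_config()")
  set.seed(config$seed)
  genes <- config$genes
  nc <- length(config$conditions)
  n <- config$n_replicas
  ups <- config$spots_per_gene

  mu <- stats::rlnorm(config$n_genes, meanlog = log(config$baseline_mean),
                      sdlog = config$mean_sdlog)
  cv <- stats::runif(config$n_genes, config$cv_range[1], config$cv_range[2])
  names(cv) <- genes
  if (!is.null(config$cv_overrides))
    cv[names(config$cv_overrides)] <- config$cv_overrides
  sigma <- sqrt(log(1 + cv^2))
  names(mu) <- names(cv) <- names(sigma) <- genes

  # signed fold -> multiplicative factor on the condition mean
  foldfac <- matrix(1, config$n_genes, nc, dimnames = list(genes, config$conditions))
  if (!is.null(config$planted_folds)) {
    pf <- config$planted_folds
    fac <- ifelse(pf$fold >= 0, pf$fold, 1 / abs(pf$fold))
    foldfac[cbind(match(pf$gene, genes), match(pf$condition, config$conditions))] <- fac
  }

  # per-gene, per-condition loading on the block latent factor
  loading <- matrix(0, config$n_genes, nc, dimnames = list(genes, config$conditions))
  block_of <- integer(0)
  if (!is.null(config$correlation_blocks)) {
    for (bi in seq_along(config$correlation_blocks)) {
      b <- config$correlation_blocks[[bi]]
      conds <- if (is.null(b$conditions)) config$conditions else b$conditions
      l <- rep_len(b$loading, length(b$genes))
      loading[match(b$genes, genes), conds] <- l
      block_of[b$genes] <- bi
    }
  }

  rows <- vector("list", nc * n)
  ri <- 0L
  for (ci in seq_len(nc)) {
    cond <- config$conditions[ci]
    for (k in seq_len(n)) {
      # one latent factor per block per sample
      f <- if (length(config$correlation_blocks)) {
        stats::rnorm(length(config$correlation_blocks))
      } else numeric(0)
      eps <- stats::rnorm(config$n_genes)
      l <- loading[, ci]
      fg_gene <- ifelse(names(l) %in% names(block_of),
                        f[block_of[names(l)]], 0)
      fg_gene[is.na(fg_gene)] <- 0
      z <- l * fg_gene + sqrt(1 - l^2) * eps
      repval <- mu * foldfac[, ci] * exp(sigma * z - sigma^2 / 2)

      tau <- sqrt(log(1 + config$spot_cv^2))
      gene_idx <- rep(seq_len(config$n_genes), ups)
      spot_idx <- sequence(ups)
      spot_noise <- exp(tau * stats::rnorm(length(gene_idx)) - tau^2 / 2)
      spot_val <- repval[gene_idx] * spot_noise
      bg <- pmax(config$background_level *
                   (1 + 0.1 * stats::rnorm(length(gene_idx))), 0)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        probe_id = sprintf("%s_s%d", genes[gene_idx], spot_idx),
        gene = genes[gene_idx],
        condition = cond,
        replica = k,
        fg = spot_val + bg,
        bg = bg,
        stringsAsFactors = FALSE
      )
    }
  }
  probes <- do.call(rbind, rows)
  rownames(probes) <- NULL

  # plant quality-filter failures: fg dropped below 2 x bg in one sample
  all_probe_ids <- unique(probes$probe_id)
  failing <- character(0)
  if (config$failing_spot_fraction > 0) {
    n_fail <- floor(config$failing_spot_fraction * length(all_probe_ids))
    if (n_fail > 0) {
      failing <- sort(sample(all_probe_ids, n_fail))
      for (p in failing) {
        idx <- which(probes$probe_id == p)
        hit <- idx[sample.int(length(idx), 1L)]
        probes$fg[hit] <- 1.5 * probes$bg[hit]
      }
    }
  }

  grid <- expand.grid(gene = genes, condition = config$conditions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pf_key <- paste(grid$gene, grid$condition)
  fold_signed <- rep(1, nrow(grid))
  if (!is.null(config$planted_folds)) {
    pf <- config$planted_folds
    fold_signed[match(paste(pf$gene, pf$condition), pf_key)] <- pf$fold
  }
  folds <- data.frame(gene = grid$gene, condition = grid$condition,
                      true_fold = fold_signed, true_cv = cv[grid$gene],
                      stringsAsFactors = FALSE)
  rownames(folds) <- NULL

  pair_signs <- NULL
  if (!is.null(config$correlation_blocks)) {
    ps <- list()
    for (b in config$correlation_blocks) {
      conds <- if (is.null(b$conditions)) config$conditions else b$conditions
      l <- rep_len(b$loading, length(b$genes))
      cmb <- utils::combn(seq_along(b$genes), 2)
      for (cond in conds) {
        ps[[length(ps) + 1L]] <- data.frame(
          gene_i = b$genes[cmb[1, ]], gene_j = b$genes[cmb[2, ]],
          condition = cond,
          sign = sign(l[cmb[1, ]] * l[cmb[2, ]]),
          stringsAsFactors = FALSE)
      }
    }
    pair_signs <- do.call(rbind, ps)
  }

  list(probes = probes,
       truth = list(folds = folds, pair_signs = pair_signs,
                    failing_probes = failing, true_cv = cv))
}

#' Write a simulated dataset as TSV fixture files
#'
#' Emits `probes.tsv` (columns `probe_id`, `gene`, `condition`, `replica`,
#' `fg`, `bg`), `truth.tsv` (columns `gene`, `condition`, `true_fold`,
#' `true_cv`) and, when correlation blocks were planted, `truth_pairs.tsv`.
#' Numeric columns are printed with 17 significant digits so the files
#' round-trip losslessly through [read_probe_table()].
#'
#' @param sim result of [gfp_simulate()], or any list with `probes`/`truth`.
#' @param dir output directory, created if missing.
#' @return invisibly, the paths written.
#' @export
write_gfp_fixture <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- function(x) {
    if (is.double(x)) sprintf("%.17g", x) else as.character(x)
  }
  write_tsv <- function(df, path) {
    out <- as.data.frame(lapply(df, fmt), stringsAsFactors = FALSE)
    names(out) <- names(df)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  paths <- file.path(dir, "probes.tsv")
  write_tsv(sim$probes, paths[1])
  if (!is.null(sim$truth$folds)) {
    p <- file.path(dir, "truth.tsv")
    write_tsv(sim$truth$folds, p)
    paths <- c(paths, p)
  }
  if (!is.null(sim$truth$pair_signs)) {
    p <- file.path(dir, "truth_pairs.tsv")
    write_tsv(sim$truth$pair_signs, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a probe-level expression table
#'
#' @param path TSV file with columns `probe_id`, `gene`, `condition`,
#'   `replica`, `fg`, `bg` (in any order; extra columns are ignored).
#' @return a probe table data.frame.
#' @export
read_probe_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(probe_id = "character",
                                         gene = "character",
                                         condition = "character",
                                         replica = "integer",
                                         fg = "numeric", bg = "numeric"))
  need <- c("probe_id", "gene", "condition", "replica", "fg", "bg")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("probe table is missing columns: ", paste(miss, collapse = ", "))
  df[need]
}

#' Read a ground-truth table written by [write_gfp_fixture()]
#'
#' @param path TSV file with columns `gene`, `condition`, `true_fold`,
#'   `true_cv`.
#' @return a data.frame.
#' @export
read_ground_truth <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c(gene = "character",
                                   condition = "character",
                                   true_fold = "numeric",
                                   true_cv = "numeric"))
}

#' Configuration of the example dataset shipped with the package
#'
#' The probe table under `inst/extdata/example_probes.tsv` (with its
#' `example_truth.tsv`) was produced by [gfp_simulate()] from exactly this
#' configuration, so it can be regenerated byte-for-byte: 50 genes in two
#' conditions with four replicas, mixed 1-2 spot redundancy, three planted
#' fold changes, one synergistic and one antagonistic correlation block, and
#' 5% planted failing spots.
#'
#' @return a `gfp_sim_config` object.
#' @export
example_fixture_config <- function() {
  gfp_sim_config(
    n_genes = 50,
    conditions = c("NOR", "TUM"),
    n_replicas = 4L,
    spots_per_gene = rep_len(c(1L, 2L), 50),
    baseline_mean = 500,
    cv_range = c(0.05, 0.35),
    planted_folds = data.frame(
      gene = c("G0001", "G0002", "G0003"),
      condition = "TUM",
      fold = c(3, -2.5, 1.8)),
    correlation_blocks = list(
      list(genes = sprintf("G%04d", 10:13), loading = 0.97),
      list(genes = c("G0020", "G0021"), loading = c(0.97, -0.97))),
    background_level = 20,
    failing_spot_fraction = 0.05,
    seed = 20240L)
}
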