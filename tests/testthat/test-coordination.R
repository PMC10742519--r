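test_that("critical correlation magnitudes match the replicate regimes", {
  expect_equal(round(critical_cor(4), 2), 0.95)
  expect_equal(round(critical_cor(8), 2), 0.71)
  expect_equal(round(critical_cor(12), 2), 0.58)
  m <- 3:30
  expect_true(all(diff(critical_cor(m)) < 0))
  expect_error(critical_cor(2), "at least 3")
})

test_that("critical_cor agrees with a brute-force null simulation", {
  # independent oracle: empirical (1 - alpha) quantile of |r| under the
  # null of independent normal pairs
  set.seed(1)
  for (m in c(4, 8, 12)) {
    r <- replicate(40000, cor(rnorm(m), rnorm(m)))
    emp <- unname(quantile(abs(r), 0.95))
    expect_equal(critical_cor(m), emp, tolerance = 0.02)
  }
})

test_that("correlation p-values match cor.test on random profiles", {
  set.seed(7)
  for (i in 1:25) {
    m <- sample(3:12, 1)
    x <- rnorm(m)
    y <- rnorm(m)
    r <- cor(x, y)
    expect_equal(cor_pvalue(r, m), cor.test(x, y)$p.value,
                 tolerance = 1e-10)
  }
  expect_equal(cor_pvalue(1, 5), 0)
})

test_that("cor_pair handles self-correlation, logs, and degeneracy", {
  x <- c(1.2, 3.4, 0.8, 2.2)
  self <- cor_pair(x, x)
  expect_equal(self$COR, 1)
  expect_equal(self$m, 4L)
  flat <- cor_pair(x, rep(2, 4))
  expect_true(flat$undefined)
  expect_true(is.na(flat$COR))
  expect_error(cor_pair(x, c(-1, 1, 1, 1)), "positive")
  expect_error(cor_pair(x, x[1:3]), "equal length")
  # log2 transform is what is correlated
  y <- 2^c(1, 2, 3, 4.5)
  z <- 2^c(2, 4, 6, 9)
  expect_equal(cor_pair(y, z)$COR, 1, tolerance = 1e-12)
})

test_that("pairs classify into SYN/ANT/IND/NONE per the thresholds", {
  expect_identical(classify_pair(0.3, 4), "NONE")
  expect_identical(classify_pair(-0.96624, 4), "ANT")
  expect_identical(classify_pair(0.0, 4), "IND")
  expect_identical(classify_pair(0.05, 4), "IND")   # tie goes to IND
  thr <- critical_cor(4)
  expect_identical(classify_pair(thr, 4), "SYN")    # tie is significant
  expect_identical(classify_pair(NA_real_, 4), "NONE")
  expect_identical(classify_pair(c(0.99, -0.99, 0.01, 0.5), 4),
                   c("SYN", "ANT", "IND", "NONE"))
  # higher paired-value count lowers the threshold
  expect_identical(classify_pair(0.75, 8), "SYN")
  expect_identical(classify_pair(0.75, 4), "NONE")
})

test_that("COORD score obeys its identity on classes and percentages", {
  cls <- c("SYN", "SYN", "ANT", "IND", "NONE")
  cs <- coord_score(cls)
  expect_equal(cs$pct_syn, 40)
  expect_equal(cs$COORD, cs$pct_syn + cs$pct_ant - cs$pct_ind,
               tolerance = 1e-9)
  expect_equal(coord_score(rep("IND", 10))$COORD, -100)
  expect_equal(coord_score(pct = c(20.76, 20.76, 4.68))$COORD, 36.84,
               tolerance = 1e-9)
  expect_error(coord_score(), "exactly one")
  expect_error(coord_score(pct = c(-1, 2, 3)), "non-negative")
})

test_that("correlation matrices are symmetric with unit diagonal", {
  cfg <- gfp_sim_config(n_genes = 12, conditions = c("NOR", "TUM"),
                        seed = 31)
  es <- normalize_probes(filter_probes(gfp_simulate(cfg)$probes))
  cors <- cor_matrices(es)
  for (cm in cors) {
    expect_equal(attr(cm, "m"), 4L)
    expect_equal(unname(diag(cm)), rep(1, nrow(cm)), tolerance = 1e-12)
    expect_equal(cm, t(cm), tolerance = 1e-12)
  }
  # spot mode raises the paired-value count
  cfg2 <- gfp_sim_config(n_genes = 10, conditions = "NOR",
                         spots_per_gene = 2L, seed = 32)
  es2 <- normalize_probes(filter_probes(gfp_simulate(cfg2)$probes))
  expect_equal(attr(cor_matrices(es2, mode = "spot")$NOR, "m"), 8L)
  cfg3 <- gfp_sim_config(n_genes = 10, conditions = "NOR",
                         spots_per_gene = c(1L, 2L), seed = 33)
  es3 <- normalize_probes(filter_probes(gfp_simulate(cfg3)$probes))
  expect_error(cor_matrices(es3, mode = "spot"), "equal spot count")
})

test_that("coordination profiles list significant partners only", {
  block <- sprintf("G%04d", 1:4)
  hits <- 0L
  n_seeds <- 20L
  for (s in seq_len(n_seeds)) {
    cfg <- gfp_sim_config(n_genes = 30, conditions = c("NOR", "TUM"),
                          cv_range = c(0.1, 0.3), spot_cv = 0,
                          correlation_blocks = list(
                            list(genes = block, loading = 0.99)),
                          seed = 500 + s)
    fit <- gfp(gfp_simulate(cfg)$probes, reference = "NOR")
    prof <- coordination_profile(fit, "G0001", sprintf("G%04d", 1:10),
                                 "NOR")
    expect_false("G0001" %in% prof$partner)
    expect_true(all(prof$class %in% c("SYN", "ANT", "IND")))
    # the designated block-mate is listed as a synergistic partner
    if ("G0002" %in% prof$partner[prof$class == "SYN"]) hits <- hits + 1L
  }
  expect_gt(hits / n_seeds, 0.5)
  expect_error(coordination_profile(fit, "NOPE", block, "NOR"),
               "not quantified")
})

test_that("delta_cor measures the net coordination change", {
  mk_cm <- function(v, genes) {
    cm <- matrix(v, length(genes), length(genes),
                 dimnames = list(genes, genes))
    diag(cm) <- 1
    attr(cm, "m") <- 4L
    cm
  }
  genes <- paste0("g", 1:11)
  fit <- structure(list(
    cor = list(NOR = mk_cm(0, genes), TUM = mk_cm(0, genes)),
    reference = "NOR", params = list(alpha = 0.05, ind_cut = 0.05)),
    class = "gfp")
  expect_equal(as.numeric(delta_cor(fit, "g1", "TUM")), 0)
  # fully correlated with 10 partners in cancer, uncorrelated in reference
  fit$cor$TUM <- mk_cm(1, genes)
  expect_equal(as.numeric(delta_cor(fit, "g1", "TUM")), 10)

  # a block present only in the cancer condition raises delta_cor
  block <- sprintf("G%04d", 1:5)
  pos <- 0L
  n_seeds <- 20L
  for (s in seq_len(n_seeds)) {
    cfg <- gfp_sim_config(n_genes = 12, conditions = c("NOR", "TUM"),
                          correlation_blocks = list(
                            list(genes = block, loading = 0.99,
                                 conditions = "TUM")),
                          seed = 700 + s)
    f <- gfp(gfp_simulate(cfg)$probes, reference = "NOR")
    d <- vapply(block, function(g)
      as.numeric(delta_cor(f, g, "TUM", genes = block)), numeric(1))
    if (all(d > 0)) pos <- pos + 1L
  }
  expect_gt(pos / n_seeds, 0.5)
})
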