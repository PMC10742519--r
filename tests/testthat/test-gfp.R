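test_that("GMT files round-trip, collapse duplicates, and reject empties", {
  sets <- list(SETA = c("ESR1", "AP2A1", "DNM2"),
               SETB = c("AP2A1", "AVP"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_identical(lapply(back, as.character), sets)
  # a gene in two sets appears in both but counts once in the union
  expect_length(unique(unlist(back)), 4L)
  writeLines("DUP\tsrc\tA\tB\tA", path)
  expect_warning(b2 <- read_gmt(path), "duplicate")
  expect_identical(as.character(b2$DUP), c("A", "B"))
  writeLines("EMPTY\tsrc", path)
  expect_error(read_gmt(path), "no genes")

  shipped <- read_gmt(system.file("extdata", "excretory_pathways.gmt",
                                  package = "gfabric"))
  expect_named(shipped, c("ALDO", "COLL", "ENDO", "PROX", "VASO"))
  expect_true(all(lengths(shipped) >= 2))
})

test_that("the full pipeline satisfies every stage invariant", {
  cfg <- gfp_sim_config(
    n_genes = 60, conditions = c("NOR", "PTA", "PTB"),
    spots_per_gene = c(1L, 2L),
    planted_folds = data.frame(gene = c("G0001", "G0002"),
                               condition = c("PTA", "PTB"),
                               fold = c(4, -4)),
    correlation_blocks = list(
      list(genes = sprintf("G%04d", 10:13), loading = 0.98)),
    cv_range = c(0.05, 0.3), failing_spot_fraction = 0.05, seed = 202)
  sim <- gfp_simulate(cfg)
  pw <- list(PATHA = sprintf("G%04d", c(1, 2, 10:13)),
             PATHB = sprintf("G%04d", 20:29),
             MISSING = c("NOT1", "NOT2"))
  expect_warning(fit <- gfp(sim$probes, reference = "NOR", pathways = pw),
                 "MISSING")

  # preprocess: per-sample median exactly 1, positive expression
  expect_equal(unname(apply(fit$eset$a, 2, median)),
               rep(1, ncol(fit$eset$a)), tolerance = 1e-9)
  expect_true(all(fit$eset$a > 0))

  # descriptors: positive AVE, defined REV, median REC at 0 per condition
  expect_true(all(fit$stats$AVE > 0))
  expect_true(all(fit$stats$REV >= 0))
  for (cond in fit$conditions) {
    rec <- fit$stats$REC[fit$stats$condition == cond]
    expect_equal(median(rec[is.finite(rec)]), 0, tolerance = 1e-9)
  }

  # regulation: the regulome never contains p >= 0.05, |x| >= 1 always,
  # WIR vanishes exactly at |x| = 1 and carries the sign of x
  reg <- fit$regulation
  expect_true(all(abs(reg$x) >= 1))
  expect_true(all(reg$p[reg$significant] < 0.05))
  expect_true(all(abs(reg$x[reg$significant]) > reg$CUT[reg$significant]))
  expect_true(all(sign(reg$WIR[abs(reg$x) > 1]) ==
                    sign(reg$x[abs(reg$x) > 1])))

  # fabric: TDI dominates each of its components
  expect_true(all(reg$TDI >= abs(reg$WIR) - 1e-12))
  expect_true(all(reg$TDI >= abs(reg$delta_control) - 1e-12))
  expect_true(all(reg$TDI >= abs(reg$delta_cor) - 1e-12))
  expect_equal(reg$TDI,
               sqrt(reg$WIR^2 + reg$delta_control^2 + reg$delta_cor^2),
               tolerance = 1e-12)

  # coordination summaries: COORD identity and bounded percentages,
  # quantified-denominator convention
  co <- fit$pathways$coordination
  expect_equal(co$COORD, co$pct_syn + co$pct_ant - co$pct_ind,
               tolerance = 1e-9)
  expect_true(all(co$pct_syn + co$pct_ant + co$pct_ind <= 100 + 1e-9))
  pr <- fit$pathways$regulation
  sig_a <- subset(reg, contrast == "PTA->NOR" &
                    gene %in% pw$PATHA & significant)
  expect_equal(pr$pct_up[pr$pathway == "PATHA" &
                           pr$contrast == "PTA->NOR"],
               100 * sum(sig_a$x > 0) / pr$n_quantified[1])
  # WPR equals the brute-force mean of |WIR| over the quantified set
  expect_equal(pr$WPR[pr$pathway == "PATHA" & pr$contrast == "PTA->NOR"],
               mean(abs(reg$WIR[reg$contrast == "PTA->NOR" &
                                  reg$gene %in% pw$PATHA])),
               tolerance = 1e-12)

  # planted regulations are recovered with the right directions
  expect_true(reg$significant[reg$gene == "G0001" &
                                reg$contrast == "PTA->NOR"])
  expect_identical(reg$direction[reg$gene == "G0001" &
                                   reg$contrast == "PTA->NOR"], "up")
  expect_true(reg$significant[reg$gene == "G0002" &
                                reg$contrast == "PTB->NOR"])
  expect_identical(reg$direction[reg$gene == "G0002" &
                                   reg$contrast == "PTB->NOR"], "down")

  # methods run and agree with the components
  expect_output(print(fit), "Genomic fabric")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.gfp")
  expect_output(print(sm), "COORD")
  cf <- coef(fit)
  expect_identical(dim(cf), c(nrow(fit$eset$a), 3L))
  expect_equal(cf["G0005", "NOR"],
               fit$stats$AVE[fit$stats$gene == "G0005" &
                               fit$stats$condition == "NOR"])
})

test_that("reruns are deterministic and written tables diff cleanly", {
  cfg <- gfp_sim_config(n_genes = 20, conditions = c("NOR", "TUM"),
                        seed = 55)
  sim <- gfp_simulate(cfg)
  fit1 <- gfp(sim$probes, reference = "NOR",
              pathways = list(P = sprintf("G%04d", 1:6)))
  fit2 <- gfp(gfp_simulate(cfg)$probes, reference = "NOR",
              pathways = list(P = sprintf("G%04d", 1:6)))
  expect_equal(fit1$regulation, fit2$regulation, tolerance = 0)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_gfp_tables(fit1, d1)
  write_gfp_tables(fit2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  expect_true(all(c("descriptors.tsv", "regulation.tsv", "gch.tsv",
                    "classes_NOR.tsv", "pathway_coordination.tsv")
                  %in% list.files(d1)))
})

test_that("swapping the reference negates x and delta_control", {
  cfg <- gfp_sim_config(n_genes = 15, conditions = c("NOR", "TUM"),
                        planted_folds = data.frame(
                          gene = "G0001", condition = "TUM", fold = 2.5),
                        seed = 66)
  sim <- gfp_simulate(cfg)
  f1 <- gfp(sim$probes, reference = "NOR")
  f2 <- gfp(sim$probes, reference = "TUM")
  flip <- abs(f1$regulation$x) > 1
  expect_equal(f2$regulation$x[flip], -f1$regulation$x[flip],
               tolerance = 1e-12)
  expect_equal(f2$regulation$delta_control,
               -f1$regulation$delta_control, tolerance = 1e-12)
  expect_equal(f2$regulation$p, f1$regulation$p, tolerance = 1e-12)
  expect_error(gfp(sim$probes, reference = "XXX"), "reference")
})

test_that("the pipeline recovers planted folds at the stated rates", {
  sig2 <- 0L
  sig1 <- 0L
  n_seeds <- 40L
  for (s in seq_len(n_seeds)) {
    cfg <- gfp_sim_config(
      n_genes = 12, conditions = c("NOR", "TUM"),
      cv_range = c(0.1, 0.1), spot_cv = 0,
      planted_folds = data.frame(gene = "G0001", condition = "TUM",
                                 fold = 2),
      seed = 2000 + s)
    fit <- gfp(gfp_simulate(cfg)$probes, reference = "NOR")
    reg <- fit$regulation
    if (reg$significant[reg$gene == "G0001"]) sig2 <- sig2 + 1L
    # G0002 carries no fold: its calls estimate the false-positive rate
    if (reg$significant[reg$gene == "G0002"]) sig1 <- sig1 + 1L
  }
  expect_gte(sig2 / n_seeds, 0.80)
  expect_lte(sig1 / n_seeds, 0.10)
})

test_that("planted correlation signs are classified SYN and ANT", {
  # classified in the spot-paired mode (2 spots -> 8 paired values), the
  # regime where the significance threshold drops to 0.71
  syn_ok <- 0L
  ant_ok <- 0L
  n_seeds <- 20L
  block_cv <- structure(rep(0.25, 4), names = sprintf("G%04d", 1:4))
  for (s in seq_len(n_seeds)) {
    cfg <- gfp_sim_config(
      n_genes = 60, conditions = "NOR", cv_range = c(0.1, 0.3),
      baseline_mean = 5000, spots_per_gene = 2L, cv_overrides = block_cv,
      correlation_blocks = list(
        list(genes = c("G0001", "G0002"), loading = 0.99),
        list(genes = c("G0003", "G0004"), loading = c(0.99, -0.99))),
      seed = 3000 + s)
    es <- normalize_probes(filter_probes(gfp_simulate(cfg)$probes))
    cm <- cor_matrices(es, mode = "spot")$NOR
    m <- attr(cm, "m")
    if (classify_pair(cm["G0001", "G0002"], m) == "SYN") syn_ok <- syn_ok + 1L
    if (classify_pair(cm["G0003", "G0004"], m) == "ANT") ant_ok <- ant_ok + 1L
  }
  expect_gt(syn_ok / n_seeds, 0.5)
  expect_gt(ant_ok / n_seeds, 0.5)
})
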