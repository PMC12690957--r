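test_that("simulation is deterministic for a fixed seed", {
  cfg <- shadeSimConfig(n_genes = 60, n_regions = 70, n_tf_peaks = 20,
                        chrom_length = 5e5)
  s1 <- simulateShadeExperiment(cfg, seed = 3)
  s2 <- simulateShadeExperiment(cfg, seed = 3)
  expect_identical(granges(simRegions(s1)), granges(simRegions(s2)))
  expect_identical(assay(simGeneCounts(s1)), assay(simGeneCounts(s2)))
  expect_identical(simTruth(s1)$gene_class, simTruth(s2)$gene_class)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeSimFixtures(s1, d1); writeSimFixtures(s2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
})

test_that("structural truth fractions are exact under half-up rounding", {
  sim <- smallSim()
  reg <- simRegions(sim)
  cfg <- sim@config
  expect_identical(sum(reg$promoter_proximal),
                   as.integer(floor(cfg$frac_promoter_proximal *
                                      cfg$n_regions + 0.5)))
  tf <- simTfPeaks(sim)
  expect_identical(sum(tf$open),
                   as.integer(floor(cfg$frac_tf_peaks_open *
                                      cfg$n_tf_peaks + 0.5)))
  # promoter-proximal truth: midpoint within 2 kb 5' of the host gene TSS
  genes <- simGenes(sim)
  prom <- reg[reg$promoter_proximal]
  g <- genes[prom$gene_id]
  tss <- tssPosition(g)
  mid <- start(prom) + width(prom) %/% 2
  d <- ifelse(as.character(strand(g)) == "+", mid - tss, tss - mid)
  expect_true(all(d >= -2000 & d < 0))
  # class labels cover every feature exactly once
  expect_identical(sort(names(simTruth(sim)$gene_class)),
                   sort(genes$gene_id))
  expect_false(any(is.na(reg$class)))
})

test_that("degenerate region counts are handled", {
  cfg <- shadeSimConfig(n_genes = 40, n_regions = 0, n_tf_peaks = 0,
                        chrom_length = 5e5, n_blacklist_promoter = 0,
                        n_blacklist_distal = 0)
  sim <- simulateShadeExperiment(cfg, seed = 2)
  expect_identical(length(simRegions(sim)), 0L)
  expect_identical(length(simGenes(sim)), 40L)
  expect_error(simulateAnnotation(shadeSimConfig(n_genes = 5000,
                                                 chrom_length = 1e5)),
               "infeasible")
})

test_that("nbDraw recovers NB2 moments and the Poisson limit", {
  set.seed(101)
  x <- nbDraw(1e5, 5, 0)
  expect_lt(abs(mean(x) - 5), 0.1)
  y <- nbDraw(1e5, 100, 0.1)
  expect_lt(abs(var(y) - 1100) / 1100, 0.1)
  expect_lt(abs(mean(y) - 100), 1.5)
  expect_error(nbDraw(1, 0, 0.1), "positive")
  expect_error(nbDraw(1, 5, -0.1), "non-negative")
})

test_that("replicate peaks reproduce regions exactly at zero jitter", {
  cfg <- shadeSimConfig(n_genes = 60, n_regions = 70, n_tf_peaks = 10,
                        chrom_length = 5e5, jitter_sd = 0,
                        frac_private_false_peaks = 0)
  set.seed(5)
  ann <- simulateAnnotation(cfg)
  pk <- simulateReplicatePeaks(ann, cfg)
  n_reg <- length(ann$regions)
  for (r in pk) {
    nuclear <- r[!as.character(seqnames(r)) %in% c("ChrC", "ChrM")]
    expect_identical(length(nuclear), n_reg)
    expect_identical(sort(start(nuclear)), sort(start(ann$regions)))
    expect_identical(sort(end(nuclear)), sort(end(ann$regions)))
  }
})

test_that("private false peaks are replicate-private and land off-truth", {
  sim <- smallSim()
  cfg <- sim@config
  n_private <- as.integer(floor(cfg$frac_private_false_peaks * cfg$n_regions))
  reg <- simRegions(sim)
  for (pk in simPeaks(sim)) {
    nuclear <- pk[!as.character(seqnames(pk)) %in% c("ChrC", "ChrM")]
    expect_identical(length(nuclear), length(reg) + n_private)
    priv <- nuclear[GenomicRanges::countOverlaps(nuclear, reg) == 0]
    expect_identical(length(priv), n_private)
    d <- GenomicRanges::distanceToNearest(priv, reg)
    expect_true(all(S4Vectors::mcols(d)$distance >= 1000))
  }
})

test_that("planted expression profiles have the stated closed forms", {
  lfc <- 1.5
  r <- plantedLog2Profile("transient_up_tf_dep", "WT", "LRFR_1h", lfc)
  expect_equal(2^r, 2^1.5)
  expect_identical(plantedLog2Profile("transient_up_tf_dep", "tf_mutant",
                                      c("HRFR", "LRFR_1h", "LRFR_25h"), lfc),
                   c(0, 0, 0))
  expect_identical(plantedLog2Profile("null", "WT",
                                      c("HRFR", "LRFR_1h", "LRFR_25h"), lfc),
                   c(0, 0, 0))
  # truth means obey the profiles
  sim <- smallSim()
  tr <- simTruth(sim)
  tu <- names(tr$gene_class)[tr$gene_class == "transient_up_tf_dep"][1]
  mu <- tr$gene_mu[tu, ]
  design <- simDesign(sim)
  wt1 <- design$sample_id[design$genotype == "WT" &
                            design$condition == "LRFR_1h"][1]
  wth <- design$sample_id[design$genotype == "WT" &
                            design$condition == "HRFR"][1]
  m1 <- design$sample_id[design$genotype == "tf_mutant" &
                           design$condition == "LRFR_1h"][1]
  mh <- design$sample_id[design$genotype == "tf_mutant" &
                           design$condition == "HRFR"][1]
  expect_equal(unname(mu[wt1] / mu[wth]), 2^1.5)
  expect_equal(unname(mu[m1] / mu[mh]), 1)
})

test_that("every true target gene's window catches a TF peak", {
  sim <- smallSim()
  tg <- callTargets(simTfPeaks(sim), simGenes(sim))
  expect_setequal(tg$gene_id[tg$bound], simTruth(sim)$target_genes)
})

test_that("config validation rejects bad inputs", {
  expect_error(shadeSimConfig(frac_promoter_proximal = 1.2), "fraction")
  expect_error(shadeSimConfig(dispersion = -1), "dispersion")
  expect_error(shadeSimConfig(gene_class_props = c(a = 0.9, b = 0.2)),
               "sum")
})
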