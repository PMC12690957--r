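gr <- function(chrom, start1, end1, ...) GRanges(chrom, IRanges(start1, end1), ...)

mkgene <- function(chrom, start1, end1, strand, id) {
  g <- gr(chrom, start1, end1, strand = strand)
  g$gene_id <- id
  g
}

test_that("nearestTss signed distances and bins, strand-aware", {
  # + strand gene, TSS at 10001; peak midpoint 9201 -> 800 bp upstream
  g <- mkgene("Chr1", 10001, 12000, "+", "gA")
  pk <- gr("Chr1", 9101, 9300)
  ann <- nearestTss(pk, g)
  expect_identical(ann$signed_distance, -800L)
  expect_identical(ann$bin, "promoter_0.1-2kb_5'")

  # - strand gene, TSS at 20001; a point to its right is upstream
  gm <- mkgene("Chr1", 18001, 20001, "-", "gB")
  pk2 <- gr("Chr1", 20401, 20600)  # midpoint 20501
  ann2 <- nearestTss(pk2, gm)
  expect_identical(ann2$signed_distance, -500L)
  expect_identical(ann2$bin, "promoter_0.1-2kb_5'")

  # midpoint exactly at the TSS
  ann3 <- nearestTss(gr("Chr1", 9901, 10100), g)  # midpoint 10001
  expect_identical(ann3$signed_distance, 0L)
  expect_identical(ann3$bin, "TSS")

  # threshold arithmetic for the remaining bins
  genes <- g
  cases <- list(list(mid = 10001 - 2500, bin = "upstream_2-3kb_5'"),
                list(mid = 10001 - 3500, bin = "distal"),
                list(mid = 11000, bin = "gene_body"),
                list(mid = 12500, bin = "downstream"),
                list(mid = 13500, bin = "distal"))
  for (cs in cases) {
    p <- gr("Chr1", cs$mid - 100, cs$mid + 100)  # midpoint == cs$mid
    expect_identical(nearestTss(p, genes)$bin, cs$bin, info = cs$bin)
  }
  expect_error(nearestTss(pk, g[0]), "empty gene list")
})

test_that("nearestTss prefers the summit and breaks ties lexicographically", {
  g2 <- c(mkgene("Chr1", 1001, 2000, "+", "gB"),
          mkgene("Chr1", 3001, 4000, "+", "gA"))  # TSSs 1001 and 3001
  pk <- gr("Chr1", 1901, 2100)  # midpoint 2001: equidistant from both TSSs
  expect_identical(nearestTss(pk, g2)$gene_id, "gA")
  pk$peakSummit <- 10L          # summit at 1911 -> nearest is gB
  expect_identical(nearestTss(pk, g2)$gene_id, "gB")
})

test_that("nearestTss matches the brute-force oracle", {
  set.seed(31)
  for (i in 1:200) {
    n_genes <- sample(2:6, 1)
    gs <- sample.int(8000, n_genes)
    genes <- GRanges(sample(c("Chr1", "Chr2"), n_genes, TRUE),
                     IRanges(gs, gs + sample(200:900, n_genes, TRUE)),
                     strand = sample(c("+", "-"), n_genes, TRUE))
    genes$gene_id <- sprintf("g%02d", sample.int(99, n_genes))
    peaks <- randomPeakSet(5)
    # restrict peaks to chromosomes that have genes (else no nearest exists)
    peaks <- peaks[as.character(seqnames(peaks)) %in%
                     as.character(seqnames(genes))]
    if (!length(peaks)) next
    got <- nearestTss(peaks, genes)
    want <- bruteNearestTss(peaks, genes)
    expect_identical(got$gene_id, want$gene_id, info = paste("instance", i))
    expect_identical(got$signed_distance, want$signed_distance)
  }
})

test_that("callTargets window arithmetic and limits", {
  g <- mkgene("Chr1", 10001, 12000, "+", "gA")
  expect_true(callTargets(gr("Chr1", 7101, 7300), g)$bound)    # in window
  expect_false(callTargets(gr("Chr1", 6801, 6990), g)$bound)   # misses it
  # zero windows reduce to gene-body overlap
  expect_true(callTargets(gr("Chr1", 11990, 12500), g, 0, 0)$bound)
  expect_false(callTargets(gr("Chr1", 12001, 12500), g, 0, 0)$bound)
  expect_error(callTargets(gr("Chr1", 1, 10), g, -1, 0), "non-negative")
  # one peak may bind two genes with overlapping windows
  g2 <- c(g, mkgene("Chr1", 13001, 14000, "+", "gB"))
  tc <- callTargets(gr("Chr1", 12500, 12700), g2)
  expect_identical(tc$bound, c(TRUE, TRUE))
})

test_that("callTargets matches the brute-force oracle", {
  set.seed(32)
  for (i in 1:200) {
    n_genes <- sample(2:6, 1)
    gs <- sample.int(9000, n_genes)
    genes <- GRanges(sample(c("Chr1", "Chr2"), n_genes, TRUE),
                     IRanges(gs, gs + sample(200:900, n_genes, TRUE)),
                     strand = sample(c("+", "-"), n_genes, TRUE))
    genes$gene_id <- sprintf("g%02d", seq_len(n_genes))
    peaks <- randomPeakSet(5)
    got <- callTargets(peaks, genes, 1500, 400)
    expect_identical(got$bound, bruteCallTargets(peaks, genes, 1500, 400),
                     info = paste("instance", i))
  }
})

test_that("open/closed classification is a point rule", {
  region <- gr("Chr1", 1001, 1400)
  names(region) <- "rA"
  inpk <- gr("Chr1", 1101, 1300)
  res <- classifyAccessibility(inpk, region)
  expect_identical(res$calls$state, "open")
  expect_identical(res$calls$overlapping_region, "rA")
  # peak overlaps by a sliver but its midpoint is outside -> closed
  edge <- gr("Chr1", 1391, 1800)  # midpoint 1596
  expect_identical(classifyAccessibility(edge, region)$calls$state, "closed")
  # summit overrides the midpoint
  edge$peakSummit <- 5L           # summit 1396, inside
  expect_identical(classifyAccessibility(edge, region)$calls$state, "open")
  expect_identical(classifyAccessibility(GRanges(), region)$fraction_closed, 0)
})

test_that("truth recovery: targets and open fraction on the fixture", {
  sim <- smallSim()
  tr <- simTruth(sim)
  cons <- filterConsensus(buildConsensus(simPeaks(sim)), simBlacklist(sim))
  res <- classifyAccessibility(simTfPeaks(sim), cons)
  expect_identical(res$calls$state == "open", unname(tr$tf_open))
  expect_equal(res$fraction_closed, mean(!tr$tf_open))
  tg <- callTargets(simTfPeaks(sim), simGenes(sim))
  expect_setequal(tg$gene_id[tg$bound], tr$target_genes)
})
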