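gr <- function(chrom, start1, end1, ...)
  GRanges(chrom, IRanges(start1, end1), ...)

test_that("overlapLength follows the closed-interval arithmetic", {
  a <- gr("Chr1", 101, 200)  # [100, 200) in half-open terms
  b <- gr("Chr1", 151, 250)
  expect_identical(overlapLength(a, b), 50L)
  expect_identical(overlapLength(a, a), 100L)
  expect_identical(overlapLength(a, gr("Chr2", 101, 200)), 0L)
  # symmetry and the min-width bound on random pairs
  set.seed(11)
  for (i in 1:50) {
    x <- randomPeakSet(1); y <- randomPeakSet(1)
    expect_identical(overlapLength(x, y), overlapLength(y, x))
    expect_lte(overlapLength(x, y), min(width(x), width(y)))
  }
})

test_that("mergeIntervals merges touching intervals and is idempotent", {
  touching <- c(gr("Chr1", 1, 10), gr("Chr1", 11, 20))  # [0,10) + [10,20)
  m <- mergeIntervals(touching)
  expect_identical(start(m), 1L)
  expect_identical(end(m), 20L)
  contained <- c(gr("Chr1", 1, 10), gr("Chr1", 6, 8))
  expect_identical(width(mergeIntervals(contained)), 10L)
  expect_identical(length(mergeIntervals(GRanges())), 0L)
  set.seed(12)
  for (i in 1:25) {
    x <- randomPeakSet(8)
    m1 <- mergeIntervals(x)
    expect_identical(m1, mergeIntervals(m1))          # idempotent
    expect_lte(sum(width(m1)), sum(width(x)))          # never increases bp
    expect_true(all(GenomicRanges::isDisjoint(m1)))
  }
})

test_that("removeBlacklisted drops 1-bp overlaps and organellar intervals", {
  bl <- blacklist(gr("Chr1", 200, 300))
  expect_identical(length(removeBlacklisted(gr("Chr1", 101, 200), bl)), 0L)
  expect_identical(length(removeBlacklisted(gr("Chr1", 101, 199), bl)), 1L)
  expect_identical(length(removeBlacklisted(gr("ChrM", 101, 200), bl)), 0L)
  empty_bl <- blacklist(organelles = character(0))
  x <- GRanges(c("Chr1", "ChrM"), IRanges(c(1, 5), c(50, 20)))
  expect_identical(granges(removeBlacklisted(x, empty_bl)), granges(x))
})

test_that("strand-aware TSS/TES anatomy", {
  g <- c(gr("Chr1", 1001, 2000, strand = "+"),
         gr("Chr1", 5001, 6000, strand = "-"))
  expect_identical(tssPosition(g), c(1001L, 6000L))
  expect_identical(tesPosition(g), c(2000L, 5001L))
  expect_error(tssPosition(gr("Chr1", 1, 10)), "stranded")
})

test_that("BED and narrowPeak round-trip byte-identically", {
  bed_lines <- c("Chr1\t999\t2000\tx\t0\t+", "Chr2\t0\t100\ty\t5\t.")
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(bed_lines, f)
  x <- readBed(f)
  expect_identical(start(x), c(1000L, 1L))  # 0-based on disk -> 1-based here
  expect_identical(end(x), c(2000L, 100L))
  f2 <- withr::local_tempfile(fileext = ".bed")
  writeBed(x, f2)
  expect_identical(readLines(f2), bed_lines)

  np_lines <- c("Chr1\t999\t2000\tp1\t100\t.\t5.5\t-1\t-1\t50",
                "ChrC\t10\t310\tp2\t7\t.\t1\t-1\t-1\t-1")
  f3 <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(np_lines, f3)
  p <- readNarrowPeak(f3)
  expect_identical(p$peakSummit, c(50L, NA_integer_))
  expect_identical(chromShade:::peakReferencePoint(p)[1], 1050L)
  f4 <- withr::local_tempfile(fileext = ".narrowPeak")
  writeNarrowPeak(p, f4)
  expect_identical(readLines(f4), np_lines)
})

test_that("malformed interval files raise errors naming the line", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("Chr1\t0\t100\ta\t0\t+", "Chr1\t5\t50"), f)
  expect_error(readBed(f), "line 2")
  f2 <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines("Chr1\t0\t100", f2)
  expect_error(readNarrowPeak(f2), "line 1")
})

test_that("GFF3 gene models convert at the boundary and validate strand", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "Chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tID=gA",
               "Chr1\tsrc\tgene\t3001\t4000\t.\t-\t.\tID=gB"), f)
  g <- readGeneModels(f)
  expect_identical(start(g), c(1001L, 3001L))  # 0-based starts 1000, 3000
  expect_identical(tssPosition(g), c(1001L, 4000L))
  f2 <- withr::local_tempfile(fileext = ".gff3")
  writeGeneModels(g, f2)
  g2 <- readGeneModels(f2)
  expect_identical(granges(g), granges(g2))
  expect_identical(g$gene_id, g2$gene_id)

  f3 <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "Chr1\tsrc\tgene\t1\t10\t.\t.\t.\tID=gX"), f3)
  expect_error(readGeneModels(f3), "nstranded")
})

test_that("count matrix and design tables round-trip", {
  m <- matrix(0:5, nrow = 2, dimnames = list(c("fa", "fb"),
                                             c("s1", "s2", "s3")))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeCountMatrix(m, f)
  expect_identical(readCountMatrix(f), m)
  d <- shadeDesign(replicates = 2)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeDesign(d, f2)
  d2 <- readDesign(f2)
  expect_identical(d2$sample_id, d$sample_id)
  expect_identical(d2$condition, d$condition)
})
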