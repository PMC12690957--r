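## Readers and writers for the plain-text formats the pipeline consumes.
##
## BED6 and narrowPeak (BED6+4) are 0-based half-open on disk and converted
## to the 1-based closed GRanges convention in memory; GFF3 is 1-based
## inclusive already. Writing inverts the conversion, so write(read(x)) is
## byte-identical for well-formed files. narrowPeak/BED are simple fixed
## tab-separated tables and are read with the base table reader; GFF3 goes
## through rtracklayer.

.checkLines <- function(n_fields, expected, path) {
  bad <- which(n_fields != expected)
  if (length(bad))
    stop(sprintf("malformed line %d in '%s': expected %d fields, found %d",
                 bad[1], path, expected, n_fields[bad[1]]))
}

#' Read and write BED6 interval files
#'
#' @param path File path.
#' @param x A `GRanges` with optional `name`, `score` metadata columns.
#' @return `readBed` returns a `GRanges`; `writeBed` invisibly returns `path`.
#' @export
readBed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  .checkLines(lengths(fields), 6L, path)
  m <- matrix(unlist(fields), ncol = 6L, byrow = TRUE)
  gr <- GRanges(m[, 1],
                IRanges(as.integer(m[, 2]) + 1L, as.integer(m[, 3])),
                strand = ifelse(m[, 6] %in% c("+", "-"), m[, 6], "*"))
  gr$name <- m[, 4]
  gr$score <- suppressWarnings(as.numeric(m[, 5]))
  names(gr) <- gr$name
  gr
}

#' @rdname readBed
#' @export
writeBed <- function(x, path) {
  strands <- as.character(strand(x))
  strands[strands == "*"] <- "."
  score <- if (is.null(x$score)) rep(0, length(x)) else x$score
  name <- if (is.null(x$name)) {
    if (is.null(names(x))) paste0("interval_", seq_along(x)) else names(x)
  } else x$name
  df <- data.frame(chrom = as.character(seqnames(x)),
                   start = format(start(x) - 1L, scientific = FALSE, trim = TRUE),
                   end = format(end(x), scientific = FALSE, trim = TRUE),
                   name = name,
                   score = score, strand = strands)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write narrowPeak (BED6+4) peak files
#'
#' The 10th column is the summit offset from the peak start (0-based, or -1
#' when absent); it is stored in the `peakSummit` metadata column and used by
#' summit-point operations downstream.
#'
#' @param path File path.
#' @param x A `GRanges` with optional `signalValue`, `pValue`, `qValue`,
#'   `peakSummit` metadata columns.
#' @return `readNarrowPeak` returns a `GRanges`.
#' @export
readNarrowPeak <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  .checkLines(lengths(fields), 10L, path)
  m <- matrix(unlist(fields), ncol = 10L, byrow = TRUE)
  gr <- GRanges(m[, 1],
                IRanges(as.integer(m[, 2]) + 1L, as.integer(m[, 3])),
                strand = ifelse(m[, 6] %in% c("+", "-"), m[, 6], "*"))
  gr$name <- m[, 4]
  gr$score <- as.numeric(m[, 5])
  gr$signalValue <- as.numeric(m[, 7])
  gr$pValue <- as.numeric(m[, 8])
  gr$qValue <- as.numeric(m[, 9])
  summit <- as.integer(m[, 10])
  summit[summit < 0L] <- NA_integer_
  gr$peakSummit <- summit
  if (any(!is.na(summit) & (summit < 0L | summit >= width(gr))))
    stop("summit offset outside peak in '", path, "'")
  names(gr) <- gr$name
  gr
}

#' @rdname readNarrowPeak
#' @export
writeNarrowPeak <- function(x, path) {
  strands <- as.character(strand(x))
  strands[strands == "*"] <- "."
  getcol <- function(col, default) {
    v <- mcols(x)[[col]]
    if (is.null(v)) rep(default, length(x)) else v
  }
  summit <- getcol("peakSummit", NA_integer_)
  summit[is.na(summit)] <- -1L
  df <- data.frame(chrom = as.character(seqnames(x)),
                   start = format(start(x) - 1L, scientific = FALSE, trim = TRUE),
                   end = format(end(x), scientific = FALSE, trim = TRUE),
                   name = getcol("name", paste0("peak_", seq_along(x))),
                   score = getcol("score", 0),
                   strand = strands,
                   signalValue = getcol("signalValue", 0),
                   pValue = getcol("pValue", -1),
                   qValue = getcol("qValue", -1),
                   peak = summit)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Extracts records of type `gene` and returns them as a `GRanges` named by
#' gene identifier (the `ID` attribute). Coordinates are kept in the GFF3
#' 1-based inclusive convention, which is the in-memory GRanges convention.
#' Genes must be stranded.
#'
#' @param path Path to a GFF3 file.
#' @return A `GRanges` of gene bodies with `gene_id` metadata, sorted.
#' @export
readGeneModels <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  genes <- gff[gff$type == "gene"]
  if (length(genes) == 0L)
    stop("no gene records in '", path, "'")
  if (any(as.character(strand(genes)) == "*"))
    stop("unstranded gene record in '", path, "'")
  ids <- genes$ID
  if (is.null(ids) || anyNA(ids)) stop("gene records without ID in '", path, "'")
  out <- granges(genes)
  out$gene_id <- as.character(ids)
  names(out) <- out$gene_id
  GenomicRanges::sort(out, ignore.strand = TRUE)
}

#' Write gene models to GFF3
#'
#' @param genes A `GRanges` of gene bodies with `gene_id`.
#' @param path Output path.
#' @export
writeGeneModels <- function(genes, path) {
  lines <- sprintf("%s\tchromShade\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                   as.character(seqnames(genes)), start(genes), end(genes),
                   as.character(strand(genes)), genes$gene_id)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read and write feature-by-sample count matrices
#'
#' Tab-separated with a header of sample identifiers and feature identifiers
#' in the first column. Counts must be non-negative integers.
#'
#' @param path File path.
#' @param counts An integer matrix with feature rownames and sample colnames.
#' @return `readCountMatrix` returns an integer matrix.
#' @export
readCountMatrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  if (any(m < 0)) stop("negative counts in '", path, "'")
  if (anyDuplicated(rownames(m))) stop("duplicate feature ids in '", path, "'")
  m
}

#' @rdname readCountMatrix
#' @export
writeCountMatrix <- function(counts, path) {
  df <- data.frame(feature_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write sample design tables
#'
#' Columns: `sample_id`, `genotype`, `condition`, `replicate`.
#'
#' @param path File path.
#' @param design A data.frame with the design columns.
#' @export
readDesign <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "genotype", "condition", "replicate")
  if (!all(need %in% names(df)))
    stop("design table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df[c("genotype", "condition", "replicate")]))
    stop("duplicate (genotype, condition, replicate) rows in design")
  df
}

#' @rdname readDesign
#' @export
writeDesign <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
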