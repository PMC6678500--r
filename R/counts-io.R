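# Readers and writers for the bin/chromosome count substrates.

.tileAutosomes <- function(seqlens, binSize) {
  seqlens <- seqlens[names(seqlens) %in% .AUTOSOMES]
  seqlens <- seqlens[order(match(names(seqlens), .AUTOSOMES))]
  starts <- lapply(seqlens, function(len) seq(0L, len - 1L, by = binSize))
  chrom <- rep(names(seqlens), lengths(starts))
  start0 <- unlist(starts, use.names = FALSE)
  ends <- pmin(start0 + binSize, rep(unname(seqlens), lengths(starts)))
  GRanges(chrom, IRanges(start = start0 + 1, end = ends))
}

.gcFromFasta <- function(bins, fastaPath) {
  idx <- scanFaIndex(fastaPath)
  faNames <- as.character(seqnames(idx))
  norm <- suppressWarnings(tryCatch(.normalizeChrom(faNames),
                                    error = function(e) faNames))
  lookup <- setNames(faNames, norm)
  query <- bins
  binChrom <- as.character(seqnames(bins))
  if (!all(binChrom %in% names(lookup)))
    stopConfig("reference FASTA lacks sequences for: %s",
               paste(setdiff(unique(binChrom), names(lookup)), collapse = ", "))
  query <- GRanges(lookup[binChrom],
                   IRanges(GenomicRanges::start(bins), GenomicRanges::end(bins)))
  seqs <- scanFa(fastaPath, query)
  freq <- letterFrequency(seqs, letters = c("G", "C", "A", "T"))
  acgt <- rowSums(freq)
  gc <- ifelse(acgt > 0, (freq[, "G"] + freq[, "C"]) / acgt, NA_real_)
  as.numeric(gc)
}

#' Bin aligned reads from a BAM file
#'
#' Counts retained alignments into fixed-width bins tiling the 22 autosomes.
#' A read is assigned to the bin containing its leftmost mapped base.
#' Unmapped, secondary, supplementary and duplicate-flagged records, records
#' below the mapping-quality threshold, and records on sex chromosomes or the
#' mitochondrion are skipped. Reference names other than `1..22/chr1..chr22`
#' (plus X/Y/M/MT) raise an error naming the offending contig.
#'
#' @param file path to a BAM file.
#' @param binSize bin width in bp (>= 1000; default 20000).
#' @param mapqMin minimum mapping quality retained (default 40; records with
#'   strictly lower MAPQ are dropped).
#' @param reference optional FASTA path used to compute per-bin GC fractions;
#'   when absent GC is `NA` (GC correction then requires external GC values).
#' @param sampleId sample name for the single output column (default: file
#'   base name).
#' @return A single-sample [BinCountMatrix-class] covering every autosome bin.
#' @export
binAlignments <- function(file, binSize = 20000L, mapqMin = 40L,
                          reference = NULL, sampleId = NULL) {
  if (!file.exists(file)) stopConfig("BAM file not found: %s", file)
  if (binSize < 1000) stopConfig("binSize must be >= 1000 bp")
  if (is.null(sampleId)) sampleId <- sub("\\.bam$", "", basename(file))
  header <- scanBamHeader(file)[[1]]$targets
  norm <- .normalizeChrom(names(header))  # errors on foreign contigs
  keep <- !is.na(norm)
  seqlens <- setNames(as.integer(header[keep]), norm[keep])
  if (!length(seqlens)) stopConfig("BAM header contains no autosomes")
  bins <- .tileAutosomes(seqlens, as.integer(binSize))

  param <- ScanBamParam(
    what = c("rname", "pos"),
    flag = scanBamFlag(isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
                       isSupplementaryAlignment = FALSE,
                       isDuplicate = FALSE),
    mapqFilter = as.integer(mapqMin))
  reads <- scanBam(file, param = param)[[1]]
  rchrom <- .normalizeChrom(as.character(reads$rname))
  sel <- !is.na(rchrom) & !is.na(reads$pos)
  rchrom <- rchrom[sel]
  pos0 <- reads$pos[sel] - 1L  # SAM is 1-based; internal convention 0-based

  nBinsPer <- ceiling(seqlens / as.integer(binSize))
  offsets <- setNames(cumsum(c(0, head(nBinsPer, -1))), names(nBinsPer))
  idx <- offsets[rchrom] + pos0 %/% as.integer(binSize) + 1
  counts <- tabulate(idx, nbins = length(bins))
  gc <- if (!is.null(reference)) .gcFromFasta(bins, reference) else NULL
  BinCountMatrix(matrix(as.numeric(counts), ncol = 1,
                        dimnames = list(NULL, sampleId)),
                 bins = bins, gc = gc)
}

#' Write / read bin-count tables
#'
#' Tab-separated schema: comment header lines (tool version, parameters),
#' then columns `chrom`, `start`, `end`, `gc`, optionally `retained`, and one
#' column per sample. Coordinates are 0-based half-open. Integer counts
#' round-trip bit-exactly.
#'
#' @param x a [BinCountMatrix-class].
#' @param path output/input TSV path.
#' @return `writeBinCounts` returns `path` invisibly; `readBinCounts` returns
#'   a [BinCountMatrix-class].
#' @export
writeBinCounts <- function(x, path) {
  gr <- rowRanges(x)
  corr <- metadata(x)$corrected
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   gc = binGC(x), check.names = FALSE)
  if (!all(binRetained(x))) df$retained <- as.integer(binRetained(x))
  df <- cbind(df, as.data.frame(assay(x, "counts"), check.names = FALSE))
  hdr <- .toolHeader(sprintf("corrected=%s",
                             if (length(corr)) paste(corr, collapse = ",") else "none"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = TRUE))
  invisible(path)
}

#' @rdname writeBinCounts
#' @export
readBinCounts <- function(path) {
  if (!file.exists(path)) stopConfig("file not found: %s", path)
  df <- tryCatch(
    read.table(path, header = TRUE, sep = "\t", comment.char = "#",
               check.names = FALSE, fill = FALSE,
               colClasses = NA, stringsAsFactors = FALSE),
    error = function(e) stopConfig("malformed bin-count table %s: %s",
                                   path, conditionMessage(e)))
  need <- c("chrom", "start", "end", "gc")
  if (!all(need %in% colnames(df)[seq_len(min(5, ncol(df)))]))
    stopConfig("bin-count table must start with columns chrom,start,end,gc")
  if (nrow(df) == 0) stopConfig("no bins in %s", path)
  retained <- NULL
  sampleCols <- setdiff(colnames(df), need)
  if ("retained" %in% sampleCols) {
    retained <- as.logical(df$retained)
    sampleCols <- setdiff(sampleCols, "retained")
  }
  if (!length(sampleCols)) stopConfig("no sample columns in %s", path)
  key <- paste(df$chrom, df$start)
  if (anyDuplicated(key))
    stopConfig("duplicate bin at row %d: %s",
               which(duplicated(key))[1], key[which(duplicated(key))[1]])
  counts <- as.matrix(df[, sampleCols, drop = FALSE])
  if (anyNA(counts))
    stopConfig("missing count at row %d", which(!complete.cases(counts))[1])
  neg <- which(rowSums(counts < 0) > 0)
  # negative values are legal only in corrected tables
  corrLine <- grep("^# corrected=", readLines(path, n = 10), value = TRUE)
  isCorrected <- length(corrLine) && !grepl("corrected=none", corrLine[1])
  if (length(neg) && !isCorrected)
    stopConfig("negative count at row %d (bin %s)", neg[1], key[neg[1]])
  corrected <- if (isCorrected)
    strsplit(sub("^# corrected=", "", corrLine[1]), ",")[[1]] else character()
  BinCountMatrix(counts, bins = df[, c("chrom", "start", "end")],
                 gc = df$gc, retained = retained, corrected = corrected)
}

#' Write / read per-autosome count tables
#'
#' Tab-separated schema: comment header, then `sample_id`, `chr1`..`chr22`.
#' Row order is preserved; totals are recomputed as row sums on read.
#'
#' @param x a [ChromCountSet-class].
#' @param path output/input TSV path.
#' @return `writeChromCounts` returns `path` invisibly; `readChromCounts`
#'   returns a [ChromCountSet-class].
#' @export
writeChromCounts <- function(x, path) {
  df <- data.frame(sample_id = sampleIds(x), chromCounts(x),
                   check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.toolHeader(), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = TRUE))
  invisible(path)
}

#' @rdname writeChromCounts
#' @export
readChromCounts <- function(path) {
  if (!file.exists(path)) stopConfig("file not found: %s", path)
  df <- tryCatch(
    read.table(path, header = TRUE, sep = "\t", comment.char = "#",
               check.names = FALSE, fill = FALSE, stringsAsFactors = FALSE),
    error = function(e) stopConfig("malformed chromosome-count table %s: %s",
                                   path, conditionMessage(e)))
  if (!"sample_id" %in% colnames(df))
    stopConfig("missing column sample_id")
  missing <- setdiff(.AUTOSOMES, colnames(df))
  if (length(missing))
    stopConfig("missing chromosome column(s): %s",
               paste(missing, collapse = ", "))
  m <- as.matrix(df[, .AUTOSOMES, drop = FALSE])
  if (anyNA(m) || !is.numeric(m))
    stopConfig("missing or non-numeric count in row %d",
               which(!complete.cases(m))[1])
  ChromCountSet(m, sampleIds = as.character(df$sample_id))
}
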