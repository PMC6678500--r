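#' Binned read-count matrix
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] subclass holding
#' per-bin read counts for one or more samples. Rows are fixed-width genomic
#' bins tiling the 22 autosomes (the last bin of each chromosome is truncated
#' at the chromosome end); columns are samples. `rowData` carries the GC
#' fraction of each bin (`gc`, in \[0, 1\], possibly `NA` when no reference
#' sequence was available) and the retention mask (`retained`) produced by
#' empty-bin filtering. Counts are non-negative integers before correction and
#' may become negative reals after GC correction (no clipping is applied, so
#' chromosome-level aggregation stays unbiased).
#'
#' @name BinCountMatrix-class
#' @aliases BinCountMatrix
#' @exportClass BinCountMatrix
setClass("BinCountMatrix", contains = "RangedSummarizedExperiment")

setValidity("BinCountMatrix", function(object) {
  msg <- character()
  if (!"counts" %in% names(assays(object)))
    msg <- c(msg, "assay 'counts' is required")
  rd <- rowData(object)
  if (!all(c("gc", "retained") %in% colnames(rd))) {
    msg <- c(msg, "rowData must contain 'gc' and 'retained'")
  } else {
    gc <- rd$gc
    if (!is.numeric(gc) || any(gc < 0 | gc > 1, na.rm = TRUE))
      msg <- c(msg, "gc fractions must lie in [0, 1] (or NA)")
    if (!is.logical(rd$retained) || anyNA(rd$retained))
      msg <- c(msg, "'retained' must be logical without NA")
  }
  sq <- as.character(seqnames(rowRanges(object)))
  if (length(sq) && !all(sq %in% .AUTOSOMES))
    msg <- c(msg, "bins must lie on chr1..chr22")
  if (length(msg)) msg else TRUE
})

#' Construct a BinCountMatrix
#'
#' @param counts numeric matrix, bins x samples.
#' @param bins a [GenomicRanges::GRanges] of bins, or a data.frame with
#'   columns `chrom`, `start`, `end` (0-based half-open coordinates).
#' @param gc per-bin GC fraction in \[0, 1\] (or `NA`). Ignored when `bins`
#'   is a GRanges that already carries a `gc` metadata column.
#' @param retained logical retention mask (default: all bins retained).
#' @param sampleIds sample identifiers (default: `colnames(counts)`).
#' @param corrected character tag describing applied corrections, e.g.
#'   `"gc"` or `c("gc", "pca")`; stored in `metadata()`.
#' @return A [BinCountMatrix-class] object.
#' @export
BinCountMatrix <- function(counts, bins, gc = NULL, retained = NULL,
                           sampleIds = colnames(counts),
                           corrected = character()) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.data.frame(bins)) {
    chrom <- .normalizeChrom(bins$chrom, allowSkip = FALSE)
    # internal convention is 0-based half-open; GRanges is 1-based closed
    bins <- GRanges(chrom, IRanges(start = bins$start + 1, end = bins$end))
  }
  if (is.null(gc)) gc <- mcols(bins)$gc
  if (is.null(gc)) gc <- rep(NA_real_, length(bins))
  if (is.null(retained)) retained <- mcols(bins)$retained
  if (is.null(retained)) retained <- rep(TRUE, length(bins))
  if (length(bins) != nrow(counts))
    stopConfig("bin list length (%d) does not match count rows (%d)",
               length(bins), nrow(counts))
  if (is.null(sampleIds)) sampleIds <- paste0("sample", seq_len(ncol(counts)))
  mcols(bins) <- DataFrame(gc = as.numeric(gc), retained = as.logical(retained))
  colnames(counts) <- sampleIds
  se <- SummarizedExperiment(assays = list(counts = counts), rowRanges = bins)
  out <- new("BinCountMatrix", se)
  metadata(out)$corrected <- corrected
  out
}

#' @describeIn BinCountMatrix-class per-bin GC fraction.
#' @param x a `BinCountMatrix`.
#' @export
setMethod("binGC", "BinCountMatrix", function(x) rowData(x)$gc)

#' @describeIn BinCountMatrix-class logical retention mask.
#' @export
setMethod("binRetained", "BinCountMatrix", function(x) rowData(x)$retained)

#' @describeIn BinCountMatrix-class sample identifiers.
#' @export
setMethod("sampleIds", "BinCountMatrix", function(x) colnames(x))

setMethod("show", "BinCountMatrix", function(object) {
  cat(sprintf("BinCountMatrix: %d bins x %d samples (%d retained bins)\n",
              nrow(object), ncol(object), sum(binRetained(object))))
  corr <- metadata(object)$corrected
  cat(sprintf("  corrected: %s\n",
              if (length(corr)) paste(corr, collapse = ",") else "none"))
})

# key used to check that a denoiser and a matrix refer to the same bins
.binKey <- function(x, retainedOnly = TRUE) {
  gr <- rowRanges(x)
  key <- paste0(as.character(seqnames(gr)), ":", GenomicRanges::start(gr) - 1L)
  if (retainedOnly) key[binRetained(x)] else key
}

#' Per-sample autosomal count vectors
#'
#' Holds, for each sample, the 22-vector of autosomal read counts (raw or
#' corrected) used by the z-score models. Sex chromosomes are excluded
#' throughout because their read share depends on fetal sex. Counts may be
#' non-integer (after GC/PCA correction) but must be finite; subsampling
#' additionally requires integer counts.
#'
#' @name ChromCountSet-class
#' @aliases ChromCountSet
#' @exportClass ChromCountSet
setClass("ChromCountSet", representation(counts = "matrix"))

setValidity("ChromCountSet", function(object) {
  m <- object@counts
  msg <- character()
  if (ncol(m) != 22L) msg <- c(msg, "counts must have exactly 22 columns")
  else if (!identical(colnames(m), .AUTOSOMES))
    msg <- c(msg, "columns must be named chr1..chr22")
  if (!is.numeric(m) || any(!is.finite(m)))
    msg <- c(msg, "counts must be finite numbers")
  if (length(msg)) msg else TRUE
})

#' Construct a ChromCountSet
#'
#' @param counts numeric matrix samples x 22 (columns `chr1..chr22` or
#'   `1..22`), or a single 22-vector.
#' @param sampleIds optional sample identifiers (default: rownames).
#' @return A [ChromCountSet-class].
#' @export
ChromCountSet <- function(counts, sampleIds = NULL) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  counts <- as.matrix(counts)
  if (ncol(counts) != 22L)
    stopConfig("expected 22 autosome columns, got %d", ncol(counts))
  if (!is.null(colnames(counts)))
    colnames(counts) <- .normalizeChrom(colnames(counts), allowSkip = FALSE)
  else colnames(counts) <- .AUTOSOMES
  counts <- counts[, .AUTOSOMES, drop = FALSE]
  storage.mode(counts) <- "double"
  if (nrow(counts) > 0) {
    if (!is.null(sampleIds)) rownames(counts) <- sampleIds
    if (is.null(rownames(counts)))
      rownames(counts) <- paste0("sample", seq_len(nrow(counts)))
  }
  new("ChromCountSet", counts = counts)
}

#' @describeIn ChromCountSet-class samples x 22 count matrix.
#' @param x a `ChromCountSet`.
#' @export
setMethod("chromCounts", "ChromCountSet", function(x) x@counts)

#' @describeIn ChromCountSet-class per-sample total autosomal count `n`.
#' @export
setMethod("sampleTotals", "ChromCountSet", function(x) rowSums(x@counts))

#' @describeIn ChromCountSet-class sample identifiers.
#' @export
setMethod("sampleIds", "ChromCountSet", function(x) rownames(x@counts))

#' @export
setMethod("length", "ChromCountSet", function(x) nrow(x@counts))

#' @export
setMethod("[", "ChromCountSet", function(x, i, j, ..., drop = FALSE) {
  new("ChromCountSet", counts = x@counts[i, , drop = FALSE])
})

setMethod("show", "ChromCountSet", function(object) {
  n <- sampleTotals(object)
  cat(sprintf("ChromCountSet: %d samples x 22 autosomes\n", length(object)))
  if (length(object))
    cat(sprintf("  total reads: min %.3g / median %.3g / max %.3g\n",
                min(n), median(n), max(n)))
})
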