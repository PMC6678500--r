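# Per-sample GC correction, cohort PCA denoising, aggregation, subsampling.

#' Mask bins with insufficient coverage across training samples
#'
#' A bin is retained when the fraction of samples with a nonzero count is at
#' least `minNonzeroFraction`. The default (1) drops a bin that is empty in
#' any sample — the strictest reading of empty-bin filtering; 0 retains all
#' bins. Counts are never modified, only the retention mask.
#'
#' @param x a [BinCountMatrix-class].
#' @param minNonzeroFraction required fraction of samples with nonzero count
#'   in \[0, 1\] (default 1).
#' @return `x` with an updated `retained` mask (AND-combined with any
#'   existing mask).
#' @export
filterEmptyBins <- function(x, minNonzeroFraction = 1) {
  if (minNonzeroFraction < 0 || minNonzeroFraction > 1)
    stopConfig("minNonzeroFraction must be in [0, 1]")
  counts <- assay(x, "counts")
  frac <- rowMeans(counts != 0)
  keep <- frac >= minNonzeroFraction
  rowData(x)$retained <- binRetained(x) & keep
  if (!any(binRetained(x))) stopConfig("no informative bins")
  x
}

#' Fit a per-sample GC LOESS curve
#'
#' Local regression of the bin read count on bin GC fraction, used to predict
#' the expected count `RCloess` of every bin from its GC content. The fit is
#' evaluated at the observed GC values and stored as an interpolation grid.
#'
#' @param counts numeric vector of bin counts (retained bins of one sample).
#' @param gc matching GC fractions.
#' @param span LOESS smoothing fraction in (0, 1\]; default 0.3.
#' @return A [GcCorrectionFit-class].
#' @export
fitGcLoess <- function(counts, gc, span = 0.3) {
  ok <- is.finite(counts) & is.finite(gc)
  counts <- counts[ok]; gc <- gc[ok]
  if (length(counts) < 50)
    stopConfig("need >= 50 retained bins with GC values to fit (got %d)",
               length(counts))
  if (diff(range(gc)) == 0)
    stopConfig(paste("degenerate GC range (all values identical);",
                     "consider skipping GC correction"))
  fit <- loess(counts ~ gc, span = span, degree = 1,
               family = "gaussian",
               control = stats::loess.control(surface = "interpolate"))
  grid <- sort(unique(gc))
  fitted <- as.numeric(predict(fit, newdata = data.frame(gc = grid)))
  new("GcCorrectionFit", span = span, gcGrid = grid, fittedGrid = fitted,
      rcAvg = mean(counts))
}

.predictGc <- function(fit, gc) {
  approx(fit@gcGrid, fit@fittedGrid, xout = gc, rule = 2)$y
}

#' Apply a GC correction to bin counts
#'
#' Corrects each bin count for its GC-predicted deviation from the global
#' average: mode `"signed"` (default) subtracts the signed deviation,
#' `RCcor = RC - (RCloess - RCavg)`, which recentres counts and removes the
#' GC trend in both directions; mode `"as_printed"` subtracts the absolute
#' deviation, `RCcor = RC - |RCloess - RCavg|`, which penalises any
#' GC-predicted departure regardless of direction. Corrected counts may be
#' negative; they are deliberately not clipped (clipping would bias
#' chromosome proportions).
#'
#' @param counts numeric vector of observed bin counts.
#' @param gc matching GC fractions.
#' @param fit a [GcCorrectionFit-class] from the same sample.
#' @param mode `"signed"` or `"as_printed"`.
#' @return numeric vector of corrected counts.
#' @export
applyGcCorrection <- function(counts, gc, fit,
                              mode = c("signed", "as_printed")) {
  mode <- match.arg(mode)
  dev <- .predictGc(fit, gc) - fit@rcAvg
  if (mode == "as_printed") counts - abs(dev) else counts - dev
}

#' GC-correct every sample of a bin matrix
#'
#' Convenience wrapper: fits [fitGcLoess()] per sample on retained bins and
#' applies [applyGcCorrection()]. Masked-out bins are left untouched (they
#' are excluded downstream anyway).
#'
#' @param x a [BinCountMatrix-class] with GC fractions.
#' @param mode correction mode, see [applyGcCorrection()].
#' @param span LOESS span.
#' @return a corrected [BinCountMatrix-class] tagged `corrected=gc`.
#' @export
gcCorrectSamples <- function(x, mode = c("signed", "as_printed"),
                             span = 0.3) {
  mode <- match.arg(mode)
  counts <- assay(x, "counts")
  ret <- binRetained(x)
  gc <- binGC(x)
  if (anyNA(gc[ret]))
    stopConfig("GC fractions are missing for retained bins")
  for (j in seq_len(ncol(counts))) {
    fit <- fitGcLoess(counts[ret, j], gc[ret], span = span)
    counts[ret, j] <- applyGcCorrection(counts[ret, j], gc[ret], fit, mode)
  }
  out <- BinCountMatrix(counts, bins = rowRanges(x), gc = gc, retained = ret,
                        sampleIds = colnames(counts),
                        corrected = unique(c(metadata(x)$corrected, "gc")))
  out
}

#' Fit a principal-component denoiser on euploid controls
#'
#' Bin counts of each training sample are normalized to proportions (so depth
#' differences do not dominate), centered, and decomposed; the top
#' `nComponents` directions capture noise shared across euploid individuals
#' (recurrent CNVs, batch structure) and are later subtracted from every
#' sample.
#'
#' @param x a GC-corrected [BinCountMatrix-class] of euploid controls.
#' @param nComponents number of leading components to remove (>= 0).
#' @return A [PcaDenoiser-class].
#' @export
fitPcaDenoiser <- function(x, nComponents = 5L) {
  nComponents <- as.integer(nComponents)
  if (nComponents < 0L) stopConfig("nComponents must be >= 0")
  ret <- binRetained(x)
  counts <- assay(x, "counts")[ret, , drop = FALSE]
  nS <- ncol(counts)
  if (nS < nComponents + 2L)
    stopConfig("need at least nComponents + 2 = %d training samples, got %d",
               nComponents + 2L, nS)
  P <- t(counts) / colSums(counts)   # samples x bins, rows sum to 1
  binMeans <- colMeans(P)
  key <- .binKey(x)
  if (nComponents == 0L)
    return(new("PcaDenoiser", nComponents = 0L, binMeans = binMeans,
               components = matrix(0, 0, length(binMeans)), binKey = key))
  pc <- prcomp(P, center = TRUE, rank. = nComponents)
  if (length(pc$sdev) < nComponents ||
      pc$sdev[nComponents] <= 1e-12 * max(pc$sdev[1], .Machine$double.eps))
    stopConfig("training matrix is rank deficient: cannot extract %d component(s)",
               nComponents)
  new("PcaDenoiser", nComponents = nComponents, binMeans = binMeans,
      components = t(pc$rotation), binKey = key)
}

#' Remove the stored principal directions from a sample
#'
#' The sample's bin proportions are centered on the training means, the
#' projection onto the stored components is removed, and the result is
#' rescaled to the sample's original total. The operation is idempotent.
#'
#' @param x a [BinCountMatrix-class] with the same retained bin set as the
#'   denoiser's training matrix.
#' @param denoiser a [PcaDenoiser-class].
#' @return a denoised [BinCountMatrix-class] tagged `corrected=...,pca`.
#' @export
applyPcaDenoise <- function(x, denoiser) {
  if (!identical(.binKey(x), denoiser@binKey))
    stopConfig("bin set does not match the denoiser's training bins")
  counts <- assay(x, "counts")
  ret <- binRetained(x)
  W <- denoiser@components             # k x bins
  m <- denoiser@binMeans
  for (j in seq_len(ncol(counts))) {
    tot <- sum(counts[ret, j])
    r <- counts[ret, j] / tot
    centered <- r - m
    if (denoiser@nComponents > 0L) {
      proj <- drop(W %*% centered)
      centered <- centered - drop(crossprod(W, proj))
    }
    counts[ret, j] <- (centered + m) * tot
  }
  BinCountMatrix(counts, bins = rowRanges(x), gc = binGC(x), retained = ret,
                 sampleIds = colnames(counts),
                 corrected = unique(c(metadata(x)$corrected, "pca")))
}

#' Aggregate retained bins to autosome counts
#'
#' Sums the counts of retained bins per autosome for every sample. Mass is
#' conserved exactly: the per-sample total equals the sum over retained bins.
#'
#' @param x a [BinCountMatrix-class].
#' @return A [ChromCountSet-class] (autosomes absent from the bin list get 0).
#' @export
aggregateToChromosomes <- function(x) {
  ret <- binRetained(x)
  counts <- assay(x, "counts")[ret, , drop = FALSE]
  chrom <- as.character(seqnames(rowRanges(x)))[ret]
  agg <- rowsum(counts, group = chrom)
  m <- matrix(0, ncol(counts), 22, dimnames = list(colnames(counts), .AUTOSOMES))
  m[, rownames(agg)] <- t(agg)
  ChromCountSet(m, sampleIds = colnames(counts))
}

# Vectorized multivariate-hypergeometric split: draw nTarget reads without
# replacement from each sample's reads (rows of `m`). Sequential conditional
# hypergeometric draws across the 22 chromosomes, vectorized across samples.
.hyperSplit <- function(m, nTarget) {
  nS <- nrow(m)
  out <- matrix(0, nS, ncol(m), dimnames = dimnames(m))
  remainingPop <- rowSums(m)
  remainingDraw <- rep(as.double(nTarget), length.out = nS)
  for (j in seq_len(ncol(m) - 1L)) {
    white <- m[, j]
    black <- remainingPop - white
    k <- rhyper(nS, white, black, remainingDraw)
    out[, j] <- k
    remainingDraw <- remainingDraw - k
    remainingPop <- black
  }
  out[, ncol(m)] <- remainingDraw
  out
}

#' Uniform read subsampling to a target depth
#'
#' Draws `nTarget` reads without replacement from a sample's reads
#' (multivariate hypergeometric over the 22 autosomes), emulating a uniform
#' random selection of mapped alignments. The output total equals `nTarget`
#' exactly and the draw is deterministic given `seed`. A with-replacement
#' (multinomial) variant is available via `method = "multinomial"`.
#'
#' @param x a [ChromCountSet-class] or a numeric 22-vector of integer counts.
#' @param nTarget target total read count (0 < nTarget <= each sample total).
#' @param seed integer seed.
#' @param method `"hypergeometric"` (default, without replacement) or
#'   `"multinomial"` (with replacement).
#' @param ... unused.
#' @return same class as `x`, with totals equal to `nTarget`.
#' @export
setMethod("subsampleCounts", "ChromCountSet",
  function(x, nTarget, seed, method = c("hypergeometric", "multinomial"), ...) {
    method <- match.arg(method)
    m <- chromCounts(x)
    if (!.isWholeNumber(m)) stopConfig("subsampling requires integer counts")
    if (nTarget <= 0) stopConfig("nTarget must be positive")
    tot <- rowSums(m)
    if (any(tot < nTarget)) {
      bad <- which(tot < nTarget)[1]
      stopConfig("nTarget (%g) exceeds total reads (%g) of sample %s",
                 nTarget, tot[bad], sampleIds(x)[bad])
    }
    if (all(tot == nTarget)) return(x)
    out <- withSeed(seed, {
      if (method == "hypergeometric") {
        full <- .hyperSplit(round(m), nTarget)
        full[tot == nTarget, ] <- m[tot == nTarget, ]
        full
      } else {
        t(vapply(seq_len(nrow(m)), function(i) {
          if (tot[i] == nTarget) return(m[i, ])
          as.numeric(rmultinom(1, nTarget, m[i, ] / tot[i]))
        }, numeric(22)))
      }
    })
    ChromCountSet(out, sampleIds = sampleIds(x))
  })

#' @rdname subsampleCounts-ChromCountSet-method
#' @export
setMethod("subsampleCounts", "numeric",
  function(x, nTarget, seed, method = c("hypergeometric", "multinomial"), ...) {
    set <- ChromCountSet(x)
    drop(chromCounts(subsampleCounts(set, nTarget, seed,
                                     method = match.arg(method))))
  })
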