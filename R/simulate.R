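# Synthetic NIPT cohort generator: multinomial read allocation, per-sample
# CNV jitter, optional GC bin bias, trisomy spiking by fetal fraction.

#' Simulation configuration
#'
#' Describes one cohort condition. Defaults emulate a production shallow-WGS
#' NIPT run: 3M autosomal reads per sample, baseline autosome proportions
#' proportional to hg19 autosome lengths, and multiplicative per-sample
#' proportion jitter with SD 0.002 standing in for random individual CNVs —
#' the mechanism producing the depth-independent excess ratio variance the
#' adaptive model corrects with its constant `c`.
#'
#' @param nSamples number of samples.
#' @param depth fixed read count per sample, or the median when
#'   `depthSigma > 0`.
#' @param depthSigma log-normal sdlog of the per-sample depth (0 = fixed
#'   depth).
#' @param pBaseline baseline autosome proportions (22-vector summing to 1;
#'   default proportional to hg19 autosome lengths).
#' @param cnvSd SD of the multiplicative per-chromosome proportion jitter
#'   (dimensionless; default 0.002).
#' @param gcBiasAmplitude slope of the linear bin-level GC bias (0 = none;
#'   only used in bin-level mode).
#' @param trisomyChrom `NA` (euploid) or 13/18/21.
#' @param fetalFraction fixed fetal fraction in \[0, 1\].
#' @param ffShape optional `c(a, b)` for a Beta(a, b) fetal-fraction model
#'   (overrides `fetalFraction`).
#' @param binsPerChrom 0 for chromosome-level output ([ChromCountSet-class]);
#'   > 0 to additionally split each chromosome's reads over that many bins
#'   ([BinCountMatrix-class]).
#' @param seed integer seed; the whole cohort derives deterministically from
#'   it.
#' @return a `SimCohortConfig` list (class-tagged).
#' @export
simCohortConfig <- function(nSamples, depth = 3e6, depthSigma = 0,
                            pBaseline = NULL, cnvSd = 0.002,
                            gcBiasAmplitude = 0, trisomyChrom = NA,
                            fetalFraction = 0, ffShape = NULL,
                            binsPerChrom = 0L, seed) {
  if (missing(seed)) stopConfig("an explicit seed is required")
  if (is.null(pBaseline))
    pBaseline <- .HG19_AUTOSOME_LENGTHS / sum(.HG19_AUTOSOME_LENGTHS)
  if (length(pBaseline) != 22 || abs(sum(pBaseline) - 1) > 1e-8)
    stopConfig("pBaseline must be a 22-vector summing to 1")
  if (cnvSd < 0) stopConfig("cnvSd must be >= 0")
  if (fetalFraction < 0 || fetalFraction > 1)
    stopConfig("fetalFraction must be in [0, 1]")
  if (!is.na(trisomyChrom) && !trisomyChrom %in% c(13, 18, 21))
    stopConfig("trisomyChrom must be NA, 13, 18 or 21")
  structure(list(nSamples = as.integer(nSamples), depth = depth,
                 depthSigma = depthSigma, pBaseline = as.numeric(pBaseline),
                 cnvSd = cnvSd, gcBiasAmplitude = gcBiasAmplitude,
                 trisomyChrom = trisomyChrom, fetalFraction = fetalFraction,
                 ffShape = ffShape, binsPerChrom = as.integer(binsPerChrom),
                 seed = as.integer(seed)),
            class = "SimCohortConfig")
}

#' Effective per-sample autosome proportions
#'
#' Applies multiplicative CNV jitter `p_i (1 + e_i)`, `e_i ~ N(0, cnvSd)`,
#' then trisomy dosage on the affected chromosome, `p_t (1 + ff/2)` (a
#' trisomic placenta contributes 3/2 of the diploid dose on the fetal
#' fraction of fragments), then renormalizes to sum 1. Jitter vectors that
#' push any proportion to zero or below are resampled (warning after 10
#' retries). Uses the current RNG state.
#'
#' @param pBaseline 22-vector of baseline proportions.
#' @param cnvSd jitter SD.
#' @param trisomyChrom `NA` or the affected autosome.
#' @param ff fetal fraction.
#' @return effective proportion 22-vector summing to 1.
#' @export
effectiveProportions <- function(pBaseline, cnvSd, trisomyChrom = NA,
                                 ff = 0) {
  p <- pBaseline
  if (cnvSd > 0) {
    tries <- 0
    repeat {
      eps <- rnorm(22, 0, cnvSd)
      pj <- p * (1 + eps)
      tries <- tries + 1
      if (all(pj > 0)) break
      if (tries > 10) warning("more than 10 jitter resampling attempts")
    }
    p <- pj
  }
  if (!is.na(trisomyChrom) && ff > 0)
    p[trisomyChrom] <- p[trisomyChrom] * (1 + ff / 2)
  p / sum(p)
}

.drawDepth <- function(config) {
  if (config$depthSigma > 0)
    round(rlnorm(1, meanlog = log(config$depth), sdlog = config$depthSigma))
  else round(config$depth)
}

.drawFf <- function(config) {
  if (!is.null(config$ffShape))
    rbeta(1, config$ffShape[1], config$ffShape[2])
  else config$fetalFraction
}

#' Simulate a single sample
#'
#' Draws the depth, the effective proportions, and the multinomial read
#' allocation over the 22 autosomes; in bin-level mode each chromosome's
#' count is further split multinomially over its bins with weights
#' `1 + gcBiasAmplitude * (gc_b - mean(gc))`.
#'
#' @param config a [simCohortConfig()] object.
#' @param sampleId sample name.
#' @param seed integer seed for this sample.
#' @param binGc optional per-bin GC values (list by chromosome) for bin-level
#'   mode; normally supplied by [simulateCohort()].
#' @return list: `counts` (22-vector), `binCounts` (or NULL), `ff`, `n`,
#'   `label`.
#' @export
simulateSample <- function(config, sampleId = "sample1", seed,
                           binGc = NULL) {
  withSeed(seed, {
    n <- .drawDepth(config)
    ff <- .drawFf(config)
    pEff <- effectiveProportions(config$pBaseline, config$cnvSd,
                                 config$trisomyChrom, ff)
    x <- as.numeric(rmultinom(1, n, pEff))
    names(x) <- .AUTOSOMES
    binCounts <- NULL
    if (config$binsPerChrom > 0) {
      if (is.null(binGc)) binGc <- .drawBinGc(config)
      gcAll <- unlist(binGc)
      gcCenter <- mean(gcAll)
      binCounts <- unlist(lapply(1:22, function(ch) {
        w <- 1 + config$gcBiasAmplitude * (binGc[[ch]] - gcCenter)
        as.numeric(rmultinom(1, x[ch], w / sum(w)))
      }))
    }
    list(counts = x, binCounts = binCounts, ff = ff, n = n,
         label = if (!is.na(config$trisomyChrom)) "trisomic" else "euploid",
         sample_id = sampleId)
  })
}

.drawBinGc <- function(config) {
  lapply(1:22, function(ch) runif(config$binsPerChrom, 0.3, 0.6))
}

.simBinRanges <- function(config, binGc) {
  binSize <- 20000L
  starts <- rep((seq_len(config$binsPerChrom) - 1L) * binSize, 22)
  chrom <- rep(.AUTOSOMES, each = config$binsPerChrom)
  gr <- GRanges(chrom, IRanges(start = starts + 1, end = starts + binSize))
  mcols(gr)$gc <- unlist(binGc)
  gr
}

#' Simulate a cohort
#'
#' Generates `nSamples` samples under one condition, deterministically from
#' the configuration seed (per-sample seeds are derived internally, so any
#' sample can be regenerated in isolation).
#'
#' @param config a [simCohortConfig()] object.
#' @return list with `counts` (a [ChromCountSet-class], or a
#'   [BinCountMatrix-class] in bin-level mode with the chromosome-level set
#'   in `chromCounts`) and `truth` (data.frame: `sample_id`, `label`,
#'   `ff_true`, `n_true`, `seed`).
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "SimCohortConfig"))
  nS <- config$nSamples
  ids <- sprintf("sim%04d", seq_len(nS))
  binGc <- if (config$binsPerChrom > 0)
    withSeed(.deriveSeed(config$seed, 0L), .drawBinGc(config)) else NULL
  seeds <- vapply(seq_len(nS), function(i) .deriveSeed(config$seed, i),
                  integer(1))
  sims <- lapply(seq_len(nS), function(i)
    simulateSample(config, ids[i], seeds[i], binGc = binGc))
  truth <- data.frame(
    sample_id = ids,
    label = vapply(sims, `[[`, character(1), "label"),
    ff_true = vapply(sims, `[[`, numeric(1), "ff"),
    n_true = vapply(sims, `[[`, numeric(1), "n"),
    seed = seeds, stringsAsFactors = FALSE)
  chrom <- ChromCountSet(
    t(vapply(sims, `[[`, numeric(22), "counts")), sampleIds = ids)
  out <- list(counts = chrom, truth = truth)
  if (config$binsPerChrom > 0) {
    bins <- .simBinRanges(config, binGc)
    bm <- t(vapply(sims, `[[`, numeric(length(bins)), "binCounts"))
    out$bins <- BinCountMatrix(t(bm), bins = bins, sampleIds = ids)
    out$chromCounts <- chrom
  }
  out
}
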