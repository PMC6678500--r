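#' Target/reference chromosome selector
#'
#' Binary selector vectors over the 22 autosomes: `u` marks the single target
#' (potentially aneuploid) chromosome, `v` the reference set. Constraints:
#' exactly one target; at least one reference chromosome; target and
#' reference disjoint; chromosomes 13, 18 and 21 (the common trisomic
#' autosomes) never enter the reference set.
#'
#' @name ReferenceSelector-class
#' @aliases ReferenceSelector
#' @exportClass ReferenceSelector
setClass("ReferenceSelector",
         representation(u = "numeric", v = "numeric"))

setValidity("ReferenceSelector", function(object) {
  u <- object@u; v <- object@v
  msg <- character()
  if (length(u) != 22L || length(v) != 22L)
    msg <- c(msg, "u and v must have length 22")
  else {
    if (!all(u %in% c(0, 1)) || !all(v %in% c(0, 1)))
      msg <- c(msg, "u and v must be binary")
    if (sum(u) != 1) msg <- c(msg, "exactly one target chromosome required")
    if (sum(v) < 1) msg <- c(msg, "reference set must be non-empty")
    if (any(u * v != 0)) msg <- c(msg, "target must not be in the reference set")
    if (any(v[c(13, 18, 21)] != 0))
      msg <- c(msg, "chromosomes 13, 18, 21 are excluded from reference sets")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ReferenceSelector
#'
#' @param target target autosome number (1..22).
#' @param reference integer vector of reference autosome numbers.
#' @return A [ReferenceSelector-class].
#' @export
ReferenceSelector <- function(target, reference) {
  u <- numeric(22); v <- numeric(22)
  u[target] <- 1
  v[reference] <- 1
  new("ReferenceSelector", u = u, v = v)
}

#' @describeIn ReferenceSelector-class target autosome number.
#' @param x a `ReferenceSelector`.
#' @export
setMethod("targetChrom", "ReferenceSelector", function(x) which(x@u == 1))

#' @describeIn ReferenceSelector-class sorted reference autosome numbers.
#' @export
setMethod("referenceChroms", "ReferenceSelector", function(x) which(x@v == 1))

setMethod("show", "ReferenceSelector", function(object) {
  cat(sprintf("ReferenceSelector: target chr%d, reference {%s}\n",
              targetChrom(object),
              paste(referenceChroms(object), collapse = ", ")))
})

#' Per-sample GC LOESS fit
#'
#' Stores the fitted LOESS curve (as a grid of GC values and fitted expected
#' counts, evaluated by interpolation) together with the sample's global mean
#' bin count `rcAvg`. Used by [applyGcCorrection()].
#'
#' @name GcCorrectionFit-class
#' @aliases GcCorrectionFit
#' @exportClass GcCorrectionFit
setClass("GcCorrectionFit",
         representation(span = "numeric", gcGrid = "numeric",
                        fittedGrid = "numeric", rcAvg = "numeric"))

setMethod("show", "GcCorrectionFit", function(object) {
  cat(sprintf(
    "GcCorrectionFit: span %.2f, GC range [%.3f, %.3f], rcAvg %.2f\n",
    object@span, min(object@gcGrid), max(object@gcGrid), object@rcAvg))
})

#' Principal-component denoiser
#'
#' Top principal directions of the per-sample bin-proportion matrix of
#' euploid training controls. Applying the denoiser removes a test sample's
#' projection onto these directions, suppressing recurrent structural noise
#' shared across individuals.
#'
#' @name PcaDenoiser-class
#' @aliases PcaDenoiser
#' @exportClass PcaDenoiser
setClass("PcaDenoiser",
         representation(nComponents = "integer", binMeans = "numeric",
                        components = "matrix", binKey = "character"))

setValidity("PcaDenoiser", function(object) {
  k <- object@nComponents
  if (k < 0L) return("nComponents must be >= 0")
  if (k > 0L) {
    if (nrow(object@components) != k)
      return("components must have nComponents rows")
    g <- object@components %*% t(object@components)
    if (max(abs(g - diag(k))) > 1e-6)
      return("components must be orthonormal")
  }
  TRUE
})

setMethod("show", "PcaDenoiser", function(object) {
  cat(sprintf("PcaDenoiser: %d component(s) over %d bins\n",
              object@nComponents, length(object@binMeans)))
})

#' Fixed-variance (NCV) z-score model
#'
#' Classical normalized chromosomal value model: the chromosome ratio's mean
#' and standard deviation are estimated once from euploid training samples
#' and applied unchanged to every test sample, regardless of its depth.
#'
#' @name FixvarModel-class
#' @aliases FixvarModel
#' @exportClass FixvarModel
setClass("FixvarModel",
         representation(selector = "ReferenceSelector", muFix = "numeric",
                        sigmaFix = "numeric", trainDepths = "numeric",
                        nTrain = "integer"))

setValidity("FixvarModel", function(object) {
  if (!(object@sigmaFix > 0)) return("sigmaFix must be > 0")
  if (!(object@muFix > 0)) return("muFix must be > 0")
  TRUE
})

setMethod("show", "FixvarModel", function(object) {
  cat(sprintf(
    "FixvarModel (target chr%d): mu = %.6g, sigma = %.3g, %d training samples\n",
    targetChrom(object@selector), object@muFix, object@sigmaFix,
    object@nTrain))
  cat(sprintf("  training depths: min %.3g / median %.3g / max %.3g\n",
              object@trainDepths[["min"]], object@trainDepths[["median"]],
              object@trainDepths[["max"]]))
})

#' Adaptive-variance z-score model
#'
#' Holds the trained autosome proportion vector `p`, the scalar products
#' `q1 = p.u` and `q2 = p.v`, the depth-independent bias constant `c`
#' (in units of the chromosome ratio), the combination mode for the corrected
#' standard deviation, and the depth grid used to estimate `c`. Mean and SD
#' for a test sample are recomputed from its own total read count, so the
#' model transfers across sequencing depths.
#'
#' @name AdavarModel-class
#' @aliases AdavarModel
#' @exportClass AdavarModel
setClass("AdavarModel",
         representation(selector = "ReferenceSelector", p = "numeric",
                        q1 = "numeric", q2 = "numeric", c = "numeric",
                        combineMode = "character", depthGrid = "numeric",
                        nTrain = "integer"))

setValidity("AdavarModel", function(object) {
  msg <- character()
  if (length(object@p) != 22L) msg <- c(msg, "p must have length 22")
  if (abs(sum(object@p) - 1) > 1e-8) msg <- c(msg, "p must sum to 1")
  if (!(object@q1 > 0 && object@q1 < 1)) msg <- c(msg, "q1 must be in (0,1)")
  if (!(object@q2 > 0 && object@q2 < 1)) msg <- c(msg, "q2 must be in (0,1)")
  if (object@q1 + object@q2 > 1 + 1e-12) msg <- c(msg, "q1 + q2 must be <= 1")
  if (object@c < 0) msg <- c(msg, "bias constant c must be >= 0")
  if (!object@combineMode %in% c("quadrature", "linear"))
    msg <- c(msg, "combineMode must be 'quadrature' or 'linear'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AdavarModel", function(object) {
  cat(sprintf(
    "AdavarModel (target chr%d): q1 = %.6g, q2 = %.6g, c = %.3g (%s)\n",
    targetChrom(object@selector), object@q1, object@q2, object@c,
    object@combineMode))
  cat(sprintf("  reference {%s}; c depth grid: %s\n",
              paste(referenceChroms(object@selector), collapse = ", "),
              paste(format(object@depthGrid, big.mark = ","), collapse = ", ")))
})

#' Observed-vs-theoretical SD profile across depths
#'
#' For a grid of read depths, records the empirical SD of the chromosome
#' ratio across training samples subsampled to that depth, the theoretical
#' multinomial SD at that depth, and their difference. The average difference
#' is the bias constant `c`.
#'
#' @name DeviationProfile-class
#' @aliases DeviationProfile
#' @exportClass DeviationProfile
setClass("DeviationProfile",
         representation(depths = "numeric", observedSd = "numeric",
                        theoreticalSd = "numeric", nSamples = "integer",
                        nReplicates = "integer"))

setValidity("DeviationProfile", function(object) {
  msg <- character()
  if (length(object@depths) != length(object@observedSd) ||
      length(object@depths) != length(object@theoreticalSd))
    msg <- c(msg, "depths/observedSd/theoreticalSd must have equal length")
  if (length(object@depths) > 1 && any(diff(object@depths) <= 0))
    msg <- c(msg, "depths must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' @describeIn DeviationProfile-class observed minus theoretical SD per depth.
#' @param profile a `DeviationProfile`.
#' @export
deviationDifferences <- function(profile) {
  profile@observedSd - profile@theoreticalSd
}

#' @describeIn DeviationProfile-class tabular view of the profile.
#' @param x a `DeviationProfile`.
#' @param ... unused.
#' @export
setMethod("as.data.frame", "DeviationProfile", function(x, ...) {
  data.frame(depth = x@depths, observed_sd = x@observedSd,
             theoretical_sd = x@theoreticalSd,
             difference = x@observedSd - x@theoreticalSd)
})

setMethod("show", "DeviationProfile", function(object) {
  cat(sprintf(
    "DeviationProfile: %d depths (%d samples x %d replicates per stratum)\n",
    length(object@depths), object@nSamples, object@nReplicates))
  print(as.data.frame(object))
})
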