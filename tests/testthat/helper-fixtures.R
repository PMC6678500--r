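# Fixtures built in code: simulated cohorts, selectors, and a tiny SAM file.

hg19P <- function() {
  lens <- c(249250621, 243199373, 198022430, 191154276, 180915260, 171115067,
            159138663, 146364022, 141213431, 135534747, 135006516, 133851895,
            115169878, 107349540, 102531392, 90354753, 81195210, 78077248,
            59128983, 63025520, 48129895, 51304566)
  lens / sum(lens)
}

euploidCohort <- function(n, depth, cnvSd = 0.002, seed = 1, ...) {
  simulateCohort(simCohortConfig(nSamples = n, depth = depth, cnvSd = cnvSd,
                                 seed = seed, ...))$counts
}

allEligibleSelector <- function(target = 21) {
  ReferenceSelector(target, setdiff(1:22, c(target, 13, 18, 21)))
}

# ChromCountSet whose chromosome ratio (target 21 over reference {1}) takes
# prescribed values: chr1 count fixed at `ref`, chr21 count = y * ref.
ratioCohort <- function(y, ref = 1e6) {
  m <- matrix(1, nrow = length(y), ncol = 22)
  m[, 1] <- ref
  m[, 21] <- y * ref
  ChromCountSet(m)
}

# Minimal coordinate-sorted SAM with 22 autosomes (+ chrX) of 100,050 bp and
# a configurable read set; converted to BAM on the fly.
writeTestBam <- function(reads, dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("bamfixture")
    dir.create(dir)
  }
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:chr%d\tLN:100050", 1:22),
           "@SQ\tSN:chrX\tLN:100050")
  samPath <- file.path(dir, "test.sam")
  writeLines(c(hdr, reads), samPath)
  Rsamtools::asBam(samPath, file.path(dir, "test"), overwrite = TRUE)
}

samRead <- function(id, chrom, pos1, mapq, flag = 0L) {
  sprintf("%s\t%d\t%s\t%d\t%d\t35M\t*\t0\t0\t*\t*", id, flag, chrom, pos1,
          mapq)
}
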