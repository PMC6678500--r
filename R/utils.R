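# Internal helpers shared across modules.

.AUTOSOMES <- paste0("chr", 1:22)

# hg19 autosome lengths (bp), used as the default baseline proportion source
# for the simulator.
.HG19_AUTOSOME_LENGTHS <- c(
  chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
  chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
  chr9 = 141213431, chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
  chr13 = 115169878, chr14 = 107349540, chr15 = 102531392, chr16 = 90354753,
  chr17 = 81195210, chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
  chr21 = 48129895, chr22 = 51304566
)

# Configuration/validation failures get their own condition class so the CLI
# can map them to exit code 2.
stopConfig <- function(fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c("adavar_config_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Normalize chromosome labels: "1".."22" and "chr1".."chr22" map to "chrN";
# sex chromosomes and mitochondria map to NA (skipped); anything else errors.
.normalizeChrom <- function(x, allowSkip = TRUE) {
  raw <- as.character(x)
  stripped <- sub("^chr", "", raw)
  out <- rep(NA_character_, length(raw))
  auto <- stripped %in% as.character(1:22)
  out[auto] <- paste0("chr", stripped[auto])
  skip <- stripped %in% c("X", "Y", "M", "MT")
  bad <- !auto & !skip
  if (any(bad)) {
    stopConfig("reference names not mappable to 1..22/chr1..chr22: %s",
               paste(unique(raw[bad]), collapse = ", "))
  }
  if (!allowSkip && any(skip)) {
    stopConfig("non-autosomal chromosome not allowed here: %s",
               paste(unique(raw[skip]), collapse = ", "))
  }
  out
}

# Deterministic sub-seed derivation; keeps everything inside 32-bit range.
.deriveSeed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(abs(seed) %% 2147483647)
  for (i in seq_along(idx)) {
    h <- (h * 48271 + as.double(idx[i]) * 9973 + i * 7919) %% 2147483647
  }
  as.integer(h) + 1L
}

# Evaluate `expr` under a fixed seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Column standard deviations with the N-1 denominator, no extra deps.
.colSds <- function(m) {
  n <- nrow(m)
  if (n < 2L) return(rep(NA_real_, ncol(m)))
  mu <- colMeans(m)
  sqrt(pmax(colSums(m * m) - n * mu^2, 0) / (n - 1))
}

.isWholeNumber <- function(x, tol = 1e-8) {
  all(is.finite(x)) && all(abs(x - round(x)) < tol)
}

.toolHeader <- function(...) {
  extra <- c(...)
  c(sprintf("# adavar %s", as.character(packageVersion("adavar"))),
    if (length(extra)) paste0("# ", extra))
}
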