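# Internal helpers shared across modules.

#' @useDynLib octsum, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards.  Every source of randomness in the package flows through
# an explicit seed via this helper; no function perturbs global RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a 32-bit sub-seed from a base seed and a stream index.
deriveSeed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483629)
}

# pmax/pmin take attributes from their first argument; keep x first so
# matrix dims survive
clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Bilinear resize of a rows x cols matrix (EBImage's first dimension maps to
# our rows, so no transposition is needed).
resizeBilinear <- function(img, nr, nc) {
  out <- EBImage::resize(EBImage::Image(img), w = nr, h = nc,
                         filter = "bilinear")
  matrix(EBImage::imageData(out), nr, nc)
}
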