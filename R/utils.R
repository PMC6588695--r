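## Internal helpers shared across modules.

#' @importFrom methods is new validObject show setValidity
#' @importFrom stats coef cor cutree dist fisher.test hclust kmeans ks.test
#'   lm lm.fit p.adjust pf phyper predict qnorm quantile rnorm runif sd
#'   smooth.spline var setNames
#' @importFrom utils read.csv write.csv
NULL

## Typed conditions so callers/tests can distinguish failure modes.
mcStop <- function(class, msg) {
  stop(errorCondition(msg, class = c(class, "metacortexError", "error")))
}

mcAssert <- function(ok, class, msg) {
  if (!isTRUE(ok)) mcStop(class, msg)
}

## log2 of a linear-scale intensity matrix; zeros are not representable on the
## log scale, so strictly positive values are required.
log2Matrix <- function(m) {
  mcAssert(all(is.finite(m)) && all(m > 0), "validationError",
           "log2 transform requires strictly positive, finite intensities")
  log2(m)
}

## Row-standardize (per peak): mean 0, SD 1. Zero-variance rows come back as
## all-zero with their index recorded in the 'degenerate' attribute.
rowStandardize <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1L, sd)
  bad <- which(!is.finite(s) | s == 0)
  s[bad] <- 1
  z <- (m - mu) / s
  z[bad, ] <- 0
  attr(z, "center") <- mu
  attr(z, "scale") <- s
  attr(z, "degenerate") <- bad
  z
}
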