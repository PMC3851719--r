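## Shared fixtures: small landscapes and fast protocols so unit tests run
## in seconds; the full-scale study conditions live in test-acceptance.R.

kT300 <- 0.0083144621 * 300

## the packaged two-well template geometry
templateLandscape <- function(boundDepth = 10, unboundDepth = 12) {
  ToyLandscape(rbind(
    rectangularWell(0.02, boundDepth, 0.05, 0.015),
    rectangularWell(0.33, unboundDepth, 0.06, 0.015)))
}

## flat landscape whose domain is fully covered by the pulled range
flatLandscape <- function(bounds = c(-0.03, 0.38))
  ToyLandscape(bounds = bounds)

## reference protocol sped up for cheap tests
fastProtocol <- function(speedup = 8, ...)
  PullingProtocol(velocity = 1.75e-4 * speedup, ...)

## hand-built single-slice ensemble (stationary restraint, one frame per
## replica): the umbrella-sampling reduction of the reweighting scheme
singleSliceEnsemble <- function(q, lambda = 0, work = rep(0, length(q)),
                                nhb = NULL, k = 3.9e4, temperature = 300) {
  if (is.null(nhb)) nhb <- rep(1L, length(q))
  proto <- PullingProtocol(springConstant = k, lambda0 = lambda,
                           lambda1 = lambda, velocity = 0, nSteps = 0L,
                           recordEvery = 1L, temperature = temperature)
  WorkEnsemble(position = matrix(q, 1L), work = matrix(work, 1L),
               nhb = matrix(nhb, 1L), time = 0, lambda = lambda,
               protocol = proto)
}

## rebuild an ensemble with a modified work matrix (keeps W_0 = 0)
withWorks <- function(ens, W) {
  WorkEnsemble(position = positions(ens), work = W, nhb = hbonds(ens),
               time = timeGrid(ens), lambda = lambdaSchedule(ens),
               protocol = protocolOf(ens), landscape = landscapeOf(ens))
}
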