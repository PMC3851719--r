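## Jarzynski + WHAM (Hummer-Szabo) frame reweighting.
##
## Raw weight of frame (t, i):
##   r_{t,i} = exp(-beta (W_{t,i} - f_t)) /
##             sum_{t'} N exp(-beta (V(q_{t,i}, lambda_{t'}) - f_{t'}))
## with f_t the per-slice Jarzynski free energies and V the harmonic bias.
## The numerator factor exp(+beta f_t) normalizes each slice's
## work-weighted density (the per-slice identity is
## <delta(x - x_t) e^{-beta W_t}> = e^{-beta (U + V_t(x))} / Z_0, so each
## slice must be divided by <e^{-beta W_t}> = e^{-beta f_t} before
## WHAM pooling); without it the pooled density is not proportional to
## e^{-beta U}.  Normalized over all frames of the ensemble.  Everything
## is done in log space; the denominator kernel lives in C++
## (cpp_log_denominator).

.computeLogWeights <- function(W, q, lambda, springConstant, kT, stride) {
  .checkFiniteWork(W)
  beta <- 1 / kT
  f <- -kT * (apply(-W * beta, 1L, logSumExp) - log(ncol(W)))
  logr <- -beta * (W - f) -
    cpp_log_denominator(q, lambda, f, beta, springConstant, as.integer(stride))
  logZ <- logSumExp(as.vector(logr))
  if (!is.finite(logZ))
    stop("degenerate weights: total weight vanished (all frames infinitely biased)")
  list(logw = logr - logZ, sliceFE = f)
}

#' Unbiased per-frame weights for a pulling ensemble
#'
#' Combines the per-slice Jarzynski free energies with weighted-histogram
#' pooling over all restraint positions, assigning each recorded frame an
#' unbiased equilibrium weight.  Sums of these weights over any frame
#' partition (e.g. a hydrogen-bond-count state, or CV bins) give
#' equilibrium populations, so free energies can be projected onto any
#' a-posteriori chosen collective variable.
#'
#' The per-slice free energies are taken from the Jarzynski estimate
#' directly (no self-consistent iteration); each slice contributes the
#' same number of frames by construction.  `stride` decimates the slices
#' entering the weight denominator (a speed knob; the default 1 uses all).
#'
#' @param ensemble a [WorkEnsemble-class].
#' @param temperature temperature (K); defaults to the protocol's.
#' @param stride denominator slice decimation (integer >= 1).
#' @return a [FrameWeights-class].
#' @export
frameWeights <- function(ensemble, temperature = NULL, stride = 1L) {
  stopifnot(is(ensemble, "WorkEnsemble"))
  if (is.null(temperature)) temperature <- protocolOf(ensemble)@temperature
  k <- protocolOf(ensemble)@springConstant
  res <- .computeLogWeights(works(ensemble), positions(ensemble),
                            lambdaSchedule(ensemble), k,
                            .kT(temperature), stride)
  new("FrameWeights", weights = exp(res$logw), sliceFE = res$sliceFE,
      temperature = temperature, springConstant = k,
      stride = as.integer(stride))
}

#' @rdname FrameWeights-class
#' @export
setMethod("weightMatrix", "FrameWeights", function(x) x@weights)

#' @rdname FrameWeights-class
#' @export
setMethod("sliceFreeEnergies", "FrameWeights", function(x) x@sliceFE)

#' @describeIn FrameWeights-class display summary
#' @param object a `FrameWeights`.
#' @export
setMethod("show", "FrameWeights", function(object) {
  d <- suppressWarnings(weightConcentration(object))
  cat(sprintf(paste0(
    "FrameWeights: %d slices x %d replicas, T = %g K\n",
    "  trajectory ESS %.1f, max trajectory weight fraction %.3f\n"),
    nrow(object@weights), ncol(object@weights), object@temperature,
    d$ess, d$maxTrajFraction))
})

#' Weight-concentration diagnostics
#'
#' The exponential Jarzynski average can be dominated by a few low-work
#' realizations.  This diagnostic aggregates the normalized frame weights
#' per trajectory and reports the Kish effective sample size
#' \eqn{(\sum_i w_i)^2 / \sum_i w_i^2} and the largest single-trajectory
#' share of the total weight; a share above 0.5 raises a warning
#' (outlier-dominated estimate).
#'
#' @param weights a [FrameWeights-class], or a matrix/vector of normalized
#'   weights with one column (element) per trajectory.
#' @return list with `ess` and `maxTrajFraction`.
#' @export
weightConcentration <- function(weights) {
  w <- if (is(weights, "FrameWeights")) weights@weights else weights
  traj <- if (is.matrix(w)) colSums(w) else as.numeric(w)
  tot <- sum(traj)
  ess <- tot^2 / sum(traj^2)
  frac <- max(traj) / tot
  if (frac > 0.5)
    warning(sprintf(
      "a single trajectory carries %.0f%% of the total weight (ESS %.1f): the estimate is outlier-dominated",
      100 * frac, ess))
  list(ess = ess, maxTrajFraction = frac)
}

#' Project the free energy onto an a-posteriori collective variable
#'
#' Bins the frames by `cvValues` and returns
#' \eqn{F(bin) = -k_B T \ln \sum_{frames \in bin} w}, minimum-anchored.
#' Bins that receive no weight are reported as `NA` (undefined, never
#' interpolated).
#'
#' @param weights a [FrameWeights-class].
#' @param cvValues CV value per frame: a matrix shaped like the weight
#'   matrix, or a vector of the same total length.
#' @param binning `"discrete"` (one bin per distinct value, for integer
#'   CVs like a hydrogen-bond count) or a numeric vector of increasing bin
#'   edges for a continuous CV.
#' @return a [FreeEnergyProfile-class] over the CV (`aux$weightPerBin`,
#'   `aux$singleSupport`).
#' @export
projectFreeEnergy <- function(weights, cvValues, binning = "discrete") {
  stopifnot(is(weights, "FrameWeights"))
  w <- as.vector(weights@weights)
  cv <- as.vector(cvValues)
  if (length(cv) != length(w))
    stop("need one CV value per weighted frame (", length(w), ")")
  if (identical(binning, "discrete")) {
    lev <- sort(unique(cv))
    sums <- vapply(lev, function(v) sum(w[cv == v]), 0.0)
    centers <- lev
  } else {
    edges <- as.numeric(binning)
    if (length(edges) < 2L || is.unsorted(edges, strictly = TRUE))
      stop("binning must be 'discrete' or increasing numeric bin edges")
    idx <- findInterval(cv, edges, rightmost.closed = TRUE)
    keep <- idx >= 1L & idx <= length(edges) - 1L
    sums <- vapply(seq_len(length(edges) - 1L),
                   function(b) sum(w[keep & idx == b]), 0.0)
    centers <- (edges[-1] + edges[-length(edges)]) / 2
  }
  kT <- .kT(weights@temperature)
  fe <- ifelse(sums > 0, -kT * log(sums), NA_real_)
  fe <- fe - min(fe, na.rm = TRUE)
  single <- sum(sums > 0) == 1L
  if (single)
    warning("all weight falls in a single bin: profile has single support")
  new("FreeEnergyProfile", grid = as.numeric(centers), values = fe,
      gridLabel = "cv", anchor = "minimum",
      temperature = weights@temperature,
      aux = list(weightPerBin = sums, singleSupport = single))
}

.stateSums <- function(w, counts) {
  counts <- as.vector(counts)
  if (length(counts) != length(w))
    stop("need one hydrogen-bond count per weighted frame")
  if (anyNA(counts))
    stop("hydrogen-bond counts contain NA: cannot partition frames")
  c(bound = sum(w[counts >= 1L]), unbound = sum(w[counts == 0L]))
}

#' Bound/unbound free-energy difference from frame weights
#'
#' Partitions the frames by the discrete hydrogen-bond count (`n >= 1`
#' bound, `n = 0` unbound) and returns
#' \eqn{\Delta F_{breaking} = -k_B T \ln(\sum_{unbound} w / \sum_{bound}
#' w)}; the formation direction is its exact negative.  Weight-concentration
#' diagnostics are attached.
#'
#' @param weights a [FrameWeights-class].
#' @param counts hydrogen-bond count per frame (matrix shaped like the
#'   weight matrix, or vector of the same total length), e.g.
#'   `hbonds(ensemble)`.
#' @param direction `"breaking"` or `"formation"`.
#' @return a [DeltaFResult-class] (no standard error yet; see
#'   [bootstrapDeltaF()]).
#' @export
stateDeltaF <- function(weights, counts,
                        direction = c("breaking", "formation")) {
  stopifnot(is(weights, "FrameWeights"))
  direction <- match.arg(direction)
  s <- .stateSums(as.vector(weights@weights), counts)
  for (st in names(s))
    if (s[[st]] <= 0)
      stop("degenerate partition: the ", st, " state carries no weight")
  kT <- .kT(weights@temperature)
  val <- -kT * log(s[["unbound"]] / s[["bound"]])
  if (direction == "formation") val <- -val
  diag <- suppressWarnings(weightConcentration(weights))
  diag$boundWeight <- s[["bound"]]; diag$unboundWeight <- s[["unbound"]]
  new("DeltaFResult", value = val, direction = direction, se = NA_real_,
      nReplicas = ncol(weights@weights), temperature = weights@temperature,
      diagnostics = diag, resamples = numeric(), nFailed = NA_integer_,
      B = NA_integer_)
}

#' Two-system comparison: ligand-induced stabilization
#'
#' \eqn{\Delta\Delta F = \Delta F_{apo} - \Delta F_{holo}} for two results
#' sharing direction convention and temperature; the standard error is
#' combined in quadrature, \eqn{\sqrt{se_{apo}^2 + se_{holo}^2}}.  With
#' breaking-direction inputs a negative value means the ligand stabilizes
#' the paired state.
#'
#' @param apo,holo [DeltaFResult-class] objects for the ligand-free and
#'   ligand-bound systems.
#' @return a [DeltaFResult-class]; `diagnostics` keeps both inputs.
#' @export
deltaDeltaF <- function(apo, holo) {
  stopifnot(is(apo, "DeltaFResult"), is(holo, "DeltaFResult"))
  if (apo@direction != holo@direction)
    stop("direction convention mismatch: ", apo@direction, " vs ",
         holo@direction)
  if (abs(apo@temperature - holo@temperature) > 1e-9)
    stop("temperature mismatch between the two results")
  se <- sqrt(apo@se^2 + holo@se^2)
  new("DeltaFResult", value = apo@value - holo@value,
      direction = apo@direction, se = se,
      nReplicas = min(apo@nReplicas, holo@nReplicas),
      temperature = apo@temperature,
      diagnostics = list(apo = apo, holo = holo),
      resamples = numeric(), nFailed = NA_integer_, B = NA_integer_)
}

#' @rdname DeltaFResult-class
#' @export
setMethod("dfValue", "DeltaFResult", function(x) x@value)

#' @rdname DeltaFResult-class
#' @export
setMethod("dfSe", "DeltaFResult", function(x) x@se)

#' @rdname DeltaFResult-class
#' @export
setMethod("dfDirection", "DeltaFResult", function(x) x@direction)

#' @rdname DeltaFResult-class
#' @export
setMethod("dfDiagnostics", "DeltaFResult", function(x) x@diagnostics)

#' @describeIn DeltaFResult-class display summary
#' @param object a `DeltaFResult`.
#' @export
setMethod("show", "DeltaFResult", function(object) {
  se <- if (is.na(object@se)) "" else sprintf(" +/- %.2f", object@se)
  cat(sprintf("DeltaF (%s): %.3f%s kJ/mol  [N = %d, T = %g K]\n",
              object@direction, object@value, se, object@nReplicas,
              object@temperature))
  d <- object@diagnostics
  if (!is.null(d$ess))
    cat(sprintf("  trajectory ESS %.1f, max trajectory fraction %.3f\n",
                d$ess, d$maxTrajFraction))
  if (!is.na(object@B))
    cat(sprintf("  bootstrap: B = %d, %d failed resample(s)\n",
                object@B, object@nFailed))
})
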