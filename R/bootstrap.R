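#' Bootstrap standard error for the state free-energy difference
#'
#' Nonparametric bootstrap at the whole-trajectory level (frames within a
#' trajectory are correlated, so trajectories are the exchangeable unit):
#' `B` resamples of the N trajectories are drawn with replacement, the full
#' pipeline (per-slice Jarzynski free energies, frame weights, state
#' partition) is re-run on each, and the standard error is the standard
#' deviation of the resample distribution.  The point estimate is the
#' full-sample value and is never altered by resampling.  Resamples in
#' which a state ends up with zero weight are dropped but counted; more
#' than 20% failures aborts with a diagnostics error.
#'
#' @param ensemble a [WorkEnsemble-class] with at least 2 replicas.
#' @param direction `"breaking"` or `"formation"`.
#' @param B number of resamples (>= 2, default 200).
#' @param seed integer RNG seed; same seed, same resample distribution.
#' @param stride denominator slice decimation (see [frameWeights()]).
#' @param temperature temperature (K); defaults to the protocol's.
#' @return a [DeltaFResult-class] with `se`, `resamples`, `nFailed`, `B`.
#' @export
bootstrapDeltaF <- function(ensemble, direction = c("breaking", "formation"),
                            B = 200L, seed = 1L, stride = 1L,
                            temperature = NULL) {
  stopifnot(is(ensemble, "WorkEnsemble"))
  direction <- match.arg(direction)
  if (ncol(ensemble) < 2L) stop("bootstrap needs at least 2 trajectories")
  if (B < 2L) stop("B must be >= 2")
  if (is.null(temperature)) temperature <- protocolOf(ensemble)@temperature
  kT <- .kT(temperature)
  k <- protocolOf(ensemble)@springConstant
  W <- works(ensemble); q <- positions(ensemble)
  counts <- hbonds(ensemble); lam <- lambdaSchedule(ensemble)
  if (anyNA(counts))
    stop("ensemble lacks hydrogen-bond counts: cannot partition frames")

  point <- stateDeltaF(frameWeights(ensemble, temperature = temperature,
                                    stride = stride), counts, direction)

  one <- function(idx) {
    res <- .computeLogWeights(W[, idx, drop = FALSE],
                              q[, idx, drop = FALSE], lam, k, kT, stride)
    s <- .stateSums(exp(as.vector(res$logw)), counts[, idx, drop = FALSE])
    if (any(s <= 0)) return(NA_real_)
    v <- -kT * log(s[["unbound"]] / s[["bound"]])
    if (direction == "formation") -v else v
  }

  set.seed(as.integer(seed))
  vals <- vapply(seq_len(B), function(b)
    one(sample.int(ncol(W), ncol(W), replace = TRUE)), 0.0)
  failed <- sum(is.na(vals))
  if (failed > 0.2 * B)
    stop("bootstrap diagnostics error: ", failed, " of ", B,
         " resamples had an empty state")
  ok <- vals[!is.na(vals)]
  out <- point
  out@se <- stats::sd(ok)
  out@resamples <- ok
  out@nFailed <- as.integer(failed)
  out@B <- as.integer(B)
  out
}

#' Convergence report for a free-energy estimate
#'
#' A result is flagged converged when its bootstrap standard error is at
#' or below the thermal energy k_B T, the trajectory effective sample size
#' is at least 10, and no single trajectory carries more than half the
#' total weight (the low-work-outlier pathology of exponential averages).
#'
#' @param result a [DeltaFResult-class] carrying `se` and diagnostics.
#' @param temperature temperature (K) defining k_B T; defaults to the
#'   result's.
#' @return list with `converged`, a per-criterion `criteria` data.frame
#'   and a printable `text`.
#' @export
convergenceReport <- function(result, temperature = NULL) {
  stopifnot(is(result, "DeltaFResult"))
  if (is.null(temperature)) temperature <- result@temperature
  kT <- .kT(temperature)
  d <- result@diagnostics
  ess <- if (!is.null(d$ess)) d$ess else NA_real_
  frac <- if (!is.null(d$maxTrajFraction)) d$maxTrajFraction else NA_real_
  crit <- data.frame(
    criterion = c("se <= kT", "ESS >= 10", "max trajectory fraction <= 0.5"),
    value = c(result@se, ess, frac),
    threshold = c(kT, 10, 0.5),
    pass = c(!is.na(result@se) && result@se <= kT,
             !is.na(ess) && ess >= 10,
             !is.na(frac) && frac <= 0.5))
  txt <- c(sprintf("convergence report (kT = %.3f kJ/mol at %g K):",
                   kT, temperature),
           sprintf("  %-32s %8.3f  (threshold %.3f)  %s", crit$criterion,
                   crit$value, crit$threshold,
                   ifelse(crit$pass, "PASS", "FAIL")))
  list(converged = all(crit$pass),
       outlierDominated = !is.na(frac) && frac > 0.5,
       criteria = crit, text = paste(txt, collapse = "\n"))
}
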