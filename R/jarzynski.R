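#' Accumulated restraint work from a position series
#'
#' Recomputes accumulated work for a trajectory that lacks a work column
#' (e.g. an externally produced COLVAR file), using the same
#' potential-difference convention as the simulator:
#' \eqn{\Delta W_t = V(x_t, \lambda_{t+1}) - V(x_t, \lambda_t)} with
#' \eqn{V(q, \lambda) = k/2 (q - \lambda)^2}, and \eqn{W_0 = 0}.
#'
#' @param positions steered-CV values (nm).
#' @param lambdaSchedule restraint centers (nm), same length.
#' @param springConstant restraint stiffness ((kJ/mol)/nm^2), > 0.
#' @return accumulated work series (kJ/mol), same length, starting at 0.
#' @examples
#' accumulateWork(c(0, 0), c(0, 0.1), 3.9e4)   # c(0, 195)
#' @export
accumulateWork <- function(positions, lambdaSchedule, springConstant) {
  if (length(positions) != length(lambdaSchedule))
    stop("positions and lambdaSchedule must have equal length")
  .assertScalar(springConstant, "springConstant", positive = TRUE)
  n <- length(positions)
  if (n == 0L) return(numeric())
  x <- positions[-n]
  dV <- 0.5 * springConstant *
    ((x - lambdaSchedule[-1])^2 - (x - lambdaSchedule[-n])^2)
  cumsum(c(0, dV))
}

.checkFiniteWork <- function(W) {
  bad <- which(!is.finite(W), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-finite work in replica ", bad[1, 2], " at slice ", bad[1, 1])
}

#' Jarzynski free-energy profile along the pulling schedule
#'
#' The exponential work average per time slice,
#' \eqn{F(t) = -k_B T \ln\left[\frac{1}{N}\sum_i e^{-\beta W_{i,t}}\right]},
#' evaluated with a log-sum-exp scheme so that \eqn{|\beta W|} up to 1e4
#' cannot overflow.  Endpoint anchored: F at the first slice is 0.  By
#' Jensen's inequality the profile lies at or below the mean-work profile
#' everywhere (the mean work is returned alongside, in `aux`).
#'
#' @param ensemble a [WorkEnsemble-class] (N >= 1 replicas, shared grid).
#' @param temperature temperature (K); defaults to the protocol's.
#' @return a [FreeEnergyProfile-class] over time, with `aux$lambda` and
#'   `aux$meanWork`.
#' @export
jarzynskiProfile <- function(ensemble, temperature = NULL) {
  stopifnot(is(ensemble, "WorkEnsemble"))
  if (ncol(ensemble) < 1L) stop("empty ensemble")
  if (is.null(temperature)) temperature <- protocolOf(ensemble)@temperature
  W <- works(ensemble)
  .checkFiniteWork(W)
  kT <- .kT(temperature)
  f <- -kT * (apply(-W / kT, 1L, logSumExp) - log(ncol(W)))
  new("FreeEnergyProfile", grid = timeGrid(ensemble), values = f,
      gridLabel = "time", anchor = "endpoint", temperature = temperature,
      aux = list(lambda = lambdaSchedule(ensemble),
                 meanWork = rowMeans(W)))
}

#' @rdname FreeEnergyProfile-class
#' @export
setMethod("feGrid", "FreeEnergyProfile", function(x) x@grid)

#' @rdname FreeEnergyProfile-class
#' @export
setMethod("feValues", "FreeEnergyProfile", function(x) x@values)

#' @describeIn FreeEnergyProfile-class as a base `data.frame`
#' @param row.names,optional,... ignored (S3 compatibility).
#' @export
setMethod("as.data.frame", "FreeEnergyProfile",
  function(x, row.names = NULL, optional = FALSE, ...) {
    d <- data.frame(grid = x@grid, free_energy = x@values)
    names(d)[1] <- x@gridLabel
    for (nm in intersect(c("lambda", "meanWork"), names(x@aux)))
      d[[nm]] <- x@aux[[nm]]
    d
  })

#' @describeIn FreeEnergyProfile-class display summary
#' @param object a `FreeEnergyProfile`.
#' @export
setMethod("show", "FreeEnergyProfile", function(object) {
  ok <- is.finite(object@values)
  cat(sprintf(paste0(
    "FreeEnergyProfile over %s: %d points (%d defined), %s-anchored\n",
    "  range %.3f .. %.3f kJ/mol at T = %g K\n"),
    object@gridLabel, length(object@grid), sum(ok), object@anchor,
    min(object@values[ok]), max(object@values[ok]), object@temperature))
})
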