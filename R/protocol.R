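#' Construct a pulling protocol
#'
#' Defaults reproduce the steered-pulling protocol this package emulates:
#' k = 3.9e4 (kJ/mol)/nm^2, restraint moved from 0 to 0.35 nm at
#' 0.175 nm/ns (= 1.75e-4 nm/ps), 300 K.  The integration time step is
#' 0.01 ps; the default diffusion coefficient 1e-3 nm^2/ps keeps the
#' overdamped Euler-Maruyama update of the stiffly restrained coordinate
#' stable and low-bias (beta k D dt ~ 0.16).
#'
#' @param springConstant restraint stiffness ((kJ/mol)/nm^2).
#' @param lambda0,lambda1 restraint start / end (nm).
#' @param velocity pulling speed (nm/ps); may be 0 (stationary restraint),
#'   in which case `nSteps` must be supplied.
#' @param timeStep integration step (ps).
#' @param temperature temperature (K).
#' @param diffusion diffusion coefficient (nm^2/ps).
#' @param nSteps number of steps; derived from the schedule when `NULL`.
#' @param recordEvery output stride in steps; default records ~200 frames.
#' @return a [PullingProtocol-class].
#' @export
PullingProtocol <- function(springConstant = 3.9e4, lambda0 = 0,
                            lambda1 = 0.35, velocity = 1.75e-4,
                            timeStep = 0.01, temperature = 300,
                            diffusion = 1e-3, nSteps = NULL,
                            recordEvery = NULL) {
  if (is.null(nSteps)) {
    if (velocity <= 0)
      stop("nSteps must be given explicitly when velocity is 0")
    nSteps <- as.integer(round((lambda1 - lambda0) / (velocity * timeStep)))
  }
  nSteps <- as.integer(nSteps)
  if (is.null(recordEvery))
    recordEvery <- max(1L, as.integer(round(nSteps / 200)))
  new("PullingProtocol", springConstant = springConstant, lambda0 = lambda0,
      lambda1 = lambda1, velocity = velocity, timeStep = timeStep,
      temperature = temperature, diffusion = diffusion, nSteps = nSteps,
      recordEvery = as.integer(recordEvery))
}

#' Default pulling protocol, optionally slowed down
#'
#' The protocol of [PullingProtocol()] with the pulling speed divided by
#' `slowdown` (same endpoints, so the run is `slowdown` times longer).
#' Slower pulling dissipates less work and tightens the Jarzynski/WHAM
#' estimates; the packaged two-system experiment uses `slowdown = 8`.
#'
#' @param slowdown factor by which to divide the reference pulling speed.
#' @param ... passed on to [PullingProtocol()].
#' @return a [PullingProtocol-class].
#' @export
defaultProtocol <- function(slowdown = 1, ...) {
  PullingProtocol(velocity = 1.75e-4 / slowdown, ...)
}

#' @describeIn PullingProtocol-class number of integration steps
#' @export
setMethod("nSteps", "PullingProtocol", function(x) x@nSteps)

.recordedSteps <- function(protocol) {
  s <- seq.int(0L, protocol@nSteps, by = protocol@recordEvery)
  if (s[length(s)] != protocol@nSteps) s <- c(s, protocol@nSteps)
  s
}

#' @rdname timeGrid
#' @export
setMethod("timeGrid", "PullingProtocol", function(x)
  .recordedSteps(x) * x@timeStep)

#' @rdname timeGrid
#' @export
setMethod("lambdaSchedule", "PullingProtocol", function(x)
  x@lambda0 + x@velocity * .recordedSteps(x) * x@timeStep)

#' Number of equilibrium starting points along a restrained run
#'
#' Starting configurations for the pulling replicas are extracted
#' equidistantly from a restrained equilibrium run; this helper derives the
#' replica count.  With the reference protocol (one start every 16 ps from
#' an 8.192 ns = 8192 ps run) it gives exactly 512.
#'
#' @param runLength length of the equilibrium run (ps).
#' @param spacing spacing between extracted starting points (ps).
#' @return integer replica count.
#' @examples
#' startingPointCount()        # 512
#' @export
startingPointCount <- function(runLength = 8192, spacing = 16) {
  .assertScalar(runLength, "runLength", positive = TRUE)
  .assertScalar(spacing, "spacing", positive = TRUE)
  n <- runLength / spacing
  if (abs(n - round(n)) > 1e-9)
    stop("runLength must be an integer multiple of spacing")
  as.integer(round(n))
}

#' @describeIn PullingProtocol-class display summary
#' @param object a `PullingProtocol`.
#' @export
setMethod("show", "PullingProtocol", function(object) {
  cat(sprintf(paste0(
    "PullingProtocol: k = %g (kJ/mol)/nm^2, lambda %g -> %g nm\n",
    "  v = %g nm/ps, dt = %g ps, %d steps (record every %d), T = %g K, ",
    "D = %g nm^2/ps\n"),
    object@springConstant, object@lambda0, object@lambda1, object@velocity,
    object@timeStep, object@nSteps, object@recordEvery, object@temperature,
    object@diffusion))
})
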