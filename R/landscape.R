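#' Construct a toy landscape
#'
#' @param wells a `data.frame` of wells, typically built by `rbind()`-ing
#'   [gaussianWell()] / [rectangularWell()] rows; may be empty (flat
#'   potential).
#' @param thresholds numeric(2): coordinate values of the 2->1 and 1->0
#'   hydrogen-bond-count transitions (nm).
#' @param bounds numeric(2): domain of the coordinate (nm).
#' @return a [ToyLandscape-class].
#' @examples
#' land <- ToyLandscape(rbind(rectangularWell(0.02, 10, 0.05),
#'                            rectangularWell(0.33, 12, 0.06)))
#' potentialEnergy(land, c(0.02, 0.33))
#' @export
ToyLandscape <- function(wells = emptyWells(), thresholds = c(0.12, 0.25),
                         bounds = c(-0.15, 0.55)) {
  new("ToyLandscape", wells = as.data.frame(wells),
      thresholds = as.numeric(thresholds), bounds = as.numeric(bounds))
}

#' @rdname ToyLandscape
#' @export
emptyWells <- function() {
  data.frame(shape = character(), center = numeric(), depth = numeric(),
             width = numeric(), softness = numeric())
}

#' Well builders
#'
#' `gaussianWell()` is \eqn{-d \exp(-(x-c)^2 / 2 w^2)};
#' `rectangularWell()` is a smoothed square well
#' \eqn{-d/2 [\tanh((x-c+h)/s) - \tanh((x-c-h)/s)]}, whose depth approaches
#' `-d` as the half-width `h` grows past the edge softness `s`.
#'
#' @param center well center (nm).
#' @param depth well depth (kJ/mol, positive = attractive).
#' @param width Gaussian sigma (nm).
#' @param halfwidth rectangular half-width (nm).
#' @param softness rectangular edge softness (nm).
#' @return one-row `data.frame` suitable for [ToyLandscape()].
#' @export
gaussianWell <- function(center, depth, width) {
  data.frame(shape = "gaussian", center = center, depth = depth,
             width = width, softness = NA_real_)
}

#' @rdname gaussianWell
#' @export
rectangularWell <- function(center, depth, halfwidth, softness = 0.015) {
  data.frame(shape = "rectangular", center = center, depth = depth,
             width = halfwidth, softness = softness)
}

## wells as the numeric matrix the C++ kernels consume
.wellsMatrix <- function(landscape) {
  w <- landscape@wells
  if (nrow(w) == 0L) return(matrix(numeric(), 0L, 5L))
  cbind(ifelse(w$shape == "gaussian", 0, 1), w$center, w$depth, w$width,
        ifelse(is.na(w$softness), 1, w$softness))
}

#' Landscape potential energy
#'
#' Sum of the well contributions at positions `x` (deterministic and
#' continuous; an empty well list gives 0 everywhere).
#'
#' @param landscape a [ToyLandscape-class].
#' @param x positions (nm), all inside the domain bounds.
#' @return energies (kJ/mol).
#' @export
potentialEnergy <- function(landscape, x) {
  stopifnot(is(landscape, "ToyLandscape"))
  if (any(!is.finite(x)) || any(x < landscape@bounds[1]) ||
      any(x > landscape@bounds[2]))
    stop("position outside the landscape domain [",
         landscape@bounds[1], ", ", landscape@bounds[2], "] nm")
  cpp_potential(.wellsMatrix(landscape), as.numeric(x))
}

#' Discrete hydrogen-bond count at a coordinate value
#'
#' Step function of the toy coordinate: 2 below the first threshold, 1
#' between the two, 0 above the second.  Total on the whole axis.
#'
#' @param landscape a [ToyLandscape-class].
#' @param x positions (nm).
#' @return integer counts in `{0, 1, 2}`.
#' @export
hbondCount <- function(landscape, x) {
  stopifnot(is(landscape, "ToyLandscape"))
  th <- landscape@thresholds
  as.integer(ifelse(x < th[1], 2L, ifelse(x < th[2], 1L, 0L)))
}

.partitionFunctions <- function(landscape, temperature) {
  kT <- .kT(temperature)
  wm <- .wellsMatrix(landscape)
  dens <- function(x) exp(-cpp_potential(wm, x) / kT)
  b <- landscape@bounds
  cut <- landscape@thresholds[2]       # 1->0 threshold: bound is n >= 1
  zb <- integrate(dens, b[1], cut, rel.tol = 1e-10, subdivisions = 2000L)
  zu <- integrate(dens, cut, b[2], rel.tol = 1e-10, subdivisions = 2000L)
  c(bound = zb$value, unbound = zu$value)
}

#' Exact state free-energy difference by quadrature
#'
#' Ground-truth oracle for the reweighting pipeline: the free-energy
#' difference between the unbound (`n = 0`) and bound (`n >= 1`) regions of
#' a landscape, \eqn{\Delta F = -k_B T \ln(Z_{unbound} / Z_{bound})} with
#' the configurational integrals evaluated by adaptive quadrature.
#'
#' @param landscape a [ToyLandscape-class].
#' @param temperature temperature (K).
#' @param direction `"breaking"` (F(unbound) - F(bound)) or `"formation"`
#'   (its negative).
#' @return free-energy difference (kJ/mol).
#' @examples
#' # entropic limit: flat potential, state widths 0.1 vs 0.2 nm
#' flat <- ToyLandscape(thresholds = c(0.05, 0.1), bounds = c(0, 0.3))
#' quadratureDeltaF(flat, 300)   # -kT log(2) = -1.729 kJ/mol
#' @export
quadratureDeltaF <- function(landscape, temperature = 300,
                             direction = c("breaking", "formation")) {
  direction <- match.arg(direction)
  .assertScalar(temperature, "temperature", positive = TRUE)
  z <- .partitionFunctions(landscape, temperature)
  if (!all(is.finite(z)) || any(z <= 0))
    stop("degenerate partition: a state has vanishing configurational integral")
  df <- -.kT(temperature) * log(z[["unbound"]] / z[["bound"]])
  if (direction == "formation") -df else df
}

#' Calibrate the bound-well depth to a target free-energy difference
#'
#' Adjusts the depth of the (single) well lying in the bound region so that
#' [quadratureDeltaF()] in the breaking direction equals `target` to within
#' 1e-3 kJ/mol, by bracketed root finding.  This is how the packaged
#' apo-like and holo-like systems are built: same geometry, different bound
#' basin depth.
#'
#' @param landscape template [ToyLandscape-class]; exactly one well must be
#'   centered below the 1->0 threshold.
#' @param target desired breaking free-energy difference (kJ/mol).
#' @param temperature temperature (K).
#' @param depthRange depth bracket searched (kJ/mol).
#' @return the calibrated [ToyLandscape-class].
#' @export
calibrateDepth <- function(landscape, target, temperature = 300,
                           depthRange = c(0.01, 40)) {
  stopifnot(is(landscape, "ToyLandscape"))
  .assertScalar(target, "target")
  idx <- which(landscape@wells$center < landscape@thresholds[2])
  if (length(idx) != 1L)
    stop("calibration requires exactly one well in the bound region (found ",
         length(idx), ")")
  fn <- function(d) {
    l <- landscape
    l@wells$depth[idx] <- d
    quadratureDeltaF(l, temperature, "breaking") - target
  }
  flo <- fn(depthRange[1]); fhi <- fn(depthRange[2])
  if (sign(flo) == sign(fhi))
    stop("calibration target ", target, " kJ/mol not bracketed by depths [",
         depthRange[1], ", ", depthRange[2], "]")
  root <- uniroot(fn, depthRange, tol = 1e-7)
  out <- landscape
  out@wells$depth[idx] <- root$root
  achieved <- quadratureDeltaF(out, temperature, "breaking")
  if (abs(achieved - target) > 1e-3)
    stop("calibration did not converge: achieved ", signif(achieved, 6))
  out
}

#' Free-energy difference between restrained endpoint ensembles
#'
#' \eqn{-k_B T \ln \int e^{-\beta(U + V_{\lambda_1})} / \int
#' e^{-\beta(U + V_{\lambda_0})}}: the reversible work of moving the
#' restraint across the full schedule.  By the second law the ensemble-mean
#' pulling work can never fall below this number.
#'
#' @param landscape a [ToyLandscape-class].
#' @param protocol a [PullingProtocol-class] (provides k, the endpoints and
#'   the temperature).
#' @param lambda optional: evaluate at an intermediate restraint center
#'   instead of `lambda1`.
#' @return free-energy difference (kJ/mol) relative to the `lambda0`
#'   restrained ensemble.
#' @export
restrainedDeltaF <- function(landscape, protocol, lambda = NULL) {
  stopifnot(is(landscape, "ToyLandscape"), is(protocol, "PullingProtocol"))
  kT <- .kT(protocol@temperature)
  wm <- .wellsMatrix(landscape)
  b <- landscape@bounds
  k <- protocol@springConstant
  lz <- function(l) {
    dens <- function(x)
      exp(-(cpp_potential(wm, x) + 0.5 * k * (x - l)^2) / kT)
    log(integrate(dens, b[1], b[2], rel.tol = 1e-10,
                  subdivisions = 2000L)$value)
  }
  if (is.null(lambda)) lambda <- protocol@lambda1
  -kT * (lz(lambda) - lz(protocol@lambda0))
}

#' @describeIn ToyLandscape-class display summary
#' @param object a `ToyLandscape`.
#' @export
setMethod("show", "ToyLandscape", function(object) {
  cat("ToyLandscape on [", object@bounds[1], ",", object@bounds[2], "] nm,",
      nrow(object@wells), "well(s)\n")
  cat("  hbond thresholds: 2->1 at", object@thresholds[1], "nm, 1->0 at",
      object@thresholds[2], "nm\n")
  if (nrow(object@wells)) {
    for (i in seq_len(nrow(object@wells)))
      with(object@wells[i, ], cat(sprintf(
        "  %-11s well: center %.3f nm, depth %.3f kJ/mol, width %.3f nm\n",
        shape, center, depth, width)))
  }
})
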