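## S4 classes for the pulling / reweighting pipeline and the duplex module.

#' One-dimensional toy free-energy landscape
#'
#' A `ToyLandscape` is a sum of attractive wells on a bounded 1-D
#' "separation-like" coordinate (nm), standing in for the energetics of a
#' terminal base pair: a bound basin near the paired geometry and an unbound
#' basin past the rupture point.  Two increasing thresholds map the
#' coordinate to a discrete hydrogen-bond count (2, 1, 0), so that `n >= 1`
#' defines the bound state and `n == 0` the unbound state.
#'
#' @slot wells `data.frame` with columns `shape` (`"gaussian"` or
#'   `"rectangular"`), `center` (nm), `depth` (kJ/mol), `width` (nm; the
#'   Gaussian sigma, or the half-width of a rectangular well) and
#'   `softness` (nm; edge width of rectangular wells, ignored for Gaussian).
#' @slot thresholds numeric(2), increasing: positions of the 2->1 and 1->0
#'   hydrogen-bond transitions (nm), strictly inside the domain.
#' @slot bounds numeric(2): domain of the coordinate (nm).  The simulator
#'   reflects at these walls and the quadrature oracle integrates over them.
#'
#' @seealso [gaussianWell()], [rectangularWell()], [potentialEnergy()],
#'   [quadratureDeltaF()], [calibrateDepth()]
#' @export
setClass("ToyLandscape",
  representation(wells = "data.frame", thresholds = "numeric",
                 bounds = "numeric"),
  validity = function(object) {
    w <- object@wells
    th <- object@thresholds
    b <- object@bounds
    msg <- character()
    if (length(b) != 2L || !all(is.finite(b)) || b[1] >= b[2])
      msg <- c(msg, "'bounds' must be two increasing finite positions (nm)")
    if (length(th) != 2L || !all(is.finite(th)) || th[1] >= th[2])
      msg <- c(msg, "'thresholds' must be strictly increasing")
    else if (length(b) == 2L && (th[1] <= b[1] || th[2] >= b[2]))
      msg <- c(msg, "'thresholds' must lie strictly inside the domain bounds")
    need <- c("shape", "center", "depth", "width", "softness")
    if (!all(need %in% names(w))) {
      msg <- c(msg, paste("wells need columns:", paste(need, collapse = ", ")))
    } else if (nrow(w) > 0L) {
      if (!all(w$shape %in% c("gaussian", "rectangular")))
        msg <- c(msg, "well shape must be 'gaussian' or 'rectangular'")
      if (!all(is.finite(w$center)) || !all(is.finite(w$depth)))
        msg <- c(msg, "well centers and depths must be finite")
      if (!all(w$width > 0))
        msg <- c(msg, "well widths must be > 0")
      if (any(w$shape == "rectangular" & !(w$softness > 0)))
        msg <- c(msg, "rectangular wells need softness > 0")
    }
    if (length(msg)) msg else TRUE
  })

#' Constant-velocity pulling protocol
#'
#' Schedule of a moving harmonic restraint \eqn{V(q, \lambda) =
#' k/2 (q - \lambda)^2} with \eqn{\lambda(t) = \lambda_0 + v t}, plus the
#' parameters of the overdamped Langevin dynamics that the toy simulator
#' integrates under it.  The defaults follow the steered-MD protocol of the
#' riboswitch experiment this package emulates: a stiff spring of
#' 3.9e4 (kJ/mol)/nm^2 pulled from 0 to 0.35 nm at 0.175 nm/ns, 300 K.
#'
#' @slot springConstant restraint stiffness k, (kJ/mol)/nm^2.
#' @slot lambda0,lambda1 restraint start / end positions (nm).
#' @slot velocity pulling speed v (nm/ps); 0 for a stationary restraint.
#' @slot timeStep integration step dt (ps).
#' @slot temperature bath temperature (K).
#' @slot diffusion diffusion coefficient D (nm^2/ps).
#' @slot nSteps number of integration steps; derived as
#'   `round((lambda1 - lambda0) / (velocity * timeStep))` when not given.
#' @slot recordEvery output stride: a frame is recorded every this many
#'   steps (work is accumulated at every step regardless).
#'
#' @seealso [defaultProtocol()], [simulateEnsemble()]
#' @export
setClass("PullingProtocol",
  representation(springConstant = "numeric", lambda0 = "numeric",
                 lambda1 = "numeric", velocity = "numeric",
                 timeStep = "numeric", temperature = "numeric",
                 diffusion = "numeric", nSteps = "integer",
                 recordEvery = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@springConstant <= 0) msg <- c(msg, "springConstant must be > 0")
    if (object@velocity < 0) msg <- c(msg, "velocity must be >= 0")
    if (object@timeStep <= 0) msg <- c(msg, "timeStep must be > 0")
    if (object@temperature <= 0) msg <- c(msg, "temperature must be > 0")
    if (object@diffusion <= 0) msg <- c(msg, "diffusion must be > 0")
    if (object@lambda1 < object@lambda0)
      msg <- c(msg, "lambda1 must be >= lambda0")
    if (is.na(object@nSteps) || object@nSteps < 0L)
      msg <- c(msg, "nSteps must be a nonnegative integer")
    if (is.na(object@recordEvery) || object@recordEvery < 1L)
      msg <- c(msg, "recordEvery must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' Ensemble of pulling trajectories
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with recorded frames as rows and replicas as columns.  Assays:
#' `position` (steered-CV value, nm), `work` (accumulated work, kJ/mol; the
#' first frame is exactly 0) and `nhb` (discrete hydrogen-bond count).
#' `rowData` holds the shared `time` (ps) and restraint center `lambda`
#' (nm); `colData` holds per-replica `seed`; `metadata` carries the
#' generating [ToyLandscape-class] (when simulated) and
#' [PullingProtocol-class].
#'
#' @seealso [simulateEnsemble()], [frameWeights()], [jarzynskiProfile()]
#' @export
setClass("WorkEnsemble", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- character()
    a <- SummarizedExperiment::assays(object)
    need <- c("position", "work", "nhb")
    if (!all(need %in% names(a)))
      return(paste("assays must include:", paste(need, collapse = ", ")))
    if (ncol(object) < 1L) msg <- c(msg, "at least one replica is required")
    rd <- SummarizedExperiment::rowData(object)
    if (!all(c("time", "lambda") %in% names(rd)))
      msg <- c(msg, "rowData must carry 'time' and 'lambda'")
    w <- a[["work"]]
    if (nrow(w) > 0L && any(abs(w[1L, ]) > 1e-12))
      msg <- c(msg, "accumulated work must start at 0 (W_0 = 0)")
    p <- S4Vectors::metadata(object)$protocol
    if (is(p, "PullingProtocol") && nrow(object) > 0L) {
      lam <- p@lambda0 + p@velocity * rd$time
      if (max(abs(lam - rd$lambda)) > 1e-9)
        msg <- c(msg, "lambda does not match the protocol schedule")
    }
    if (length(msg)) msg else TRUE
  })

#' Free-energy profile along time or an arbitrary collective variable
#'
#' @slot grid grid positions: time (ps), restraint center (nm) or CV bin
#'   centers / discrete CV values.
#' @slot values free energies (kJ/mol); `NA` marks bins with no weight
#'   (undefined, never interpolated).
#' @slot gridLabel what the grid is (`"time"`, `"lambda"`, or a CV name).
#' @slot anchor reference convention: `"endpoint"` (F = 0 at the first
#'   slice) or `"minimum"` (min F = 0).  Profiles are equivalence classes
#'   under constant shifts; comparisons should be shift-invariant.
#' @slot temperature temperature (K) used for the estimate.
#' @slot aux list of extras (e.g. `lambda`, `meanWork`, `weightPerBin`,
#'   `singleSupport`).
#' @export
setClass("FreeEnergyProfile",
  representation(grid = "numeric", values = "numeric", gridLabel = "character",
                 anchor = "character", temperature = "numeric", aux = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@grid) != length(object@values))
      msg <- c(msg, "grid and values must have equal length")
    if (!object@anchor %in% c("endpoint", "minimum"))
      msg <- c(msg, "anchor must be 'endpoint' or 'minimum'")
    if (length(msg)) msg else TRUE
  })

#' Per-frame unbiased statistical weights (Jarzynski + WHAM)
#'
#' Normalized weights \eqn{w_{t,i}} over all frames of a pulling ensemble
#' (rows = time slices, columns = replicas), together with the per-slice
#' Jarzynski free energies \eqn{f_t} entering the weight denominator.
#' Weights sum to one over the whole ensemble; summing them over any
#' partition of the frames yields unbiased equilibrium populations.
#'
#' @slot weights matrix of normalized weights, `sum(weights) == 1`.
#' @slot sliceFE per-slice Jarzynski free energies f_t (kJ/mol), endpoint
#'   anchored (f_1 = 0).
#' @slot temperature temperature (K).
#' @slot springConstant restraint stiffness used in the bias potential.
#' @slot stride slice decimation used in the weight denominator (1 = none).
#' @seealso [frameWeights()], [stateDeltaF()], [projectFreeEnergy()]
#' @export
setClass("FrameWeights",
  representation(weights = "matrix", sliceFE = "numeric",
                 temperature = "numeric", springConstant = "numeric",
                 stride = "integer"),
  validity = function(object) {
    msg <- character()
    if (any(object@weights < 0)) msg <- c(msg, "weights must be >= 0")
    if (abs(sum(object@weights) - 1) > 1e-8)
      msg <- c(msg, "weights must sum to 1 over all frames")
    if (length(object@sliceFE) != nrow(object@weights))
      msg <- c(msg, "sliceFE must have one entry per time slice")
    if (length(msg)) msg else TRUE
  })

#' Free-energy difference between bound and unbound states
#'
#' Result container for state free-energy differences and their two-system
#' comparison.  The `direction` tag fixes the sign convention:
#' `"breaking"` is F(unbound) - F(bound), `"formation"` its exact negative.
#' A negative breaking value means the pair opens spontaneously.
#'
#' @slot value free-energy difference (kJ/mol).
#' @slot direction `"breaking"` or `"formation"`.
#' @slot se bootstrap standard error (kJ/mol); `NA` until bootstrapped.
#' @slot nReplicas number of trajectories behind the estimate.
#' @slot temperature temperature (K).
#' @slot diagnostics list: `ess` (Kish effective sample size over
#'   per-trajectory aggregated weights), `maxTrajFraction` (largest single
#'   trajectory share of total weight), and for differences the two
#'   per-system results.
#' @slot resamples bootstrap resample values (kJ/mol), possibly empty.
#' @slot nFailed number of bootstrap resamples dropped for an empty state.
#' @slot B number of bootstrap resamples requested.
#' @seealso [stateDeltaF()], [bootstrapDeltaF()], [deltaDeltaF()]
#' @export
setClass("DeltaFResult",
  representation(value = "numeric", direction = "character", se = "numeric",
                 nReplicas = "integer", temperature = "numeric",
                 diagnostics = "list", resamples = "numeric",
                 nFailed = "integer", B = "integer"),
  validity = function(object) {
    if (!object@direction %in% c("breaking", "formation"))
      return("direction must be 'breaking' or 'formation'")
    TRUE
  })

#' Fully paired RNA duplex
#'
#' Two RNA strands of equal length, paired position by position.  The top
#' strand is stored 5'->3' and the bottom strand 3'->5' (i.e. exactly as
#' written underneath the top strand in an alignment), so position i of one
#' pairs with position i of the other.  Every position must form a
#' Watson-Crick (AU, UA, GC, CG) or wobble (GU, UG) pair.
#'
#' @slot top [Biostrings::RNAString] read 5'->3'.
#' @slot bottom [Biostrings::RNAString] read 3'->5'.
#' @slot pairClass character vector, `"WC"` or `"wobble"` per position.
#' @seealso [parseDuplex()], [duplexDeltaG()]
#' @export
setClass("Duplex",
  representation(top = "RNAString", bottom = "RNAString",
                 pairClass = "character"))

#' Nearest-neighbor duplex parameter set
#'
#' Stacking free energies and end terms of the nearest-neighbor model,
#' in kcal/mol at 37 C (the native unit of the source tables; results are
#' converted to kJ/mol at 4.184 on output).
#'
#' @slot name parameter-set label (e.g. `"turner1999"`).
#' @slot stacks named numeric vector of stack free energies; names are
#'   `"XY/ZW"` with the top dinucleotide 5'-XY-3' over the bottom
#'   dinucleotide 5'-ZW-3' (pairs X.W and Y.Z).
#' @slot initiation duplex initiation penalty (kcal/mol).
#' @slot terminalAU per-end penalty for a terminal AU or GU pair (kcal/mol).
#' @slot symmetry self-complementarity correction (kcal/mol).
#' @slot source provenance of the numbers.
#' @seealso [nnParameters()], [duplexDeltaG()]
#' @export
setClass("NNParameterSet",
  representation(name = "character", stacks = "numeric",
                 initiation = "numeric", terminalAU = "numeric",
                 symmetry = "numeric", source = "character"),
  validity = function(object) {
    if (!all(is.finite(object@stacks)))
      return("all stack energies must be finite")
    TRUE
  })
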