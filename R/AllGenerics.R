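#' @rdname WorkEnsemble-class
#' @param x an object.
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname WorkEnsemble-class
#' @export
setGeneric("works", function(x) standardGeneric("works"))

#' @rdname WorkEnsemble-class
#' @export
setGeneric("hbonds", function(x) standardGeneric("hbonds"))

#' @rdname WorkEnsemble-class
#' @export
setGeneric("nReplicas", function(x) standardGeneric("nReplicas"))

#' @rdname WorkEnsemble-class
#' @export
setGeneric("protocolOf", function(x) standardGeneric("protocolOf"))

#' @rdname WorkEnsemble-class
#' @export
setGeneric("landscapeOf", function(x) standardGeneric("landscapeOf"))

#' Time and restraint-center grids
#'
#' `timeGrid()` returns the recorded frame times (ps) and
#' `lambdaSchedule()` the restraint centers (nm) at those times, for a
#' [PullingProtocol-class] or a [WorkEnsemble-class].
#'
#' @param x a `PullingProtocol` or `WorkEnsemble`.
#' @return numeric vector.
#' @export
setGeneric("timeGrid", function(x) standardGeneric("timeGrid"))

#' @rdname timeGrid
#' @export
setGeneric("lambdaSchedule", function(x) standardGeneric("lambdaSchedule"))

#' @rdname PullingProtocol-class
#' @param x an object.
#' @export
setGeneric("nSteps", function(x) standardGeneric("nSteps"))

#' @rdname FreeEnergyProfile-class
#' @param x an object.
#' @export
setGeneric("feGrid", function(x) standardGeneric("feGrid"))

#' @rdname FreeEnergyProfile-class
#' @export
setGeneric("feValues", function(x) standardGeneric("feValues"))

#' @rdname FrameWeights-class
#' @param x an object.
#' @export
setGeneric("weightMatrix", function(x) standardGeneric("weightMatrix"))

#' @rdname FrameWeights-class
#' @export
setGeneric("sliceFreeEnergies", function(x) standardGeneric("sliceFreeEnergies"))

#' @rdname DeltaFResult-class
#' @param x an object.
#' @export
setGeneric("dfValue", function(x) standardGeneric("dfValue"))

#' @rdname DeltaFResult-class
#' @export
setGeneric("dfSe", function(x) standardGeneric("dfSe"))

#' @rdname DeltaFResult-class
#' @export
setGeneric("dfDirection", function(x) standardGeneric("dfDirection"))

#' @rdname DeltaFResult-class
#' @export
setGeneric("dfDiagnostics", function(x) standardGeneric("dfDiagnostics"))

#' @rdname Duplex-class
#' @param x an object.
#' @export
setGeneric("countPairs", function(x) standardGeneric("countPairs"))

#' @rdname Duplex-class
#' @export
setGeneric("pairTypes", function(x) standardGeneric("pairTypes"))
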