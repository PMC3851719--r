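#' Assemble a work ensemble from frame matrices
#'
#' Low-level constructor used by [simulateEnsemble()] and the COLVAR
#' reader; also handy for building small ensembles by hand in tests.
#'
#' @param position,work matrices (frames x replicas): steered-CV values
#'   (nm) and accumulated work (kJ/mol, first row 0).
#' @param nhb integer matrix of hydrogen-bond counts, same shape (may be
#'   `NA` for externally read data lacking the column).
#' @param time recorded times (ps), one per frame row.
#' @param lambda restraint centers (nm), one per frame row.
#' @param protocol the generating [PullingProtocol-class].
#' @param landscape the generating [ToyLandscape-class], or `NULL`.
#' @param seeds per-replica integer seeds, or `NULL`.
#' @return a [WorkEnsemble-class].
#' @export
WorkEnsemble <- function(position, work, nhb, time, lambda, protocol,
                         landscape = NULL, seeds = NULL) {
  position <- as.matrix(position); work <- as.matrix(work)
  nhb <- matrix(as.integer(as.matrix(nhb)), nrow(position), ncol(position))
  cd <- S4Vectors::DataFrame(
    seed = if (is.null(seeds)) rep(NA_integer_, ncol(position)) else seeds)
  rownames(cd) <- sprintf("replica%04d", seq_len(ncol(position)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(position = position, work = work,
                                   nhb = nhb),
    rowData = S4Vectors::DataFrame(time = as.numeric(time),
                                   lambda = as.numeric(lambda)),
    colData = cd)
  S4Vectors::metadata(se) <- list(protocol = protocol, landscape = landscape)
  new("WorkEnsemble", se)
}

#' Simulate one pulling trajectory
#'
#' Integrates overdamped Langevin dynamics (Euler-Maruyama,
#' \eqn{x \leftarrow x - \beta D \nabla(U + V) dt + \sqrt{2 D dt}\,\eta})
#' on the landscape under the protocol's moving harmonic restraint.  The
#' starting point is drawn from the `lambda0`-restrained Boltzmann density
#' by rejection sampling (independent equilibrated starts).  Work is
#' accumulated at every integration step by the potential-difference
#' convention \eqn{W \mathrel{+}= V(x_t, \lambda_{t+1}) - V(x_t,
#' \lambda_t)}, which satisfies the discrete-time Jarzynski identity for a
#' Boltzmann-preserving propagator.  Identical (landscape, protocol, seed)
#' give a bitwise-identical trajectory.
#'
#' @param landscape a [ToyLandscape-class].
#' @param protocol a [PullingProtocol-class].
#' @param seed integer RNG seed.
#' @return a [S4Vectors::DataFrame] with columns `time` (ps), `position`
#'   (nm), `lambda` (nm), `work` (kJ/mol) and `nhb` (count), one row per
#'   recorded frame.
#' @export
simulateTrajectory <- function(landscape, protocol, seed) {
  stopifnot(is(landscape, "ToyLandscape"), is(protocol, "PullingProtocol"))
  res <- cpp_simulate(.wellsMatrix(landscape), landscape@bounds[1],
                      landscape@bounds[2], landscape@thresholds[1],
                      landscape@thresholds[2], protocol@springConstant,
                      protocol@lambda0, protocol@velocity, protocol@timeStep,
                      protocol@nSteps, protocol@recordEvery,
                      .kT(protocol@temperature), protocol@diffusion,
                      as.numeric(seed))
  S4Vectors::DataFrame(res)
}

#' Simulate an ensemble of independent pulling replicas
#'
#' Replica `i` is simulated with seed `baseSeed + i`; replicas are
#' otherwise independent and share the protocol's time grid and restraint
#' schedule.  The reference experiment uses 512 replicas per system.
#'
#' @param landscape a [ToyLandscape-class].
#' @param protocol a [PullingProtocol-class].
#' @param nReplicas number of replicas (>= 1).
#' @param baseSeed integer base seed.
#' @return a [WorkEnsemble-class].
#' @examples
#' land <- ToyLandscape(rbind(rectangularWell(0.02, 8, 0.05),
#'                            rectangularWell(0.33, 12, 0.06)))
#' ens <- simulateEnsemble(land, defaultProtocol(), nReplicas = 4,
#'                         baseSeed = 1)
#' nReplicas(ens)
#' @export
simulateEnsemble <- function(landscape, protocol, nReplicas = 512,
                             baseSeed = 1) {
  stopifnot(nReplicas >= 1)
  seeds <- as.integer(baseSeed) + seq_len(nReplicas)
  trajs <- vector("list", nReplicas)
  for (i in seq_len(nReplicas)) {
    trajs[[i]] <- tryCatch(simulateTrajectory(landscape, protocol, seeds[i]),
                           error = function(e)
                             stop("replica ", i, ": ", conditionMessage(e),
                                  call. = FALSE))
  }
  WorkEnsemble(
    position = vapply(trajs, function(t) t$position, trajs[[1]]$position),
    work = vapply(trajs, function(t) t$work, trajs[[1]]$work),
    nhb = vapply(trajs, function(t) t$nhb, trajs[[1]]$nhb),
    time = trajs[[1]]$time, lambda = trajs[[1]]$lambda,
    protocol = protocol, landscape = landscape, seeds = seeds)
}

#' @rdname WorkEnsemble
#' @param x a `WorkEnsemble`.
#' @export
setMethod("positions", "WorkEnsemble", function(x)
  SummarizedExperiment::assay(x, "position"))

#' @rdname WorkEnsemble
#' @export
setMethod("works", "WorkEnsemble", function(x)
  SummarizedExperiment::assay(x, "work"))

#' @rdname WorkEnsemble
#' @export
setMethod("hbonds", "WorkEnsemble", function(x)
  SummarizedExperiment::assay(x, "nhb"))

#' @rdname WorkEnsemble
#' @export
setMethod("nReplicas", "WorkEnsemble", function(x) ncol(x))

#' @rdname WorkEnsemble
#' @export
setMethod("protocolOf", "WorkEnsemble", function(x)
  S4Vectors::metadata(x)$protocol)

#' @rdname WorkEnsemble
#' @export
setMethod("landscapeOf", "WorkEnsemble", function(x)
  S4Vectors::metadata(x)$landscape)

#' @rdname timeGrid
#' @export
setMethod("timeGrid", "WorkEnsemble", function(x)
  SummarizedExperiment::rowData(x)$time)

#' @rdname timeGrid
#' @export
setMethod("lambdaSchedule", "WorkEnsemble", function(x)
  SummarizedExperiment::rowData(x)$lambda)

#' @describeIn WorkEnsemble display summary
#' @param object a `WorkEnsemble`.
#' @export
setMethod("show", "WorkEnsemble", function(object) {
  cat("WorkEnsemble:", ncol(object), "replicas x", nrow(object),
      "recorded frames\n")
  p <- protocolOf(object)
  if (is(p, "PullingProtocol"))
    cat(sprintf("  restraint %g -> %g nm at %g nm/ps, k = %g, T = %g K\n",
                p@lambda0, p@lambda1, p@velocity, p@springConstant,
                p@temperature))
  w <- works(object)
  cat(sprintf("  final work: mean %.3f, sd %.3f kJ/mol\n",
              mean(w[nrow(w), ]), sd(w[nrow(w), ])))
})
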