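## PLUMED-dialect COLVAR text files: a `#! FIELDS ...` header line naming
## the columns, optional `#! SET key value` lines, then whitespace-
## separated numeric rows.

#' Write an ensemble as COLVAR files, one per replica
#'
#' Each file starts with `#! FIELDS time position lambda work nhb`, a
#' `#! SET seed <n>` line recording the replica's seed, and one
#' whitespace-separated row per recorded frame (>= 6 significant digits).
#'
#' @param ensemble a [WorkEnsemble-class].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix; files are `<prefix>_0001.colvar`, ...
#' @return the file paths, invisibly.
#' @export
writeColvar <- function(ensemble, dir, prefix = "replica") {
  stopifnot(is(ensemble, "WorkEnsemble"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  q <- positions(ensemble); W <- works(ensemble); nhb <- hbonds(ensemble)
  tt <- timeGrid(ensemble); lam <- lambdaSchedule(ensemble)
  seeds <- colData(ensemble)$seed
  paths <- file.path(dir, sprintf("%s_%04d.colvar", prefix,
                                  seq_len(ncol(q))))
  for (i in seq_len(ncol(q))) {
    rows <- sprintf("%.10g %.10g %.10g %.10g %d",
                    tt, q[, i], lam, W[, i], nhb[, i])
    writeLines(c("#! FIELDS time position lambda work nhb",
                 sprintf("#! SET seed %d", seeds[i]), rows), paths[i])
  }
  invisible(paths)
}

#' Read one COLVAR trajectory
#'
#' Columns are mapped by the names in the `#! FIELDS` header, not by
#' position.  `time`, `position` and `lambda` are required; `work` and
#' `nhb` are optional (work can be recomputed downstream with
#' [accumulateWork()]; without `nhb` only position projections are
#' possible).
#'
#' @param path file path.
#' @return a [S4Vectors::DataFrame] of the named columns, with any
#'   `#! SET` keys in its metadata.
#' @export
readColvar <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || !startsWith(lines[1], "#! FIELDS "))
    stop("format error in '", path,
         "', line 1: expected a '#! FIELDS ...' header")
  fields <- strsplit(trimws(sub("^#! FIELDS", "", lines[1])), "\\s+")[[1]]
  need <- c("time", "position", "lambda")
  if (!all(need %in% fields))
    stop("format error in '", path, "': header must name at least ",
         paste(need, collapse = ", "))
  sets <- list()
  body <- character(); bodyLineNo <- integer()
  for (i in seq_along(lines)[-1]) {
    ln <- trimws(lines[i])
    if (!nchar(ln)) next
    if (startsWith(ln, "#! SET")) {
      kv <- strsplit(trimws(sub("^#! SET", "", ln)), "\\s+")[[1]]
      if (length(kv) >= 2L) sets[[kv[1]]] <- kv[2]
      next
    }
    if (startsWith(ln, "#")) next
    body <- c(body, ln); bodyLineNo <- c(bodyLineNo, i)
  }
  toks <- strsplit(body, "\\s+")
  nt <- lengths(toks)
  if (any(nt != length(fields))) {
    j <- which(nt != length(fields))[1]
    stop("format error in '", path, "', line ", bodyLineNo[j], ": ",
         nt[j], " fields, expected ", length(fields))
  }
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(toks)), ncol = length(fields), byrow = TRUE))
  if (anyNA(vals)) {
    j <- which(rowSums(is.na(vals)) > 0)[1]
    stop("format error in '", path, "', line ", bodyLineNo[j],
         ": non-numeric value")
  }
  colnames(vals) <- fields
  out <- S4Vectors::DataFrame(as.data.frame(vals))
  S4Vectors::metadata(out) <- sets
  out
}

#' Assemble COLVAR trajectories into a work ensemble
#'
#' All files must share one time grid and restraint schedule (external
#' ensembles with missing frames are rejected, not reweighted).  A missing
#' work column is recomputed with [accumulateWork()] at the recorded
#' resolution; a missing `nhb` column is filled with `NA` (state
#' partitioning then refuses to run, position projections still work).
#'
#' @param paths COLVAR file paths, one replica each.
#' @param protocol the [PullingProtocol-class] the files were produced
#'   under (provides k and the temperature).
#' @param landscape optional [ToyLandscape-class] for provenance.
#' @return a [WorkEnsemble-class].
#' @export
ensembleFromColvar <- function(paths, protocol, landscape = NULL) {
  stopifnot(length(paths) >= 1L, is(protocol, "PullingProtocol"))
  trajs <- lapply(paths, readColvar)
  ref <- trajs[[1]]
  for (i in seq_along(trajs)[-1]) {
    if (nrow(trajs[[i]]) != nrow(ref) ||
        max(abs(trajs[[i]]$time - ref$time)) > 1e-9 ||
        max(abs(trajs[[i]]$lambda - ref$lambda)) > 1e-9)
      stop("'", paths[i], "' does not share the time grid / restraint ",
           "schedule of '", paths[1], "'")
  }
  getw <- function(t) {
    if (!is.null(t$work)) t$work
    else accumulateWork(t$position, t$lambda, protocol@springConstant)
  }
  getn <- function(t) if (!is.null(t$nhb)) as.integer(t$nhb)
                      else rep(NA_integer_, nrow(t))
  seeds <- vapply(trajs, function(t) {
    s <- S4Vectors::metadata(t)$seed
    if (is.null(s)) NA_integer_ else as.integer(s)
  }, 1L)
  WorkEnsemble(
    position = vapply(trajs, function(t) t$position, ref$position),
    work = vapply(trajs, getw, ref$position),
    nhb = vapply(trajs, getn, integer(nrow(ref))),
    time = ref$time, lambda = ref$lambda, protocol = protocol,
    landscape = landscape, seeds = seeds)
}

#' Write a free-energy profile as tab-separated text
#'
#' @param profile a [FreeEnergyProfile-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeProfile <- function(profile, path) {
  stopifnot(is(profile, "FreeEnergyProfile"))
  d <- as.data.frame(profile)
  hdr <- c(sprintf("# free-energy profile over %s (%s-anchored), kJ/mol at %g K",
                   profile@gridLabel, profile@anchor, profile@temperature),
           paste0("# ", paste(names(d), collapse = "\t")))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(d, digits = 10, trim = TRUE), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write free-energy-difference results as a tab-separated table
#'
#' One row per result with columns `system`, `value`, `se`, `B`,
#' `n_failed`, `ESS`, `max_traj_fraction`, `converged`.
#'
#' @param results named list of [DeltaFResult-class] objects.
#' @param path output file.
#' @param extraHeader additional `#` header lines (e.g. provenance).
#' @return `path`, invisibly.
#' @export
writeDeltaFTable <- function(results, path, extraHeader = character()) {
  fmt <- function(x) ifelse(is.na(x), "NA", format(x, digits = 8))
  rows <- vapply(names(results), function(nm) {
    r <- results[[nm]]
    d <- r@diagnostics
    ess <- if (!is.null(d$ess)) d$ess else NA_real_
    frac <- if (!is.null(d$maxTrajFraction)) d$maxTrajFraction else NA_real_
    conv <- if (!is.na(r@se)) convergenceReport(r)$converged else NA
    paste(nm, fmt(r@value), fmt(r@se), fmt(r@B), fmt(r@nFailed), fmt(ess),
          fmt(frac), fmt(conv), sep = "\t")
  }, "")
  writeLines(c(
    "# state free-energy differences, kJ/mol (direction: breaking = F_unbound - F_bound)",
    extraHeader,
    "# system\tvalue\tse\tB\tn_failed\tESS\tmax_traj_fraction\tconverged",
    rows), path)
  invisible(path)
}
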