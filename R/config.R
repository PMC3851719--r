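## INI-style run configuration: `[section]` headers and `key = value`
## lines; `#` or `;` start comments; multi-valued keys are whitespace-
## separated.  Numeric-looking values are converted; true/false become
## logical.

.parseIniValue <- function(v) {
  parts <- strsplit(trimws(v), "\\s+")[[1]]
  if (length(parts) == 0L) return(NULL)
  low <- tolower(parts)
  if (all(low %in% c("true", "false"))) return(low == "true")
  num <- suppressWarnings(as.numeric(parts))
  if (!anyNA(num)) num else parts
}

.readIni <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  out <- list()
  section <- NULL
  for (i in seq_along(lines <- readLines(path))) {
    ln <- sub("[#;].*$", "", lines[i])
    ln <- trimws(ln)
    if (!nchar(ln)) next
    if (grepl("^\\[.+\\]$", ln)) {
      section <- sub("^\\[(.+)\\]$", "\\1", ln)
      if (is.null(out[[section]])) out[[section]] <- list()
      next
    }
    if (!grepl("=", ln) || is.null(section))
      stop("config parse error at line ", i, ": expected '[section]' or ",
           "'key = value'")
    key <- trimws(sub("=.*$", "", ln))
    out[[section]][[key]] <- .parseIniValue(sub("^[^=]*=", "", ln))
  }
  out
}

#' Path of the packaged default experiment configuration
#'
#' The packaged configuration defines the calibrated apo-like/holo-like
#' two-system experiment: landscape geometry, calibration targets
#' (-2.5 and +1.9 kJ/mol breaking free energies), the slow (1/8 speed)
#' pulling protocol, 512 replicas per system and a 200-resample bootstrap.
#'
#' @return file path.
#' @export
defaultConfigPath <- function()
  system.file("extdata", "default_experiment.ini", package = "steeredFE",
              mustWork = TRUE)

#' Read and validate a run configuration
#'
#' @param path INI-style configuration file with sections `[landscape]`,
#'   `[protocol]`, `[analysis]`, `[bootstrap]` and `[experiment]`.
#' @return a validated nested list (class `steeredFE_config`).
#' @export
readRunConfig <- function(path = defaultConfigPath()) {
  cfg <- .readIni(path)
  need <- c("landscape", "protocol", "analysis", "bootstrap", "experiment")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("config is missing section(s): ", paste(miss, collapse = ", "))
  for (key in c("seed_apo", "seed_holo"))
    if (is.null(cfg$experiment[[key]]))
      stop("config must set experiment.", key,
           " explicitly (no wall-clock seeding)")
  if (is.null(cfg$bootstrap$seed))
    stop("config must set bootstrap.seed explicitly")
  structure(cfg, class = c("steeredFE_config", "list"))
}

#' Build the landscape template described by a configuration
#'
#' @param cfg a configuration list from [readRunConfig()] (its
#'   `landscape` section is used).
#' @return a [ToyLandscape-class] with the template bound-well depth (the
#'   per-system depths come from [calibrateDepth()]).
#' @export
configLandscape <- function(cfg) {
  l <- cfg$landscape
  ToyLandscape(
    wells = rbind(
      rectangularWell(l$bound_center, l$bound_depth, l$bound_halfwidth,
                      l$bound_softness),
      rectangularWell(l$unbound_center, l$unbound_depth,
                      l$unbound_halfwidth, l$unbound_softness)),
    thresholds = l$thresholds, bounds = l$bounds)
}

#' Build the pulling protocol described by a configuration
#'
#' @param cfg a configuration list from [readRunConfig()] (its `protocol`
#'   section is used).
#' @return a [PullingProtocol-class].
#' @export
configProtocol <- function(cfg) {
  p <- cfg$protocol
  PullingProtocol(springConstant = p$spring_constant, lambda0 = p$lambda0,
                  lambda1 = p$lambda1, velocity = p$velocity,
                  timeStep = p$time_step, temperature = p$temperature,
                  diffusion = p$diffusion,
                  recordEvery = p$record_every)
}
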