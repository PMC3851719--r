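.KCAL_TO_KJ <- 4.184

#' Load an embedded nearest-neighbor parameter set
#'
#' Two Turner-rule parameter sets ship with the package as plain TSV
#' tables (see `inst/extdata/`): `"turner1999"` (0.1 kcal/mol precision,
#' as distributed with the Vienna RNA package) and `"turner2004"`
#' (two-decimal Watson-Crick stacks).  The default is the set whose
#' helix-extension prediction for the reference P1 comparison lies closest
#' to the published melting-experiment value.
#'
#' @param set `"turner1999"` (default) or `"turner2004"`.
#' @return an [NNParameterSet-class].
#' @export
nnParameters <- function(set = c("turner1999", "turner2004")) {
  set <- match.arg(set)
  path <- system.file("extdata", paste0("nn_", set, ".tsv"),
                      package = "steeredFE", mustWork = TRUE)
  src <- sub("^# source: ", "", grep("^# source:", readLines(path, n = 5),
                                     value = TRUE))
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  stacks <- setNames(tab$value[tab$type == "stack"],
                     tab$key[tab$type == "stack"])
  scalar <- function(ty) tab$value[tab$type == ty][1]
  new("NNParameterSet", name = set, stacks = stacks,
      initiation = scalar("init"), terminalAU = scalar("terminal_au"),
      symmetry = scalar("symmetry"), source = src)
}

.stackKey <- function(t1, t2, b1, b2) paste0(t1, t2, "/", b2, b1)

.lookupStack <- function(params, t1, t2, b1, b2) {
  key <- .stackKey(t1, t2, b1, b2)
  if (!is.na(params@stacks[key])) return(params@stacks[[key]])
  rev <- paste0(b2, b1, "/", t1, t2)   # read the step from the other strand
  if (!is.na(params@stacks[rev])) return(params@stacks[[rev]])
  stop("parameter set '", params@name, "' has no entry for stack ", key)
}

.isSelfComplementary <- function(d) {
  ch <- .duplexChars(d)
  identical(ch$top, rev(ch$bottom))   # both strands are the same molecule
}

#' Nearest-neighbor duplex free energy at 37 C
#'
#' \eqn{\Delta G^\circ_{37}} of a fully paired duplex as duplex initiation
#' plus the sum over nearest-neighbor stacking steps, plus a per-end
#' penalty for terminal AU or GU pairs, plus the symmetry correction for
#' self-complementary duplexes.  Source tables are kcal-denominated and
#' converted at 4.184 kJ/kcal.
#'
#' @param duplex a [Duplex-class].
#' @param params an [NNParameterSet-class]; default [nnParameters()].
#' @return free energy (kJ/mol) with attribute `parameterSet`.
#' @examples
#' duplexDeltaG(parseDuplex("GC", "CG"))
#' @export
duplexDeltaG <- function(duplex, params = nnParameters()) {
  stopifnot(is(duplex, "Duplex"), is(params, "NNParameterSet"))
  ch <- .duplexChars(duplex)
  n <- length(ch$top)
  g <- params@initiation
  for (i in seq_len(n - 1L))
    g <- g + .lookupStack(params, ch$top[i], ch$top[i + 1L],
                          ch$bottom[i], ch$bottom[i + 1L])
  for (end in c(1L, n)) {
    pair <- paste0(ch$top[end], ch$bottom[end])
    if (pair %in% c("AU", "UA", .WOBBLE_PAIRS)) g <- g + params@terminalAU
  }
  if (.isSelfComplementary(duplex)) g <- g + params@symmetry
  structure(g * .KCAL_TO_KJ, parameterSet = params@name)
}

#' Helix-extension free-energy difference
#'
#' \eqn{\Delta G^\circ_{37}(extended) - \Delta G^\circ_{37}(reference)}
#' under one parameter set.  The duplex-initiation term cancels exactly,
#' so for a terminal extension the difference reduces to the added stack
#' plus the net change in terminal penalties.  This is the
#' secondary-structure counterpart of the pulling experiment's
#' \eqn{\Delta\Delta F}: a bound ligand stacking on the terminal pair is
#' treated as one extra AU pair.
#'
#' @param extended,reference [Duplex-class] objects sharing `params`.
#' @param params an [NNParameterSet-class].
#' @return free-energy difference (kJ/mol), attribute `parameterSet`.
#' @examples
#' ext <- parseDuplex("CGCUUCAUAA", "GUGAAGUAUU")
#' ref <- parseDuplex("CGCUUCAUA",  "GUGAAGUAU")
#' deltaDeltaG(ext, ref)   # about -3.8 kJ/mol
#' @export
deltaDeltaG <- function(extended, reference, params = nnParameters()) {
  g <- duplexDeltaG(extended, params) - duplexDeltaG(reference, params)
  structure(as.numeric(g), parameterSet = params@name)
}

#' @describeIn NNParameterSet-class display summary
#' @param object an `NNParameterSet`.
#' @export
setMethod("show", "NNParameterSet", function(object) {
  cat(sprintf(paste0(
    "NNParameterSet '%s': %d stacks, init %.2f, terminal AU/GU %.2f, ",
    "symmetry %.2f kcal/mol\n  source: %s\n"),
    object@name, length(object@stacks), object@initiation,
    object@terminalAU, object@symmetry, object@source))
})
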