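.WC_PAIRS <- c("AU", "UA", "GC", "CG")
.WOBBLE_PAIRS <- c("GU", "UG")

.cleanStrand <- function(x, what) {
  if (!is.character(x) || length(x) != 1L)
    stop("'", what, "' must be a single string")
  x <- toupper(gsub("[[:space:]]", "", x))
  if (grepl("T", x)) {
    warning("'", what, "': T converted to U (DNA alphabet given for RNA)")
    x <- gsub("T", "U", x)
  }
  bad <- regmatches(x, regexpr("[^ACGU]", x))
  if (length(bad) && nchar(bad))
    stop("'", what, "' contains non-RNA character '", bad, "'")
  x
}

#' Parse a fully paired RNA duplex
#'
#' Pairs the two strands position by position — the top strand read
#' 5'->3', the bottom strand given 3'->5' exactly as written under the top
#' strand in an alignment — and classifies every pair as Watson-Crick
#' (AU, UA, GC, CG) or wobble (GU, UG).  Any other juxtaposition makes the
#' duplex invalid.
#'
#' @param top top strand, 5'->3', over `{A, C, G, U}` (T is converted to U
#'   with a warning).
#' @param bottom3to5 bottom strand, written 3'->5', same length.
#' @return a [Duplex-class].
#' @examples
#' d <- parseDuplex("CGCUUCAUA", "GUGAAGUAU")
#' countPairs(d)     # 9
#' pairTypes(d)      # one wobble at position 2
#' @export
parseDuplex <- function(top, bottom3to5) {
  top <- .cleanStrand(top, "top")
  bottom3to5 <- .cleanStrand(bottom3to5, "bottom3to5")
  if (nchar(top) != nchar(bottom3to5))
    stop("strands must have equal length (", nchar(top), " vs ",
         nchar(bottom3to5), ")")
  if (nchar(top) < 2L)
    stop("a duplex needs at least 2 base pairs")
  tc <- strsplit(top, "")[[1]]
  bc <- strsplit(bottom3to5, "")[[1]]
  pair <- paste0(tc, bc)
  cls <- ifelse(pair %in% .WC_PAIRS, "WC",
                ifelse(pair %in% .WOBBLE_PAIRS, "wobble", NA))
  if (anyNA(cls)) {
    i <- which(is.na(cls))[1]
    stop("invalid duplex: position ", i, " (", tc[i], "·", bc[i],
         ") is neither Watson-Crick nor wobble")
  }
  new("Duplex", top = Biostrings::RNAString(top),
      bottom = Biostrings::RNAString(bottom3to5), pairClass = cls)
}

#' @rdname Duplex-class
#' @export
setMethod("countPairs", "Duplex", function(x) length(x@pairClass))

#' @rdname Duplex-class
#' @export
setMethod("pairTypes", "Duplex", function(x) x@pairClass)

## character vectors of the two strands (bottom still 3'->5')
.duplexChars <- function(d)
  list(top = strsplit(as.character(d@top), "")[[1]],
       bottom = strsplit(as.character(d@bottom), "")[[1]])

#' @describeIn Duplex-class display the alignment
#' @param object a `Duplex`.
#' @export
setMethod("show", "Duplex", function(object) {
  nw <- sum(object@pairClass == "wobble")
  cat("RNA duplex,", countPairs(object), "base pairs (", nw, "wobble )\n")
  cat("  5'-", as.character(object@top), "-3'\n", sep = "")
  cat("  3'-", as.character(object@bottom), "-5'\n", sep = "")
})
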