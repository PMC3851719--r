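ALL_PAIRS <- c("AU", "UA", "GC", "CG", "GU", "UG")

## independent brute-force recomputation of the nearest-neighbor sum,
## used as the oracle for duplexDeltaG
nnBruteForce <- function(top, bottom, params) {
  tc <- strsplit(top, "")[[1]]; bc <- strsplit(bottom, "")[[1]]
  g <- params@initiation
  for (i in seq_len(length(tc) - 1L)) {
    key <- paste0(tc[i], tc[i + 1], "/", bc[i + 1], bc[i])
    v <- params@stacks[key]
    if (is.na(v))
      v <- params@stacks[paste0(bc[i + 1], bc[i], "/", tc[i], tc[i + 1])]
    g <- g + v
  }
  for (e in c(1L, length(tc)))
    if (paste0(tc[e], bc[e]) %in% c("AU", "UA", "GU", "UG"))
      g <- g + params@terminalAU
  if (identical(tc, rev(bc))) g <- g + params@symmetry
  unname(g * 4.184)
}

randomDuplex <- function(n) {
  pairs <- sample(ALL_PAIRS, n, replace = TRUE)
  list(top = paste(substr(pairs, 1, 1), collapse = ""),
       bottom = paste(substr(pairs, 2, 2), collapse = ""))
}

test_that("the printed P1 strands pair into 9 bp with one wobble", {
  d <- parseDuplex("CGCUUCAUA", "GUGAAGUAU")
  expect_identical(countPairs(d), 9L)
  expect_identical(which(pairTypes(d) == "wobble"), 2L)
  ext <- parseDuplex("CGCUUCAUAA", "GUGAAGUAUU")
  expect_identical(countPairs(ext), 10L)
})

test_that("duplex parsing validates alphabet, length and pairing", {
  expect_identical(countPairs(parseDuplex("GC", "CG")), 2L)
  expect_error(parseDuplex("AA", "AA"), "position 1")
  expect_error(parseDuplex("GCA", "CGG"), "position 3")
  expect_error(parseDuplex("GC", "CGA"), "equal length")
  expect_error(parseDuplex("GX", "CG"), "non-RNA")
  expect_warning(d <- parseDuplex("GCAT", "CGUA"), "T converted to U")
  expect_identical(as.character(d@top), "GCAU")
})

test_that("duplex free energy matches frozen hand-evaluated sums", {
  p99 <- nnParameters("turner1999")
  p04 <- nnParameters("turner2004")
  # GC/CG: initiation + stack(GC/GC), no terminal penalties; the dimer is
  # self-complementary (both strands read 5'-GC-3'), so the symmetry
  # correction applies
  expect_equal(as.numeric(duplexDeltaG(parseDuplex("GC", "CG"), p99)),
               (4.10 - 3.40 + 0.43) * 4.184, tolerance = 1e-9)
  expect_equal(as.numeric(duplexDeltaG(parseDuplex("GC", "CG"), p04)),
               (4.09 - 3.42 + 0.43) * 4.184, tolerance = 1e-9)
  # GGC/CCG is not self-complementary: no symmetry term
  expect_equal(as.numeric(duplexDeltaG(parseDuplex("GGC", "CCG"), p99)),
               (4.10 - 3.30 - 3.40) * 4.184, tolerance = 1e-9)
  # AU/UA is self-complementary with two terminal AU penalties
  expect_equal(as.numeric(duplexDeltaG(parseDuplex("AU", "UA"), p99)),
               (4.10 - 1.10 + 2 * 0.50 + 0.43) * 4.184, tolerance = 1e-9)
  # GGCC/CCGG: self-complementary tetramer
  expect_equal(as.numeric(duplexDeltaG(parseDuplex("GGCC", "CCGG"), p99)),
               (4.10 - 3.30 - 3.40 - 3.30 + 0.43) * 4.184, tolerance = 1e-9)
})

test_that("nearest-neighbor sum agrees with brute-force enumeration", {
  p <- nnParameters("turner2004")
  set.seed(42)
  for (i in 1:25) {
    d <- randomDuplex(sample(2:8, 1))
    expect_equal(as.numeric(duplexDeltaG(parseDuplex(d$top, d$bottom), p)),
                 nnBruteForce(d$top, d$bottom, p), tolerance = 1e-9)
  }
})

test_that("duplex energy is invariant under end-for-end reversal", {
  p <- nnParameters()
  rev1 <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  set.seed(7)
  for (i in 1:10) {
    d <- randomDuplex(sample(3:9, 1))
    g1 <- duplexDeltaG(parseDuplex(d$top, d$bottom), p)
    g2 <- duplexDeltaG(parseDuplex(rev1(d$bottom), rev1(d$top)), p)
    expect_equal(as.numeric(g1), as.numeric(g2), tolerance = 1e-9)
  }
})

test_that("helix-extension difference cancels initiation exactly", {
  ext <- parseDuplex("CGCUUCAUAA", "GUGAAGUAUU")
  ref <- parseDuplex("CGCUUCAUA", "GUGAAGUAU")
  p <- nnParameters()
  p2 <- p; p2@initiation <- p@initiation + 5
  expect_equal(as.numeric(deltaDeltaG(ext, ref, p)),
               as.numeric(deltaDeltaG(ext, ref, p2)), tolerance = 1e-12)
  expect_equal(as.numeric(deltaDeltaG(ref, ref, p)), 0)
})

test_that("appending a terminal pair adds its stack plus penalty changes", {
  p <- nnParameters("turner2004")
  ref <- parseDuplex("GGGC", "CCCG")
  ext <- parseDuplex("GGGCA", "CCCGU")   # append terminal A.U
  # added 5'CA/3'GU stack plus one new terminal AU penalty (GC end before)
  expected <- (p@stacks[["CA/UG"]] + p@terminalAU) * 4.184
  expect_equal(as.numeric(deltaDeltaG(ext, ref, p)), expected,
               tolerance = 1e-9)
})

test_that("both embedded parameter sets reproduce the helix-extension ddG", {
  ext <- parseDuplex("CGCUUCAUAA", "GUGAAGUAUU")
  ref <- parseDuplex("CGCUUCAUA", "GUGAAGUAU")
  # the added AA/UU stack with terminal-AU penalties cancelling
  d99 <- deltaDeltaG(ext, ref, nnParameters("turner1999"))
  d04 <- deltaDeltaG(ext, ref, nnParameters("turner2004"))
  expect_equal(as.numeric(d99), -0.90 * 4.184, tolerance = 1e-9)
  expect_equal(as.numeric(d04), -0.93 * 4.184, tolerance = 1e-9)
  expect_identical(attr(d99, "parameterSet"), "turner1999")
})

test_that("a missing table entry names the offending step", {
  p <- nnParameters()
  p@stacks <- p@stacks[setdiff(names(p@stacks), c("GC/GC"))]
  expect_error(duplexDeltaG(parseDuplex("GC", "CG"), p), "GC/GC")
})
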