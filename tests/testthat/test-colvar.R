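test_that("COLVAR files round-trip an ensemble", {
  land <- templateLandscape()
  p <- fastProtocol(32)
  ens <- simulateEnsemble(land, p, 3, baseSeed = 9)
  dir <- withr::local_tempdir()
  paths <- writeColvar(ens, dir)
  expect_length(paths, 3L)
  back <- ensembleFromColvar(paths, p)
  expect_equal(positions(back), positions(ens), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(works(back), works(ens), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_identical(as.integer(hbonds(back)), as.integer(hbonds(ens)))
  expect_identical(SummarizedExperiment::colData(back)$seed,
                   SummarizedExperiment::colData(ens)$seed)
})

test_that("columns are mapped by header name, not position", {
  f <- withr::local_tempfile(fileext = ".colvar")
  writeLines(c("#! FIELDS lambda nhb time work position",
               "0.1 2 0.0 0.0 0.101",
               "0.1 1 1.0 0.5 0.150"), f)
  tr <- readColvar(f)
  expect_equal(tr$time, c(0, 1))
  expect_equal(tr$position, c(0.101, 0.150))
  expect_equal(tr$lambda, c(0.1, 0.1))
  expect_equal(tr$work, c(0, 0.5))
})

test_that("malformed COLVAR input is a format error with a location", {
  f <- withr::local_tempfile(fileext = ".colvar")
  writeLines(c("0.0 0.1", "0.1 0.2"), f)
  expect_error(readColvar(f), "line 1")

  writeLines(c("#! FIELDS time position lambda",
               "0.0 0.1 0.0",
               "0.1 0.2"), f)
  expect_error(readColvar(f), "line 3")

  writeLines(c("#! FIELDS time position lambda",
               "0.0 0.1 abc"), f)
  expect_error(readColvar(f), "non-numeric")

  writeLines(c("#! FIELDS time position", "0.0 0.1"), f)
  expect_error(readColvar(f), "lambda")
})

test_that("a missing work column is recomputed from positions", {
  f <- withr::local_tempfile(fileext = ".colvar")
  lam <- seq(0, 0.02, by = 0.01)
  q <- c(0.001, 0.009, 0.021)
  writeLines(c("#! FIELDS time position lambda nhb",
               sprintf("%g %g %g 2", c(0, 0.01, 0.02), q, lam)), f)
  ens <- ensembleFromColvar(f, PullingProtocol(springConstant = 100,
                                               velocity = 1, timeStep = 0.01,
                                               lambda1 = 0.02))
  expect_equal(as.numeric(works(ens)), accumulateWork(q, lam, 100),
               tolerance = 1e-12)
})

test_that("mismatched replica grids are rejected", {
  f1 <- withr::local_tempfile(fileext = ".colvar")
  f2 <- withr::local_tempfile(fileext = ".colvar")
  writeLines(c("#! FIELDS time position lambda work nhb",
               "0 0.0 0 0 2", "1 0.1 0.1 1 1"), f1)
  writeLines(c("#! FIELDS time position lambda work nhb",
               "0 0.0 0 0 2", "2 0.1 0.1 1 1"), f2)
  p <- PullingProtocol(velocity = 0.1, timeStep = 1, lambda1 = 0.1)
  expect_error(ensembleFromColvar(c(f1, f2), p), "share the time grid")
})

test_that("run configuration parses sections, vectors and flags", {
  cfg <- readRunConfig()
  expect_s3_class(cfg, "steeredFE_config")
  expect_identical(cfg$landscape$bounds, c(-0.15, 0.55))
  expect_identical(cfg$landscape$thresholds, c(0.12, 0.25))
  expect_identical(cfg$experiment$n_replicas, 512)
  expect_identical(cfg$experiment$write_colvar, FALSE)
  expect_identical(cfg$bootstrap$n_resamples, 200)
  land <- configLandscape(cfg)
  expect_s4_class(land, "ToyLandscape")
  proto <- configProtocol(cfg)
  expect_equal(proto@velocity, 1.75e-4 / 8)
  expect_identical(nSteps(proto), 1600000L)
})

test_that("incomplete configurations are rejected", {
  f <- withr::local_tempfile(fileext = ".ini")
  writeLines(c("[landscape]", "bounds = 0 1"), f)
  expect_error(readRunConfig(f), "missing section")
  writeLines(c("[landscape]", "x = 1", "[protocol]", "x = 1",
               "[analysis]", "x = 1", "[bootstrap]", "seed = 1",
               "[experiment]", "seed_apo = 1"), f)
  expect_error(readRunConfig(f), "seed_holo")
  writeLines("key = 1", f)
  expect_error(readRunConfig(f), "line 1")
})
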