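## small-scale configuration for fast end-to-end runs
smallConfig <- function(targetApo = -1.5, targetHolo = 1.0, n = 24,
                        B = 30) {
  cfg <- readRunConfig()
  cfg$protocol$velocity <- 1.75e-4 * 16     # fast pulling
  cfg$protocol$record_every <- 125
  cfg$experiment$n_replicas <- n
  cfg$experiment$target_apo <- targetApo
  cfg$experiment$target_holo <- targetHolo
  cfg$bootstrap$n_resamples <- B
  cfg
}

test_that("identical system definitions give a ddF compatible with zero", {
  cfg <- smallConfig(targetApo = -0.5, targetHolo = -0.5, n = 32)
  res <- runExperiment(cfg)
  expect_identical(dfValue(res$ddf),
                   dfValue(res$apo) - dfValue(res$holo))
  expect_lt(abs(dfValue(res$ddf)), 3 * dfSe(res$ddf))
})

test_that("rerunning a configuration reproduces the summary byte for byte", {
  cfg <- smallConfig(n = 16, B = 20)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  runExperiment(cfg, outDir = d1)
  runExperiment(cfg, outDir = d2)
  for (f in c("summary.tsv", "profile_apo.tsv", "profile_holo.tsv")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  expect_true(file.exists(file.path(d1, "run.log")))
  smry <- readLines(file.path(d1, "summary.tsv"))
  expect_true(any(grepl("^ddF\t", smry)))
})

test_that("experiment results carry calibrated landscapes and reports", {
  cfg <- smallConfig(n = 16, B = 20)
  res <- runExperiment(cfg)
  expect_lt(abs(quadratureDeltaF(res$landscapes$apo) + 1.5), 1e-3)
  expect_lt(abs(quadratureDeltaF(res$landscapes$holo) - 1.0), 1e-3)
  expect_named(res$reports, c("apo", "holo"))
  expect_type(res$reports$apo$converged, "logical")
})

test_that("stage errors are labeled with the failing stage", {
  cfg <- smallConfig()
  cfg$experiment$target_apo <- -80    # outside the calibration bracket
  expect_error(runExperiment(cfg), "calibrate_apo")
})

test_that("the CLI maps subcommands onto package operations", {
  expect_identical(cliMain(character()), 2L)
  expect_identical(suppressMessages(cliMain("frobnicate")), 2L)
  expect_identical(suppressMessages(cliMain(c("nn-ddg", "--bogus", "x"))),
                   2L)

  out <- capture.output(status <- cliMain(c(
    "nn-ddg", "--top", "CGCUUCAUAA", "--bottom-3to5", "GUGAAGUAUU",
    "--ref-top", "CGCUUCAUA", "--ref-bottom-3to5", "GUGAAGUAU")))
  expect_identical(status, 0L)
  expect_match(out, "-3.8 kJ/mol", fixed = TRUE)
  expect_match(out, "turner1999")

  out2 <- capture.output(status2 <- cliMain(c(
    "oracle", "--config", defaultConfigPath(), "--system", "apo")))
  expect_identical(status2, 0L)
  expect_match(out2, "-2.5")

  out3 <- capture.output(status3 <- cliMain("--version"))
  expect_identical(status3, 0L)
  expect_match(out3, "turner1999")

  # runtime errors exit 1 with a one-line diagnostic
  expect_identical(
    suppressMessages(cliMain(c("oracle", "--config", "/nonexistent.ini",
                               "--system", "apo"))), 1L)
})

test_that("simulate/deltaf subcommands work over COLVAR files", {
  f <- withr::local_tempfile(fileext = ".ini")
  cfg <- readLines(defaultConfigPath())
  cfg <- sub("^velocity = .*", "velocity = 0.0028", cfg)
  cfg <- sub("^record_every = .*", "record_every = 125", cfg)
  cfg <- sub("^n_replicas = .*", "n_replicas = 12", cfg)
  writeLines(cfg, f)
  dir <- withr::local_tempdir()
  capture.output(status0 <- cliMain(c("simulate", "--config", f,
                                      "--system", "apo", "--out", dir)))
  expect_identical(status0, 0L)
  expect_length(list.files(dir, pattern = "\\.colvar$"), 12L)
  out <- capture.output(status <- cliMain(c("deltaf", "--colvar-dir", dir,
                                            "--config", f)))
  expect_identical(status, 0L)
  expect_match(paste(out, collapse = "\n"), "DeltaF \\(breaking\\)")
})
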