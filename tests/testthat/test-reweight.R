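test_that("single-slice reweighting reduces to umbrella unbiasing", {
  k <- 3.9e4
  set.seed(1)
  q <- 0.05 + rnorm(40, 0, 0.01)
  ens <- singleSliceEnsemble(q, lambda = 0.05, k = k)
  w <- as.numeric(weightMatrix(frameWeights(ens)))
  # direct histogram unbiasing oracle: w_i proportional to exp(+beta V_i)
  V <- 0.5 * k * (q - 0.05)^2
  ref <- exp(V / kT300); ref <- ref / sum(ref)
  expect_equal(w, ref, tolerance = 1e-10)
})

test_that("two frames with bias energies {0, kT log 2} get weights {1/3, 2/3}", {
  k <- 3.9e4
  q2 <- 0.05 + sqrt(2 * kT300 * log(2) / k)
  ens <- singleSliceEnsemble(c(0.05, q2), lambda = 0.05, k = k)
  w <- as.numeric(weightMatrix(frameWeights(ens)))
  expect_equal(w, c(1, 2) / 3, tolerance = 1e-10)
})

test_that("frame weights are a normalized distribution", {
  land <- templateLandscape()
  ens <- simulateEnsemble(land, fastProtocol(16), 32, baseSeed = 7)
  fw <- frameWeights(ens)
  expect_true(all(weightMatrix(fw) >= 0))
  expect_equal(sum(weightMatrix(fw)), 1, tolerance = 1e-12)
  expect_equal(sliceFreeEnergies(fw)[1], 0, tolerance = 1e-12)
})

test_that("shifting all works is a gauge: weights unchanged, profile shifted", {
  land <- templateLandscape()
  ens <- simulateEnsemble(land, fastProtocol(16), 16, baseSeed = 13)
  W <- works(ens); q <- positions(ens); lam <- lambdaSchedule(ens)
  shift <- 7.3
  a <- steeredFE:::.computeLogWeights(W, q, lam, 3.9e4, kT300, 1L)
  b <- steeredFE:::.computeLogWeights(W + shift, q, lam, 3.9e4, kT300, 1L)
  expect_equal(b$sliceFE, a$sliceFE + shift, tolerance = 1e-9)
  expect_equal(b$logw, a$logw, tolerance = 1e-9)
})

test_that("projection onto bins reproduces hand-computed differences", {
  k <- 3.9e4
  q2 <- 0.05 + sqrt(2 * kT300 * log(2) / k)
  # weights {1/3, 2/3} across two discrete bins -> dF = kT log 2
  ens <- singleSliceEnsemble(c(0.05, q2), lambda = 0.05, k = k)
  fw <- frameWeights(ens)
  prof <- projectFreeEnergy(fw, c(0, 1), binning = "discrete")
  expect_equal(feValues(prof), c(kT300 * log(2), 0), tolerance = 1e-10)

  # equal weights -> zero difference
  ens2 <- singleSliceEnsemble(c(0.04, 0.06), lambda = 0.05, k = k)
  prof2 <- projectFreeEnergy(frameWeights(ens2), c(0, 1), "discrete")
  expect_equal(feValues(prof2), c(0, 0), tolerance = 1e-10)

  # empty interior bins are NA, not zero
  prof3 <- projectFreeEnergy(frameWeights(ens2), c(0.04, 0.06),
                             binning = c(0.03, 0.045, 0.055, 0.07))
  expect_true(is.na(feValues(prof3)[2]))
})

test_that("projected position profile matches bin-wise quadrature on a slow pull", {
  land <- calibrateDepth(templateLandscape(), -2.5)
  p <- defaultProtocol(slowdown = 4)
  ens <- simulateEnsemble(land, p, 96, baseSeed = 19)
  fw <- frameWeights(ens)
  edges <- seq(0.0, 0.36, by = 0.03)
  prof <- projectFreeEnergy(fw, positions(ens), binning = edges)
  # oracle: -kT log integral_bin exp(-beta U), same anchoring
  wm <- steeredFE:::.wellsMatrix(land)
  zb <- vapply(seq_len(length(edges) - 1L), function(b)
    integrate(function(x) exp(-steeredFE:::cpp_potential(wm, x) / kT300),
              edges[b], edges[b + 1L], rel.tol = 1e-10)$value, 0.0)
  ref <- -kT300 * log(zb); ref <- ref - min(ref)
  ok <- is.finite(feValues(prof))
  expect_true(all(abs(feValues(prof)[ok] - ref[ok]) < 0.3))
})

test_that("state free-energy difference matches hand-computed weight ratios", {
  k <- 3.9e4
  q2 <- 0.05 + sqrt(2 * kT300 * log(2) / k)
  # bound weight 2/3, unbound 1/3: breaking dF = +kT log 2
  # (the off-center frame carries weight 2/3 and is labeled bound)
  ens <- singleSliceEnsemble(c(0.05, q2), lambda = 0.05, k = k,
                             nhb = c(0L, 1L))
  fw <- frameWeights(ens)
  df <- stateDeltaF(fw, hbonds(ens))
  expect_equal(dfValue(df), -kT300 * log((1 / 3) / (2 / 3)),
               tolerance = 1e-10)
  # formation is the exact negative
  expect_identical(dfValue(stateDeltaF(fw, hbonds(ens), "formation")),
                   -dfValue(df))
  # equal weight in both states: zero
  ens2 <- singleSliceEnsemble(c(0.04, 0.06), lambda = 0.05, k = k,
                              nhb = c(1L, 0L))
  expect_equal(dfValue(stateDeltaF(frameWeights(ens2), hbonds(ens2))), 0,
               tolerance = 1e-10)
})

test_that("an empty state is a named degenerate-partition error", {
  ens <- singleSliceEnsemble(c(0.04, 0.06), lambda = 0.05, nhb = c(2L, 1L))
  expect_error(stateDeltaF(frameWeights(ens), hbonds(ens)), "unbound")
  ens2 <- singleSliceEnsemble(c(0.04, 0.06), lambda = 0.05, nhb = c(0L, 0L))
  expect_error(stateDeltaF(frameWeights(ens2), hbonds(ens2)), "bound")
})

test_that("two-system difference and its quadrature-combined error", {
  mk <- function(v, se = NA_real_, dir = "breaking", temp = 300)
    new("DeltaFResult", value = v, direction = dir, se = se,
        nReplicas = 512L, temperature = temp, diagnostics = list(),
        resamples = numeric(), nFailed = NA_integer_, B = NA_integer_)
  dd <- deltaDeltaF(mk(-2.5, 1.4), mk(1.9, 1.7))
  expect_equal(dfValue(dd), -4.4)
  expect_equal(dfSe(dd), sqrt(1.4^2 + 1.7^2))   # ~2.2
  expect_equal(dfValue(deltaDeltaF(mk(1.1), mk(1.1))), 0)
  expect_error(deltaDeltaF(mk(1, dir = "breaking"),
                           mk(1, dir = "formation")), "direction")
  expect_error(deltaDeltaF(mk(1), mk(1, temp = 310)), "temperature")
})

test_that("weight-concentration diagnostics quantify outlier domination", {
  w <- matrix(rep(1 / 12, 12), 3)  # 4 trajectories, equal aggregate
  d <- weightConcentration(w)
  expect_equal(d$ess, 4)
  expect_equal(d$maxTrajFraction, 1 / 4)

  d2 <- suppressWarnings(weightConcentration(c(2 / 3, 1 / 3)))
  expect_equal(d2$ess, 1.8)

  expect_warning(d3 <- weightConcentration(c(0.9, 0.05, 0.05)),
                 "outlier-dominated")
  expect_equal(d3$maxTrajFraction, 0.9)
  expect_equal(suppressWarnings(weightConcentration(c(0, 1)))$ess, 1)
})
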