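test_that("noiseless exponential curves are fit exactly", {
  t <- seq(0, 216, by = 24)
  fit <- fitExponentialRate(t, 100 * exp(0.05 * t))
  expect_equal(fit$mu, 1.2, tolerance = 1e-10)  # 0.05/h = 1.2/day
  expect_false(fit$noGrowth)
  expect_gte(fit$r2, 0.95)
})

test_that("flat or declining series flag no growth instead of erroring", {
  t <- seq(0, 216, by = 24)
  flat <- fitExponentialRate(t, rep(500, length(t)))
  expect_equal(flat$mu, 0)
  expect_true(flat$noGrowth)
  declining <- fitExponentialRate(t, 100 * exp(-0.02 * t))
  expect_equal(declining$mu, 0)
  expect_true(declining$noGrowth)
  expect_error(fitExponentialRate(t[1:3], c(1, 2, 3)), class = "dataError")
  expect_error(fitExponentialRate(t, c(rep(1, 9), 0)), class = "dataError")
})

test_that("the fitted rate is invariant to fluorescence rescaling", {
  set.seed(1)
  t <- seq(0, 216, by = 24)
  y <- 100 * exp(0.03 * t) * exp(rnorm(length(t), 0, 0.05))
  f1 <- fitExponentialRate(t, y)
  f2 <- fitExponentialRate(t, 1000 * y)
  expect_equal(f1$mu, f2$mu, tolerance = 1e-12)
  expect_equal(f1$window, f2$window)
})

test_that("rates are recovered within 5 percent at 5 percent noise", {
  spec <- growthCurveSpec(profiles = list(ONE = rep(0.8, 6)),
                          noiseSigma = 0.05, replicates = 4, seed = 42)
  sim <- simulateGrowthCurves(spec)
  fits <- vapply(split(sim$data, list(sim$data$salinity, sim$data$replicate)),
                 function(d) fitExponentialRate(d$time_h, d$fluorescence)$mu,
                 numeric(1))
  expect_lt(abs(stats::median(fits) - 0.8) / 0.8, 0.05)
})

test_that("sensitivity is 100 for the reference and scales linearly", {
  rates <- rbind(
    data.frame(strain = "REF", salinity = c(0.2, 0.6, 1.8, 2.5, 3.3),
               mu = c(1.0, 0.9, 0.3, 0.2, 0.2)),
    data.frame(strain = "HALF", salinity = c(0.2, 0.6, 1.8, 2.5, 3.3),
               mu = c(0.8, 0.7, 0.5, 0.4, 0.4)),
    data.frame(strain = "FLAT", salinity = c(0.2, 0.6, 1.8, 2.5, 3.3),
               mu = rep(0.6, 5)))
  sens <- salinitySensitivity(rates, "REF")
  expect_equal(sens$sensitivity[sens$strain == "REF"], 100)
  # REF decline 1.0 - 0.2 = 0.8; HALF decline 0.8 - 0.4 = 0.4
  expect_equal(sens$sensitivity[sens$strain == "HALF"], 50)
  expect_equal(sens$sensitivity[sens$strain == "FLAT"], 0)

  # common rescaling of all rates leaves sensitivities unchanged
  rates2 <- rates; rates2$mu <- rates2$mu * 3.7
  expect_equal(salinitySensitivity(rates2, "REF")$sensitivity,
               sens$sensitivity)

  flatAll <- rates; flatAll$mu <- 1
  expect_error(salinitySensitivity(flatAll, "REF"),
               class = "undefinedSensitivityError")
  expect_error(salinitySensitivity(rates, "NOPE"),
               class = "crossReferenceError")
})

test_that("sensitivity ranking matches the planted ranking at zero noise", {
  spec <- growthCurveSpec(noiseSigma = 0, seed = 1)
  sim <- simulateGrowthCurves(spec)
  rates <- growthRateTable(sim$data)
  sens <- salinitySensitivity(rates, sim$truth$reference)
  truth <- sim$truth$sensitivity
  got <- sens$sensitivity[match(truth$strain, sens$strain)]
  expect_equal(cor(got, truth$sensitivity, method = "spearman"), 1)
  expect_equal(got, truth$sensitivity, tolerance = 1e-6)
})

test_that("response classes follow the configurable cutoffs", {
  expect_equal(classifySalinityResponse(c(100, 50, 10)),
               c("sensitive", "intermediately_sensitive", "robust"))
  expect_equal(classifySalinityResponse(33), "intermediately_sensitive")
  expect_equal(classifySalinityResponse(50, cutoffs = c(60, 80)), "robust")
  expect_error(classifySalinityResponse(50, cutoffs = c(80, 60)),
               class = "usageError")
  expect_error(classifySalinityResponse(-1), class = "usageError")
})

test_that("cell shape summaries use 1.5-IQR whiskers", {
  s <- cellShapeSummary(rep(10, 8), rep(5, 8))
  ratio <- s[s$variable == "ratio", ]
  expect_equal(ratio$median, 2)
  expect_equal(ratio$q1, 2)
  expect_equal(ratio$upper_whisker, 2)

  lengths <- c(9.8, 10, 10.1, 10.2, 10.3, 10.1, 30)   # one outlier
  widths <- rep(5, 7)
  s2 <- cellShapeSummary(lengths, widths)
  len <- s2[s2$variable == "length", ]
  expect_lt(len$upper_whisker, 30)
  expect_equal(len$n_outliers, 1L)

  expect_error(cellShapeSummary(rep(10, 4), rep(5, 4)), class = "dataError")
  expect_error(cellShapeSummary(c(10, 10, 10, 10, -1), rep(5, 5)),
               class = "dataError")
})
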