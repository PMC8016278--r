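# build a lattice-statistics object from known mean-field coefficients
syntheticStats <- function(true, kUB = 5e-4, kBU = 0.1,
                           PGrid = c(36, 64, 100, 144, 196)) {
  rates <- do.call(rbind, lapply(PGrid, function(P) {
    B <- 1:(P - 1)
    lam <- true["mLambda"] * P + true["cLambda"]
    bet <- true["mBeta"] * P + true["cBeta"]
    m <- true["aM"] / (P + true["bM"])
    data.frame(P = P, B = B, n = 200,
               kUBMean = kUB * (m * B^0.8 + 1),
               kBUMean = kBU * lam / (bet + B - 0.5))
  }))
  structure(list(rates = rates, occupancy = NULL, kUB = kUB, kBU = kBU,
                 alpha = 16), class = "latticeStats")
}

test_that("mean-field coefficients are recovered from noise-free statistics", {
  true <- c(mBeta = 0.18, cBeta = 6.9, mLambda = 0.21, cLambda = 7.3,
            aM = 27.8, bM = 23.2)
  fit <- fitMeanField(syntheticStats(true), coop = coopParams())
  expect_equal(coef(fit), true, tolerance = 0.01)
})

test_that("the binding-rate ratio is exactly 1 at an empty PSD", {
  fit <- defaultMeanFieldFit()
  r <- meanFieldRates(fit, 0, 70)
  expect_equal(r$gUB, 1)
})

test_that("too few lattice sizes or occupancy levels abort the fit", {
  true <- c(mBeta = 0.18, cBeta = 6.9, mLambda = 0.21, cLambda = 7.3,
            aM = 27.8, bM = 23.2)
  expect_error(fitMeanField(syntheticStats(true, PGrid = c(36, 64, 100))),
               "at least 4")
  st <- syntheticStats(true)
  st$rates <- st$rates[st$rates$B <= 3, ]
  expect_error(fitMeanField(st), "too few")
})

test_that("the cooperative closure reduces to the basic one without cooperativity", {
  p <- traffickingParams()
  # lambda/(beta + B - 0.5) = 1 at B* and m = 0
  flat <- new("MeanFieldFit", mBeta = 0, cBeta = 10, mLambda = 0,
              cLambda = 10 + p$BStar - 0.5, aM = 0, bM = 1,
              perP = data.frame())
  expect_equal(coopKUB0(p, flat), deriveKUB0(p), tolerance = 1e-12)
})

test_that("the calibrated cooperative rate closes the fixed point", {
  p <- traffickingParams()
  fit <- defaultMeanFieldFit()
  kc <- coopKUB0(p, fit)
  # reference value: an order of magnitude below the non-cooperative rate
  expect_equal(kc, 5e-4, tolerance = 0.3)
  conc <- p$UStar / p$ASpine0
  r <- meanFieldRates(fit, p$BStar, p$P)
  drift <- kc * r$gUB * (p$P - p$BStar) * conc - p$kBU * r$gBU * p$BStar
  expect_equal(drift, 0, tolerance = 1e-12)
  # and the simulated cooperative baseline sits at B* = 20
  tr <- simulateSpine("coop", "baseline", params = p, fit = fit, tEnd = 2000)
  expect_equal(attr(tr, "baseline")$B0, p$BStar, tolerance = 1e-6)
  expect_lt(max(abs(tr$B - p$BStar)) / p$BStar, 1e-6)
})

test_that("fixed-point curves: cooperative is steep and sigmoidal, basic shallow", {
  p <- traffickingParams()
  fit <- defaultMeanFieldFit()
  S <- seq(0, 40, by = 1)
  fpB <- fixedPointCurve("basic", p, fit, SExo = S)
  fpC <- fixedPointCurve("coop", p, fit, SExo = S)
  up <- function(fp) fp[fp$direction == "ascending", ]
  slope <- function(fp) max(abs(diff(up(fp)$BStar)))
  expect_gt(slope(fpC), 3 * slope(fpB))
  expect_true(all(diff(up(fpB)$BStar) >= -1e-9))  # basic monotone, shallow
  expect_true(all(up(fpB)$converged))
})

test_that("fixed points are confirmed by forward relaxation", {
  p <- traffickingParams()
  fit <- defaultMeanFieldFit()
  for (v in c("basic", "coop")) {
    fp <- fixedPointCurve(v, p, fit, SExo = p$SExo0)
    root <- fp$BStar[fp$direction == "ascending"]
    tr <- simulateSpine(v, "baseline", params = p, fit = fit, tEnd = 6000,
                        init = c(U = p$UStar, B = root * 1.25))
    expect_equal(tr$B[nrow(tr)], root, tolerance = 1e-4)
  }
})

test_that("the occupancy sigmoid sharpens with PSD size", {
  p <- traffickingParams()
  fit <- defaultMeanFieldFit()
  conc <- seq(4, 30, by = 0.25)
  maxSlope <- vapply(c(40, 200), function(P) {
    fp <- fixedPointCurve("coop", p, fit, conc = conc, P = P,
                          kUB0 = coopParams()@kUB)
    occ <- fp$occupancy[fp$direction == "ascending"]
    max(abs(diff(occ))) / 0.25
  }, numeric(1))
  expect_gt(maxSlope[2], maxSlope[1])
})

test_that("non-cooperative lattice statistics drive the fit to the flat limit", {
  set.seed(14)
  runs <- list()
  for (P in c(36, 64, 100, 144)) for (k in c(0.2, 0.5, 0.9, 1.3))
    runs[[paste(P, k)]] <- latticeRun(P = P, kIn = k,
                                      coop = coopParams(alpha = 0),
                                      tEnd = 1500, burnIn = 300)
  st <- suppressWarnings(latticeStatistics(runs, minCount = 10))
  fit <- fitMeanField(st, coop = coopParams(alpha = 0))
  # kUB ratio ~ 1 (m ~ 0) and kBU ratio ~ 1 across occupancies
  for (P in c(36, 144)) {
    r <- meanFieldRates(fit, c(2, P / 4, P / 2), P)
    expect_equal(r$gUB, rep(1, 3), tolerance = 0.05)
    expect_equal(r$gBU, rep(1, 3), tolerance = 0.15)
  }
})
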