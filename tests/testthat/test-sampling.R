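test_that("cost of trivially shifted curves equals two unit integrals", {
  t <- seq(0, 100, by = 1)
  ref <- data.frame(t = t, B = 20 + sin(t / 10))
  sim <- data.frame(t = t, B = ref$B + 1)
  # +1 receptor everywhere in both conditions: cost (1 + 1) = 2
  expect_equal(trajectoryCost(sim, sim, ref, ref), 2)
  expect_equal(trajectoryCost(ref, ref, ref, ref), 0)
})

test_that("trapezoidal cost matches a fine-grid Riemann oracle", {
  set.seed(2)
  t <- seq(0, 500, by = 2.5)
  base <- 20 + cumsum(rnorm(length(t), sd = 0.3))
  # keep the difference one-signed so the piecewise-linear integrand is
  # integrated exactly by both rules (they differ only in quadrature)
  r1 <- data.frame(t = t, B = base)
  s1 <- data.frame(t = t, B = base + runif(length(t), 0.5, 1.5))
  r2 <- data.frame(t = t, B = rev(base))
  s2 <- data.frame(t = t, B = rev(base) - runif(length(t), 0.5, 1.5))
  got <- trajectoryCost(s1, s2, r1, r2)
  want <- oracleCost(s1, s2, r1, r2, T = 500, n = 4e5)
  expect_equal(got, want, tolerance = 1e-5)
})

test_that("cost is stable under grid refinement", {
  rp <- referenceParams("ltp")
  mk <- function(by) {
    rc <- referenceCurve(rp, tEnd = 1800, by = by)
    data.frame(t = rc$t, B = toReceptorCounts(rc$pct, 20))
  }
  sim <- mk(2); sim$B <- sim$B * 1.07
  c1 <- trajectoryCost(sim, sim, mk(2), mk(2))
  sim2 <- mk(1); sim2$B <- sim2$B * 1.07
  c2 <- trajectoryCost(sim2, sim2, mk(1), mk(1))
  expect_lt(abs(c1 - c2) / c2, 1e-3)
})

test_that("mismatched grids are resampled with a message", {
  t1 <- seq(0, 100, by = 1); t2 <- seq(0, 100, by = 2)
  ref <- data.frame(t = t2, B = rep(20, length(t2)))
  sim <- data.frame(t = t1, B = rep(21, length(t1)))
  expect_message(v <- trajectoryCost(sim, sim, ref, ref), "resampling")
  expect_equal(v, 2)
})

test_that("sampling ranges differ only in the cooperative binding amplitude", {
  rb <- sampleRanges("basic"); rc <- sampleRanges("coop")
  expect_equal(rb$high[rb$name == "AUB"], 50)
  expect_equal(rc$high[rc$name == "AUB"], 20)
  expect_equal(rb[rb$name != "AUB", ], rc[rc$name != "AUB", ])
})

test_that("collapsed ranges reproduce the direct simulation cost", {
  ranges <- data.frame(name = c("kExo0", "tauExo2", "AExo", "kBU",
                                "tauUB2", "AUB"),
                       low = c(0.0018, 60, 5, 0.1, 60, 30),
                       high = c(0.0018, 60, 5, 0.1, 60, 30))
  set.seed(6)
  res <- runSampling("basic", ranges = ranges, nTrials = 2, topFrac = 0.5,
                     tEnd = 1800, outDt = 10)
  # direct simulation with the same point values
  p <- traffickingParams()
  pls <- list(exo = pulseSpec(A = 5, tau1 = 25, tau2 = 60),
              ub = pulseSpec(A = 30, tau1 = 5, tau2 = 60))
  s1 <- simulateSpine("basic", "ltp", params = p, pulses = pls,
                      tEnd = 1800, outDt = 10)
  s2 <- simulateSpine("basic", "ltp_noexo", params = p, pulses = pls,
                      tEnd = 1800, outDt = 10)
  rcL <- referenceCurve(referenceParams("ltp"), tEnd = 1800, by = 10)
  rcN <- referenceCurve(referenceParams("noexo"), tEnd = 1800, by = 10)
  want <- trajectoryCost(
    s1, s2,
    data.frame(t = rcL$t, B = toReceptorCounts(rcL$pct, 20)),
    data.frame(t = rcN$t, B = toReceptorCounts(rcN$pct, 20)))
  expect_equal(res$trials$cost, rep(want, 2), tolerance = 1e-10)
})

test_that("curves planted with known parameters are recovered as best match", {
  p <- traffickingParams()
  truth <- list(AExo = 5, tauExo2 = 60, AUB = 30, tauUB2 = 60)
  pls <- list(exo = pulseSpec(A = truth$AExo, tau1 = 25,
                              tau2 = truth$tauExo2),
              ub = pulseSpec(A = truth$AUB, tau1 = 5, tau2 = truth$tauUB2))
  ref1 <- simulateSpine("basic", "ltp", params = p, pulses = pls,
                        tEnd = 1800, outDt = 10)
  ref2 <- simulateSpine("basic", "ltp_noexo", params = p, pulses = pls,
                        tEnd = 1800, outDt = 10)
  refL <- data.frame(t = ref1$t, B = ref1$B)
  refN <- data.frame(t = ref2$t, B = ref2$B)
  costOf <- function(AExo, tauExo2, AUB, tauUB2) {
    pp <- list(exo = pulseSpec(A = AExo, tau1 = 25, tau2 = tauExo2),
               ub = pulseSpec(A = AUB, tau1 = 5, tau2 = tauUB2))
    s1 <- simulateSpine("basic", "ltp", params = p, pulses = pp,
                        tEnd = 1800, outDt = 10)
    s2 <- simulateSpine("basic", "ltp_noexo", params = p, pulses = pp,
                        tEnd = 1800, outDt = 10)
    trajectoryCost(s1, s2, refL, refN)
  }
  cTrue <- costOf(truth$AExo, truth$tauExo2, truth$AUB, truth$tauUB2)
  expect_equal(cTrue, 0, tolerance = 1e-10)
  perturbed <- list(c(7, 60, 30, 60), c(5, 120, 30, 60),
                    c(5, 60, 40, 60), c(5, 60, 30, 120))
  for (pt in perturbed)
    expect_gt(costOf(pt[1], pt[2], pt[3], pt[4]), cTrue + 0.01)
})

test_that("the retained top set size follows the requested fraction", {
  # 0.5% of 2000 trials keeps exactly 10
  expect_equal(floor(2000 * 0.005), 10)
  set.seed(10)
  res <- runSampling("basic", nTrials = 40, topFrac = 0.1, tEnd = 900,
                     outDt = 30)
  expect_lte(nrow(res$top), 4)
  expect_equal(res$top$cost, sort(res$top$cost))
  expect_true(all(res$top$cost <= min(res$trials$cost[
    !res$trials$trial %in% res$top$trial], Inf)))
})

test_that("sampling is reproducible under a fixed seed", {
  set.seed(33)
  r1 <- runSampling("basic", nTrials = 12, topFrac = 0.25, tEnd = 600,
                    outDt = 30)
  set.seed(33)
  r2 <- runSampling("basic", nTrials = 12, topFrac = 0.25, tEnd = 600,
                    outDt = 30)
  expect_identical(r1$trials, r2$trials)
  expect_identical(r1$summaries$B, r2$summaries$B)
})

test_that("trials with infeasible derived rates are rejected and counted", {
  # a spine with extra diffusive efflux: without exocytosis the influx
  # cannot hold U*, so near-zero kExo0 draws make kEndo negative
  p <- traffickingParams(kOut = 0.0185)
  ranges <- sampleRanges("basic")
  ranges$high[ranges$name == "kExo0"] <- 1e-6
  set.seed(3)
  res <- runSampling("basic", ranges = ranges, params = p, nTrials = 5,
                     topFrac = 0.4, tEnd = 300, outDt = 30)
  expect_equal(res$nRejected, 5)
  expect_equal(nrow(res$trials), 0)
})

test_that("overly stiff draws are flagged as failed, not fatal", {
  ranges <- sampleRanges("basic")
  ranges$low[ranges$name == "kBU"] <- 1      # maximal unbinding and
  ranges$low[ranges$name == "AUB"] <- 50     # binding amplification
  ranges$low[ranges$name == "tauUB2"] <- 8 * 60
  set.seed(13)
  res <- runSampling("basic", ranges = ranges, nTrials = 2, topFrac = 0.5,
                     tEnd = 300, outDt = 30)
  expect_equal(res$nFailed + nrow(res$trials), 2)
})
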