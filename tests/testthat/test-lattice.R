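test_that("slot rates follow the neighbour fraction exactly", {
  cp <- coopParams()
  # hand-built configuration: 2x2 occupied block in the corner of a 5x5 grid
  M <- matrix(0L, 5, 5); M[1:2, 1:2] <- 1L
  sr <- slotRates(M, cp)
  nb <- oracleNeighbours(M)
  expect_equal(sr$chi, nb / 8)
  # each occupied slot of the block has 3 occupied neighbours
  expect_equal(sr$kBUCoop[1, 1], cp$kBU * (1 - 3 / 8))
  # isolated empty slot far away: basal rates
  expect_equal(sr$kUBCoop[5, 5], cp$kUB)
  # empty slot fully surrounded: binding amplified 17-fold, alpha = 16
  M2 <- matrix(1L, 3, 3); M2[2, 2] <- 0L
  sr2 <- slotRates(M2, cp)
  expect_equal(sr2$kUBCoop[2, 2], cp$kUB * 17)
  expect_equal(sr2$kUBCoop[2, 2], 0.0085)
  # occupied slot fully surrounded never unbinds
  M3 <- matrix(1L, 3, 3)
  expect_equal(slotRates(M3, cp)$kBUCoop[2, 2], 0)
  # full-grid conditional mean matches the exhaustive combinatorial count
  expect_equal(mean(slotRates(M3, cp)$kBUCoop),
               cp$kBU * (1 - mean(oracleNeighbours(M3) / 8)))
})

test_that("a single bound receptor unbinds at the basal rate", {
  cp <- coopParams()
  M <- matrix(0L, 4, 4); M[2, 3] <- 1L
  sr <- slotRates(M, cp)
  expect_equal(sr$kBUCoop[2, 3], cp$kBU)
})

test_that("event bookkeeping balances the occupancy change exactly", {
  set.seed(21)
  r <- latticeRun(P = 64, kIn = 0.4, tEnd = 800, burnIn = 0)
  s <- r$series
  expect_equal(r$bindsTotal - r$unbindsTotal, s$B[nrow(s)] - s$B[1])
  expect_equal(sum(r$bindCount), r$bindsTotal)
  expect_equal(sum(r$unbindCount), r$unbindsTotal)
  # full start balances too
  r2 <- latticeRun(P = 36, kIn = 0.1, tEnd = 800, burnIn = 0, start = "full")
  s2 <- r2$series
  expect_equal(r2$bindsTotal - r2$unbindsTotal, s2$B[nrow(s2)] - s2$B[1])
})

test_that("an empty lattice with no receptor supply stays empty", {
  p <- traffickingParams(kExo0 = 0, kIn = 0, kEndo = 0.0021)
  set.seed(5)
  r <- latticeRun(P = 36, kIn = 0, params = p, tEnd = 500, burnIn = 0)
  expect_true(all(r$series$B == 0))
  expect_true(all(r$series$U == 0))
})

test_that("too-large step probabilities are rejected with advice", {
  set.seed(5)
  expect_error(
    latticeRun(P = 36, kIn = 0.4, coop = coopParams(dt = 20),
               clampU = TRUE, conc = 50, tEnd = 100, burnIn = 0),
    "reduce dt")
})

test_that("without cooperativity the occupancy is binomial", {
  set.seed(77)
  cp <- coopParams(alpha = 0)
  conc <- 200  # per-step bind probability 0.05 vs unbind 0.05
  r <- latticeRun(P = 64, kIn = 0, coop = cp, clampU = TRUE, conc = conc,
                  tEnd = 6000, burnIn = 500)
  q <- (cp$kUB * conc) / (cp$kUB * conc + cp$kBU)  # independent-slot occupancy
  expect_equal(r$Bbar, 64 * q, tolerance = 0.03)
  cvBinom <- sqrt((1 - q) / (64 * q))
  expect_equal(r$CV, cvBinom, tolerance = 0.15)
})

test_that("halving the step leaves the stationary occupancy unchanged", {
  set.seed(31)
  b1 <- replicate(6, latticeRun(P = 64, kIn = 0.6, coop = coopParams(dt = 0.4),
                                tEnd = 2500, burnIn = 1000)$Bbar)
  b2 <- replicate(6, latticeRun(P = 64, kIn = 0.6, coop = coopParams(dt = 0.2),
                                tEnd = 2500, burnIn = 1000)$Bbar)
  se <- sqrt(var(b1) / 6 + var(b2) / 6)
  expect_lt(abs(mean(b1) - mean(b2)), max(3 * se, 0.5))
})

test_that("conditional mean rates are monotone in the bound number", {
  set.seed(8)
  runs <- list()
  for (k in c(0.15, 0.3, 0.6, 1.0)) for (s in c("empty", "full"))
    runs[[paste(k, s)]] <- latticeRun(P = 64, kIn = k, tEnd = 3000,
                                      burnIn = 500, start = s)
  st <- suppressWarnings(latticeStatistics(runs, minCount = 30))
  d <- st$rates[st$rates$B > 0 & st$rates$B < 64, ]
  expect_gt(cor(d$B, d$kUBMean, method = "spearman"), 0.95)
  expect_lt(cor(d$B, d$kBUMean, method = "spearman"), -0.9)
})

test_that("cooperative occupancy fluctuations exceed the binomial level", {
  set.seed(12)
  r <- latticeRun(P = 64, kIn = 0.3, tEnd = 5000, burnIn = 1500)
  q <- r$Bbar / 64
  expect_gt(q, 0.1); expect_lt(q, 0.95)
  cvBinom <- sqrt((1 - q) / (64 * q))
  expect_gt(r$CV, cvBinom)
})

test_that("bound dwell times are strongly heterogeneous across the PSD", {
  set.seed(9)
  r <- latticeRun(P = 100, kIn = 0.8, tEnd = 3600, burnIn = 600)
  dw <- dwellTimes(r)
  dw <- dw[is.finite(dw)]
  expect_gt(length(dw), 50)
  # cluster cores hold receptors orders of magnitude longer than edges
  expect_gt(max(dw) / min(dw), 10)
})

test_that("lattice runs are reproducible under a fixed seed", {
  set.seed(123)
  r1 <- latticeRun(P = 36, kIn = 0.4, tEnd = 500, burnIn = 0)
  set.seed(123)
  r2 <- latticeRun(P = 36, kIn = 0.4, tEnd = 500, burnIn = 0)
  expect_identical(r1$series, r2$series)
  expect_identical(r1$boundTime, r2$boundTime)
})

test_that("P must be a perfect square", {
  expect_error(latticeRun(P = 70), "perfect square")
})

test_that("FRAP: recovery starts near zero and is slowed by cooperativity", {
  set.seed(42)
  fr <- simulateFRAP(P = 49, kIn = 0.2, trials = 12, bleachTime = 600,
                     tAfter = 240, coop = coopParams(dt = 0.25))
  expect_lt(fr$recovery[1], 0.05)
  expect_gt(fr$recovery[nrow(fr)], fr$recovery[1])

  # cooperative model: raising the mobile concentration slows recovery
  set.seed(42)
  lo <- simulateFRAP(P = 49, kIn = 0.2, trials = 12, bleachTime = 900,
                     tAfter = 240, coop = coopParams(dt = 0.25))
  hi <- simulateFRAP(P = 49, kIn = 0.65, trials = 12, bleachTime = 900,
                     tAfter = 240, coop = coopParams(dt = 0.25))
  iEnd <- nrow(lo)
  expect_gt(lo$recovery[iEnd], hi$recovery[iEnd] + 0.05)

  # ... but not in the non-cooperative control
  set.seed(42)
  cp0 <- coopParams(alpha = 0, kUB = 0.0036, dt = 0.25)
  lo0 <- simulateFRAP(P = 49, kIn = 0.2, trials = 12, bleachTime = 900,
                      tAfter = 240, coop = cp0)
  hi0 <- simulateFRAP(P = 49, kIn = 0.65, trials = 12, bleachTime = 900,
                      tAfter = 240, coop = cp0)
  expect_lt(abs(lo0$recovery[iEnd] - hi0$recovery[iEnd]), 0.1)
})
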