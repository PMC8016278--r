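test_that("spherical geometry links volume and area", {
  expect_equal(areaFromVolume(0.08), 0.898, tolerance = 1e-3)
  # unit-radius sphere: V = 4 pi / 3 gives A = 4 pi
  expect_equal(areaFromVolume(4 * pi / 3), 4 * pi, tolerance = 1e-12)
  # A ~ V^(2/3): eight-fold volume quadruples the area
  expect_equal(areaFromVolume(0.64), 4 * areaFromVolume(0.08))
  expect_equal(volumeFromArea(areaFromVolume(0.3)), 0.3)
  expect_error(areaFromVolume(0), "must be > 0")
  expect_error(areaFromVolume(-1), "must be > 0")
})

test_that("steady-state closures reproduce the reference spine rates", {
  p <- traffickingParams()
  # printed reference values, 2 significant figures
  expect_equal(p$kEndo, 0.0021, tolerance = 0.05)
  expect_equal(p$kUB0, 0.0036, tolerance = 0.05)
  expect_equal(100 * p$BStar / p$P, 28.57, tolerance = 1e-3)
  # balanced-diffusion corner: no exo/endo and influx matching efflux
  p0 <- traffickingParams(kExo0 = 0, kIn = 0.018 * 10 / areaFromVolume(0.08),
                          kOut = 0.018)
  expect_equal(p0$kEndo, 0, tolerance = 1e-12)
  # linearity of the binding-rate closure in kBU
  p2 <- traffickingParams(kBU = 0.2)
  expect_equal(p2$kUB0, 2 * traffickingParams()$kUB0)
  # BStar = 0 gives a zero binding rate
  expect_equal(traffickingParams(BStar = 0)$kUB0, 0)
  expect_error(traffickingParams(P = 10, BStar = 20), "P")
})

test_that("derived endocytosis rate agrees with a numerical root-solve", {
  set.seed(11)
  for (i in 1:10) {
    p <- traffickingParams(kExo0 = runif(1, 0.001, 0.01),
                           SExo0 = runif(1, 5, 30),
                           UStar = runif(1, 5, 20),
                           BStar = runif(1, 5, 30),
                           VSpine0 = runif(1, 0.03, 0.3))
    # independent oracle: solve dU/dt = 0 for kEndo at the fixed point
    f <- function(kE) {
      pp <- traffickingParams(kExo0 = p$kExo0, SExo0 = p$SExo0,
                              UStar = p$UStar, BStar = p$BStar,
                              VSpine0 = p$VSpine0, kEndo = kE)
      oracleFluxSum(pp$UStar, pp$BStar, pp)[["dU"]]
    }
    root <- uniroot(f, c(0, 1), tol = 1e-14)$root
    expect_equal(p$kEndo, root, tolerance = 1e-6)
  }
})

test_that("parameter inconsistency (influx too small) is rejected", {
  # with extra diffusive efflux and no exocytosis the target U* cannot
  # be sustained, so the endocytosis closure turns negative
  expect_error(traffickingParams(kExo0 = 0, kOut = 0.0185),
               "influx too small")
})

test_that("the closed parameter set is an exact fixed point", {
  p <- traffickingParams()
  d <- rhsBasic(p$UStar, p$BStar, p)
  expect_equal(unname(d), c(0, 0), tolerance = 1e-14)
  # and agrees with the independent flux-sum assembly at arbitrary states
  set.seed(4)
  for (i in 1:20) {
    U <- runif(1, 0, 40); B <- runif(1, 0, p$P)
    expect_equal(rhsBasic(U, B, p), oracleFluxSum(U, B, p),
                 tolerance = 1e-12)
  }
  # no unbinding flux from an empty PSD
  d0 <- rhsBasic(5, 0, p)
  expect_equal(d0[["dB"]], p$kUB0 * p$P * 5 / p$ASpine0)
})

test_that("slot scaling is linear in spine area", {
  expect_equal(scaleSlots(areaFromVolume(0.08)), 70)
  expect_equal(scaleSlots(2 * areaFromVolume(0.08)), 140)
  # composed with the sphere formula: 8x volume -> 4x slots
  expect_equal(scaleSlots(areaFromVolume(0.64)), 280)
})

test_that("steady-state bound pool increases weakly with influx", {
  p <- traffickingParams()
  kIns <- seq(0.05, 1, length.out = 12)
  conc <- (p$kExo0 * p$SExo0 + kIns) / (p$kEndo + p$kOut)
  B <- vapply(conc, function(cc) {
    fp <- fixedPointCurve("basic", params = p, conc = cc)
    fp$BStar[fp$direction == "ascending"]
  }, numeric(1))
  expect_true(all(diff(B) >= -1e-9))
})
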