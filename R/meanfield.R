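#' @rdname meanFieldRates
#' @export
lambdaAt <- function(fit, P) fit@mLambda * P + fit@cLambda

#' @rdname meanFieldRates
#' @export
betaAt <- function(fit, P) fit@mBeta * P + fit@cBeta

#' @rdname meanFieldRates
#' @export
mAt <- function(fit, P) fit@aM / (P + fit@bM)

#' Effective cooperative rate factors of the mean-field model
#'
#' Evaluates the occupancy-dependent multipliers that replace the
#' constant binding/unbinding rates in the ODE model:
#' `gUB = m(P) B^0.8 + 1` and `gBU = lambda(P)/(beta(P) + B - 0.5)`.
#' `lambdaAt()`, `betaAt()` and `mAt()` expose the fitted
#' lattice-size dependencies.
#'
#' @param fit a [MeanFieldFit-class]
#' @param B bound receptor number (vectorised)
#' @param P slot count (continuous)
#' @return list with components `gUB` and `gBU`
#' @export
meanFieldRates <- function(fit, B, P) {
  list(gUB = mAt(fit, P) * B^0.8 + 1,
       gBU = lambdaAt(fit, P) / (betaAt(fit, P) + B - 0.5))
}

#' Fit the mean-field reduction to lattice statistics
#'
#' Eliminates the spatial component of the cooperative lattice: for
#' each lattice size the conditional mean rates are fitted by
#' `kBUMean/kBU = lambda/(beta + B - 0.5)` (nonlinear least squares)
#' and `kUBMean/kUB = m B^0.8 + 1` (the exponent is fixed; m is the
#' single linear coefficient). The per-size coefficients are then
#' condensed into `beta(P)`, `lambda(P)` (linear) and
#' `m(P) = aM/(P + bM)` (fitted on the reciprocal scale).
#'
#' Weights are visit counts capped at `weightCap`, so heavily visited
#' near-saturation states do not dominate the mid-occupancy region
#' where the ODE models operate.
#'
#' @param stats a `latticeStats` object from [latticeStatistics()]
#' @param coop the [CoopParams-class] the runs used
#' @param weightCap cap on the per-B visit-count weights
#' @return a [MeanFieldFit-class]
#' @export
fitMeanField <- function(stats, coop = coopParams(), weightCap = 500) {
  rates <- stats$rates
  Ps <- sort(unique(rates$P))
  if (length(Ps) < 4)
    stop("need lattice statistics for at least 4 distinct P values")
  perP <- do.call(rbind, lapply(Ps, function(P) {
    d <- rates[rates$P == P & rates$B > 0 & rates$B < P, , drop = FALSE]
    if (nrow(d) < 8)
      stop(sprintf("too few occupied B levels at P = %d for the fit", P))
    w <- pmin(d$n, weightCap)
    yU <- d$kUBMean / coop@kUB
    yB <- d$kBUMean / coop@kBU
    m <- sum(w * (yU - 1) * d$B^0.8) / sum(w * d$B^1.6)
    sse <- function(lam, bet) sum(w * (yB - lam / (bet + d$B - 0.5))^2)
    co <- tryCatch({
      fb <- minpack.lm::nlsLM(yB ~ lam / (bet + B - 0.5),
                              data = data.frame(yB = yB, B = d$B),
                              start = list(lam = P / 4, bet = P / 4),
                              weights = w,
                              control = minpack.lm::nls.lm.control(maxiter = 200))
      stats::coef(fb)
    }, error = function(e) {
      # near-degenerate data (e.g. the non-cooperative control, where
      # the ratio is flat at 1): direct least squares on the log scale
      op <- stats::optim(c(log(P / 4), log(P / 4)),
                         function(th) sse(exp(th[1]), exp(th[2])))
      c(lam = exp(op$par[1]), bet = exp(op$par[2]))
    })
    data.frame(P = P, m = m, lambda = co[["lam"]], beta = co[["bet"]],
               rssUB = sum(w * (yU - (m * d$B^0.8 + 1))^2) / sum(w),
               rssBU = sse(co[["lam"]], co[["bet"]]) / sum(w))
  }))
  lb <- stats::lm(beta ~ P, data = perP)
  ll <- stats::lm(lambda ~ P, data = perP)
  li <- stats::lm(I(1 / m) ~ P, data = perP)  # 1/m = P/aM + bM/aM
  aM <- 1 / stats::coef(li)[["P"]]
  bM <- stats::coef(li)[["(Intercept)"]] * aM
  new("MeanFieldFit",
      mBeta = stats::coef(lb)[["P"]], cBeta = stats::coef(lb)[["(Intercept)"]],
      mLambda = stats::coef(ll)[["P"]],
      cLambda = stats::coef(ll)[["(Intercept)"]],
      aM = aM, bM = bM, perP = perP)
}

#' Calibrate the mean-field model from scratch
#'
#' Runs the stochastic lattice over a grid of lattice sizes and influx
#' rates — one run from an empty and one from a full grid per
#' condition, so both nucleation and evaporation configurations enter
#' the statistics — and fits the mean-field coefficients. Uses the
#' current RNG state; call `set.seed()` beforehand for reproducibility.
#'
#' @param PGrid lattice sizes (perfect squares)
#' @param kInGrid influx rates (#/s) controlling the occupancy range
#' @param coop a [CoopParams-class]
#' @param params a [TraffickingParams-class]
#' @param tEnd,burnIn per-run sampled duration and burn-in (s)
#' @param weightCap see [fitMeanField()]
#' @return list with the fitted [MeanFieldFit-class] (`fit`), the
#'   pooled `stats`, and the raw `runs`
#' @export
calibrateMeanField <- function(PGrid = c(36, 64, 100, 144, 196),
                               kInGrid = c(0.1, 0.2, 0.4, 0.6, 0.9, 1.2),
                               coop = coopParams(),
                               params = traffickingParams(),
                               tEnd = 5000, burnIn = 1000,
                               weightCap = 500) {
  runs <- list()
  for (P in PGrid)
    for (k in kInGrid)
      for (s in c("empty", "full"))
        runs[[length(runs) + 1L]] <-
          latticeRun(P = P, kIn = k, coop = coop, params = params,
                     tEnd = tEnd, burnIn = burnIn, start = s)
  stats <- latticeStatistics(runs)
  list(fit = fitMeanField(stats, coop = coop, weightCap = weightCap),
       stats = stats, runs = runs)
}

#' Basal binding rate of the cooperative mean-field model
#'
#' With cooperativity the steady state shifts, so the basal binding
#' rate must be re-derived from the adapted fixed-point equation:
#' \deqn{k^0_{UB} = \frac{A^0_{spine} B^* k_{BU}
#'   \lambda(P)/(B^* + \beta(P) - 0.5)}
#'   {(P - B^*) (1 + m(P) B^{*0.8}) U^*}.}
#' For the reference spine and the shipped calibration this is about
#' 0.0005 um^2/(# s) — an order of magnitude below the non-cooperative
#' value, because neighbour interactions amplify binding.
#'
#' @param p a [TraffickingParams-class]
#' @param fit a [MeanFieldFit-class]
#' @return binding rate (um^2/(# s))
#' @export
coopKUB0 <- function(p, fit = defaultMeanFieldFit()) {
  if (p@P <= p@BStar) stop("need P > BStar")
  den <- (p@P - p@BStar) * (1 + mAt(fit, p@P) * p@BStar^0.8) * p@UStar
  if (den <= 0) stop("non-positive denominator in the fixed-point closure")
  gB <- lambdaAt(fit, p@P) / (p@BStar + betaAt(fit, p@P) - 0.5)
  p@ASpine0 * p@BStar * p@kBU * gB / den
}

#' Fixed points of bound receptors along a parameter sweep
#'
#' Solves the algebraic fixed point of the basic or cooperative
#' mean-field model along a sweep of the exocytosis event size or of
#' the mobile receptor concentration, with warm-started continuation in
#' both sweep directions so hysteresis (coexisting branches) is
#' detected. In the cooperative model the curve is steep and sigmoidal,
#' so small shifts of the exocytosis supply move B* substantially; the
#' basic model's curve is shallow.
#'
#' @param variant `"basic"` or `"coop"`
#' @param params a [TraffickingParams-class]
#' @param fit a [MeanFieldFit-class] (cooperative variant)
#' @param SExo sweep of exocytosis event sizes (#), mapped to mobile
#'   concentrations through the trafficking balance; give either this
#'   or `conc`
#' @param conc sweep of mobile concentrations (#/um^2)
#' @param P slot count
#' @param kUB0 basal binding rate; defaults to the variant's value
#' @return data.frame with columns `sweep`, `conc`, `direction`,
#'   `BStar`, `occupancy` and `converged`; non-converged continuation
#'   points (bistability candidates) are flagged, not dropped
#' @export
fixedPointCurve <- function(variant = c("basic", "coop"),
                            params = traffickingParams(),
                            fit = defaultMeanFieldFit(),
                            SExo = NULL, conc = NULL,
                            P = params@P, kUB0 = NULL) {
  variant <- match.arg(variant)
  if (is.null(SExo) && is.null(conc))
    stop("give a sweep of SExo or conc")
  if (!is.null(SExo)) {
    if (any(SExo < 0)) stop("sweep values must be positive")
    conc <- (params@kExo0 * SExo + params@kIn) / (params@kEndo + params@kOut)
    sweep <- SExo
  } else {
    if (any(conc <= 0)) stop("sweep values must be positive")
    sweep <- conc
  }
  coop <- variant == "coop"
  if (is.null(kUB0))
    kUB0 <- if (coop) {
      if (!is.na(params@kUB0Coop)) params@kUB0Coop else coopKUB0(params, fit)
    } else params@kUB0
  drift <- function(B, cc) {
    g <- if (coop) meanFieldRates(fit, B, P) else list(gUB = 1, gBU = 1)
    kUB0 * g$gUB * (P - B) * cc - params@kBU * g$gBU * B
  }
  solveFrom <- function(cc, B0) {
    # damped Newton with numerical derivative, fall back to bisection
    B <- min(max(B0, 1e-6), P - 1e-6)
    for (i in 1:100) {
      f <- drift(B, cc)
      h <- 1e-6 * max(1, B)
      df <- (drift(B + h, cc) - drift(B - h, cc)) / (2 * h)
      if (!is.finite(df) || df == 0) break
      step <- f / df
      Bn <- B - sign(step) * min(abs(step), 0.2 * P)
      Bn <- min(max(Bn, 1e-9), P - 1e-9)
      if (abs(Bn - B) < 1e-10) { B <- Bn; break }
      B <- Bn
    }
    if (abs(drift(B, cc)) < 1e-8 * max(1, params@kBU * P))
      list(B = B, ok = TRUE)
    else list(B = B, ok = FALSE)
  }
  runDirection <- function(ord, label) {
    B <- P * 0.3
    out <- vector("list", length(ord))
    for (j in seq_along(ord)) {
      i <- ord[j]
      s <- solveFrom(conc[i], B)
      if (s$ok) B <- s$B
      out[[j]] <- data.frame(sweep = sweep[i], conc = conc[i],
                             direction = label, BStar = s$B,
                             occupancy = s$B / P, converged = s$ok)
    }
    do.call(rbind, out)
  }
  up <- runDirection(order(conc), "ascending")
  down <- runDirection(rev(order(conc)), "descending")
  res <- rbind(up, down)
  rownames(res) <- NULL
  res[order(res$direction, res$conc), ]
}
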