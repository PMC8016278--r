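#' Time-averaged L1 distance between model and reference curves
#'
#' The cost of a candidate parameter set is the time-averaged absolute
#' difference in bound receptor numbers, summed over the two
#' experimental conditions (exocytosis intact / blocked):
#' \deqn{\Delta = \frac{1}{T}\left(\int_0^T |B^{LTP}_{ref} -
#'   B^{LTP}_{sim}|\,dt + \int_0^T |B^{noexo}_{ref} -
#'   B^{noexo}_{sim}|\,dt\right),}
#' evaluated by trapezoidal quadrature. Curves are data.frames with
#' columns `t` and `B`; if the grids differ, the simulated curve is
#' linearly interpolated onto the reference grid (with a message).
#'
#' @param simLtp,simNoexo simulated curves
#' @param refLtp,refNoexo reference curves (receptor counts; see
#'   [toReceptorCounts()])
#' @param T averaging window (s); defaults to the largest common time
#' @return cost in receptors (time-averaged)
#' @export
trajectoryCost <- function(simLtp, simNoexo, refLtp, refNoexo, T = NULL) {
  one <- function(sim, ref) {
    if (is.null(T)) T <<- min(max(sim$t), max(ref$t))
    rt <- ref$t[ref$t <= T + 1e-9]
    rB <- ref$B[ref$t <= T + 1e-9]
    if (length(sim$t) != length(rt) || any(abs(sim$t[seq_along(rt)] - rt) > 1e-9)) {
      message("resampling simulated curve onto the reference grid")
      sB <- stats::approx(sim$t, sim$B, xout = rt, rule = 2)$y
    } else sB <- sim$B[seq_along(rt)]
    d <- abs(rB - sB)
    sum(diff(rt) * (d[-1] + d[-length(d)]) / 2)
  }
  (one(simLtp, refLtp) + one(simNoexo, refNoexo)) / T
}

#' Parameter ranges for random sampling
#'
#' Uniform sampling ranges of the trafficking and pulse parameters:
#' basal exocytosis event rate 0-0.01 /s, exocytosis pulse decay
#' 0-67 min and amplitude 0-20, unbinding rate 0-1 /s, binding-rate
#' pulse decay 0-8 min and amplitude 0-50 (0-20 in the cooperative
#' model, where cooperativity already amplifies binding).
#'
#' @param variant model variant; only the binding-pulse amplitude range
#'   differs for cooperative variants
#' @return data.frame with columns `name`, `low`, `high`
#' @export
sampleRanges <- function(variant = c("basic", "sltp", "coop")) {
  variant <- match.arg(variant)
  data.frame(
    name = c("kExo0", "tauExo2", "AExo", "kBU", "tauUB2", "AUB"),
    low = c(0, 0, 0, 0, 0, 0),
    high = c(0.01, 67 * 60, 20, 1, 8 * 60, if (variant == "coop") 20 else 50))
}

#' Random sampling of the parameter space against reference curves
#'
#' Draws `nTrials` parameter vectors uniformly from the given ranges,
#' re-derives the dependent rates per draw (endocytosis from the
#' mobile-pool closure; the binding rate from the basic or cooperative
#' fixed-point closure, so every trial starts from the same (U*, B*)
#' baseline), simulates the LTP and blocked-exocytosis protocols,
#' scores each trial with [trajectoryCost()], and returns the ranked
#' trials together with summary time courses of the best `topFrac`
#' fraction. Draws whose derived endocytosis rate would be negative
#' (influx too small) are rejected and reported.
#'
#' @param variant `"basic"`, `"sltp"` or `"coop"`
#' @param ranges sampling ranges, see [sampleRanges()]
#' @param nTrials number of trials
#' @param topFrac fraction of best trials retained (0.005 of 2000 keeps
#'   10)
#' @param refLtp,refNoexo reference curves in receptor counts
#'   (data.frames with `t`, `B`); defaults built from
#'   [referenceParams()] stand-ins scaled by `params$BStar`
#' @param params,sltp,fit model building blocks
#' @param tEnd,dt,outDt integration settings for each trial
#' @return list of class `"samplingResult"`: `trials` (ranked
#'   data.frame of draws, derived rates and costs), `top` (best
#'   subset), `summaries` (mean and sd time courses over the top set of
#'   B, mobile concentration, and the exocytosis/binding rate
#'   multipliers, all in percent of baseline), `nRejected` (draws with
#'   infeasible derived rates) and `nFailed` (draws whose integration
#'   failed)
#' @export
runSampling <- function(variant = c("basic", "sltp", "coop"),
                        ranges = sampleRanges(variant),
                        nTrials = 2000, topFrac = 0.005,
                        refLtp = NULL, refNoexo = NULL,
                        params = traffickingParams(),
                        sltp = sltpParams(),
                        fit = defaultMeanFieldFit(),
                        tEnd = 7200, dt = 0.1, outDt = 10) {
  variant <- match.arg(variant)
  if (nTrials * topFrac < 1) stop("nTrials * topFrac must be >= 1")
  if (is.null(refLtp)) {
    rc <- referenceCurve(referenceParams("ltp"), tEnd = tEnd, by = outDt)
    refLtp <- data.frame(t = rc$t, B = toReceptorCounts(rc$pct, params@BStar))
  }
  if (is.null(refNoexo)) {
    rc <- referenceCurve(referenceParams("noexo"), tEnd = tEnd, by = outDt)
    refNoexo <- data.frame(t = rc$t, B = toReceptorCounts(rc$pct, params@BStar))
  }
  rn <- ranges$name
  draws <- vapply(seq_len(nrow(ranges)), function(i)
    stats::runif(nTrials, ranges$low[i], ranges$high[i]),
    numeric(nTrials))
  colnames(draws) <- rn

  simVariant <- if (variant == "coop") "coop" else variant
  trials <- vector("list", nTrials)
  trajB <- list(); trajU <- list(); nRejected <- 0L; nFailed <- 0L
  for (i in seq_len(nTrials)) {
    d <- as.list(draws[i, ])
    pTry <- tryCatch(
      traffickingParams(kExo0 = d$kExo0, kBU = d$kBU,
                        SExo0 = params@SExo0, P = params@P,
                        UStar = params@UStar, BStar = params@BStar,
                        VSpine0 = params@VSpine0,
                        kIn = params@kIn, kOut = params@kOut),
      error = function(e) NULL)
    if (is.null(pTry)) { # negative derived kEndo: influx too small
      nRejected <- nRejected + 1L
      trials[[i]] <- data.frame(trial = i, as.data.frame(draws)[i, ],
                                kEndo = NA, kUB0 = NA, cost = NA,
                                ok = FALSE)
      next
    }
    if (variant == "coop")
      pTry@kUB0Coop <- coopKUB0(pTry, fit)
    # sampled decay constants may be arbitrarily small; the transient is
    # symmetric in its two time constants, only equality is degenerate
    tE2 <- max(d$tauExo2, 0.5); if (abs(tE2 - 25) < 1e-9) tE2 <- tE2 + 0.1
    tU2 <- max(d$tauUB2, 0.5); if (abs(tU2 - 5) < 1e-9) tU2 <- tU2 + 0.1
    pls <- list(exo = pulseSpec(A = d$AExo, tau1 = 25, tau2 = tE2),
                ub = pulseSpec(A = d$AUB, tau1 = 5, tau2 = tU2))
    # extreme draws can make the system too stiff for the fixed step
    # (or transiently negative): such trials are flagged and excluded
    sims <- tryCatch(suppressWarnings(list(
      simulateSpine(simVariant, "ltp", params = pTry, sltp = sltp,
                    fit = fit, pulses = pls, tEnd = tEnd, dt = dt,
                    outDt = outDt),
      simulateSpine(simVariant, "ltp_noexo", params = pTry,
                    sltp = sltp, fit = fit, pulses = pls,
                    tEnd = tEnd, dt = dt, outDt = outDt))),
      error = function(e) NULL)
    if (is.null(sims)) {
      nFailed <- nFailed + 1L
      trials[[i]] <- data.frame(trial = i, as.data.frame(draws)[i, ],
                                kEndo = pTry@kEndo, kUB0 = NA, cost = NA,
                                ok = FALSE)
      next
    }
    sim1 <- sims[[1]]; sim2 <- sims[[2]]
    cost <- trajectoryCost(sim1, sim2, refLtp, refNoexo)
    kUBused <- if (variant == "coop") pTry@kUB0Coop else pTry@kUB0
    trials[[i]] <- data.frame(trial = i, as.data.frame(draws)[i, ],
                              kEndo = pTry@kEndo, kUB0 = kUBused,
                              cost = cost, ok = TRUE)
    trajB[[i]] <- sim1$BPctBaseline
    trajU[[i]] <- 100 * sim1$UConc / sim1$UConc[1]
  }
  trials <- do.call(rbind, trials)
  ok <- trials[trials$ok & is.finite(trials$cost), , drop = FALSE]
  ok <- ok[order(ok$cost, ok$trial), , drop = FALSE]  # ties by draw order
  ok$rank <- seq_len(nrow(ok))
  nTop <- max(1L, floor(nTrials * topFrac))
  top <- ok[seq_len(min(nTop, nrow(ok))), , drop = FALSE]

  tGrid <- seq(0, tEnd, by = outDt)
  summarise <- function(lst, idx) {
    m <- do.call(rbind, lst[idx])
    data.frame(t = tGrid, mean = colMeans(m),
               sd = apply(m, 2, stats::sd))
  }
  pulsePct <- function(A, tau2v, tau1) {
    m <- vapply(seq_along(A), function(j) {
      t2 <- max(tau2v[j], 0.5); if (abs(t2 - tau1) < 1e-9) t2 <- t2 + 0.1
      pulseValue(pulseSpec(A = A[j], tau1 = tau1, tau2 = t2), tGrid) * 100
    }, numeric(length(tGrid)))
    data.frame(t = tGrid, mean = rowMeans(m), sd = apply(m, 1, stats::sd))
  }
  summaries <- if (nrow(top) > 0) list(
    B = summarise(trajB, top$trial),
    UConc = summarise(trajU, top$trial),
    kExo = pulsePct(top$AExo, top$tauExo2, 25),
    kUB = pulsePct(top$AUB, top$tauUB2, 5)) else NULL
  structure(list(trials = ok, top = top, summaries = summaries,
                 nRejected = nRejected, nFailed = nFailed,
                 variant = variant),
            class = "samplingResult")
}
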