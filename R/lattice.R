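#' Construct cooperative-lattice parameters
#'
#' @param alpha cooperativity strength; each occupied nearest neighbour
#'   (fraction chi = n/8) multiplies the binding rate by
#'   `(alpha * chi + 1)` and the unbinding rate by `(1 - chi)`.
#'   `alpha = 0` is the non-cooperative control in which both rates are
#'   constant (the neighbour dependence is switched off entirely, so
#'   slot occupancies are independent and binomial)
#' @param kUB per-slot binding rate constant (um^2/(# s))
#' @param kBU unbinding rate (1/s)
#' @param dt lattice time step (s); step probabilities must stay below 1
#' @return a [CoopParams-class]
#' @export
coopParams <- function(alpha = 16, kUB = 0.0005, kBU = 0.1, dt = 0.5) {
  obj <- new("CoopParams", alpha = alpha, kUB = kUB, kBU = kBU, dt = dt)
  validObject(obj)
  obj
}

#' Per-slot cooperative binding and unbinding rates
#'
#' For a given occupancy configuration, returns the slot-resolved rates
#' \eqn{k^{coop}_{UB} = k_{UB}(\alpha\chi + 1)} (empty slots) and
#' \eqn{k^{coop}_{BU} = k_{BU}(1 - \chi)} (occupied slots), where
#' \eqn{\chi = n/8} is the fraction of occupied nearest neighbours.
#' Edge and corner slots use the same denominator of 8 (no periodic
#' boundary), so their attainable chi is smaller.
#'
#' @param occupancy integer/logical matrix (N x N) of slot occupancy
#' @param coop a [CoopParams-class]
#' @return list with matrices `chi`, `kUBCoop` (NA at occupied slots)
#'   and `kBUCoop` (NA at empty slots)
#' @export
slotRates <- function(occupancy, coop = coopParams()) {
  M <- matrix(as.integer(occupancy != 0), nrow(occupancy), ncol(occupancy))
  N1 <- nrow(M); N2 <- ncol(M)
  Z <- matrix(0L, N1 + 2, N2 + 2)
  Z[2:(N1 + 1), 2:(N2 + 1)] <- M
  nb <- Z[1:N1, 1:N2] + Z[1:N1, 2:(N2 + 1)] + Z[1:N1, 3:(N2 + 2)] +
    Z[2:(N1 + 1), 1:N2] + Z[2:(N1 + 1), 3:(N2 + 2)] +
    Z[3:(N1 + 2), 1:N2] + Z[3:(N1 + 2), 2:(N2 + 1)] + Z[3:(N1 + 2), 3:(N2 + 2)]
  chi <- nb / 8
  if (coop@alpha == 0) chi[] <- 0  # non-cooperative control: constant rates
  kUBc <- coop@kUB * (coop@alpha * chi + 1); kUBc[M == 1L] <- NA_real_
  kBUc <- coop@kBU * (1 - chi); kBUc[M == 0L] <- NA_real_
  list(chi = chi, kUBCoop = kUBc, kBUCoop = kBUc)
}

#' Run the stochastic cooperative lattice coupled to the mobile pool
#'
#' Simulates the square-lattice PSD with synchronous per-step Bernoulli
#' binding/unbinding (neighbour fractions frozen at the start of each
#' step) coupled to a stochastically simulated mobile pool (tau-leap
#' Poisson draws of the trafficking fluxes; exocytosis delivers
#' `SExo0` receptors per Poisson event). The spine area scales linearly
#' with the slot number relative to the reference spine, so the basal
#' mobile concentration is size-independent.
#'
#' @param P slot count; must be a perfect square
#' @param kIn diffusive influx (#/s); sweeping it controls the mobile
#'   concentration and thereby the occupancy
#' @param coop a [CoopParams-class]
#' @param params a [TraffickingParams-class] supplying the trafficking
#'   rates of the mobile pool
#' @param tEnd sampled duration after burn-in (s)
#' @param burnIn burn-in duration (s); occupancy statistics (mean, CV)
#'   are collected after the burn-in, while the conditional-rate
#'   accumulators cover the whole run so that ascending (nucleation) and
#'   descending (evaporation) configurations both contribute
#' @param start `"empty"` or `"full"` initial grid
#' @param clampU clamp the mobile concentration at `conc` instead of
#'   simulating the pool (used for controls and calibration checks)
#' @param conc clamped mobile concentration (#/um^2)
#' @param bleachTime if >= 0, photobleach all receptors currently in the
#'   spine at this time (FRAP bookkeeping)
#' @param thin record the time series every `thin` steps
#' @return a list of class `"latticeRun"`: `series` (data.frame t, U,
#'   B plus bleached/unbleached splits), `cnt`/`sUB`/`sBU`
#'   (conditional-rate accumulators indexed by B = 0..P), `Bbar`, `CV`,
#'   `boundTime`/`bindCount`/`unbindCount` (per-slot N x N matrices),
#'   totals, and metadata
#' @export
latticeRun <- function(P = 64, kIn = 0.4, coop = coopParams(),
                       params = traffickingParams(),
                       tEnd = 5000, burnIn = 1000,
                       start = c("empty", "full"),
                       clampU = FALSE, conc = NULL,
                       bleachTime = -1, thin = NULL) {
  start <- match.arg(start)
  N <- as.integer(round(sqrt(P)))
  if (N * N != P) stop("P must be a perfect square for the lattice")
  A <- params@ASpine0 * P / params@P
  concFree <- (params@kExo0 * params@SExo0 + kIn) / (params@kEndo + params@kOut)
  if (is.null(conc)) conc <- concFree
  U0 <- if (clampU) round(conc * A) else round(concFree * A)
  if (is.null(thin)) thin <- max(1L, as.integer(round(1 / coop@dt)))

  res <- .lattice_sim(N, tEnd + burnIn, coop@dt, burnIn,
                      start == "full", coop@alpha, coop@kUB, coop@kBU,
                      kIn, params@kExo0, params@SExo0,
                      params@kEndo, params@kOut, A,
                      U0, clampU, conc, bleachTime, as.integer(thin))
  ser <- as.data.frame(res$series)
  ser$U <- ser$Uu + ser$Ub
  ser$B <- ser$Bu + ser$Bb
  out <- list(
    series = ser,
    cnt = res$cnt, sUB = res$sUB, sBU = res$sBU,
    Bbar = res$Bbar, Bvar = res$Bvar,
    CV = if (res$Bbar > 0) sqrt(res$Bvar) / res$Bbar else NA_real_,
    boundTime = matrix(res$boundTime, N, N),
    bindCount = matrix(res$bindCount, N, N),
    unbindCount = matrix(res$unbindCount, N, N),
    bindsTotal = res$bindsTotal, unbindsTotal = res$unbindsTotal,
    P = P, N = N, kIn = kIn, ASpine = A, dt = coop@dt,
    kUB = coop@kUB, kBU = coop@kBU, alpha = coop@alpha,
    start = start, clampU = clampU, conc = conc,
    burnIn = burnIn, tEnd = tEnd, bleachTime = bleachTime)
  class(out) <- "latticeRun"
  out
}

#' Pool lattice runs into occupancy-conditioned statistics
#'
#' Aggregates a set of [latticeRun()] results into the conditional mean
#' binding and unbinding rates given (B, P) — the averages over the
#' empty and occupied slot sets of each recorded configuration — plus
#' per-run stationary occupancy and coefficient of variation. Runs
#' whose post-burn-in occupancy still trends (first vs second half
#' differing by more than three standard errors) trigger a warning to
#' extend the burn-in.
#'
#' @param runs list of `latticeRun` objects (possibly several P values)
#' @param minCount drop B levels visited fewer than this many times
#' @return a list of class `"latticeStats"`: `rates` (data.frame P, B,
#'   n, kUBMean, kBUMean), `occupancy` (per-run data.frame), and the
#'   rate constants the runs used
#' @export
latticeStatistics <- function(runs, minCount = 5) {
  stopifnot(length(runs) >= 1)
  Ps <- vapply(runs, function(r) r$P, numeric(1))
  occ <- do.call(rbind, lapply(seq_along(runs), function(i) {
    r <- runs[[i]]
    ser <- r$series
    post <- ser[ser$t > r$burnIn, , drop = FALSE]
    if (nrow(post) >= 8) {
      h <- nrow(post) %/% 2
      m1 <- mean(post$B[seq_len(h)]); m2 <- mean(post$B[(h + 1):nrow(post)])
      se <- stats::sd(post$B) / sqrt(h)
      if (is.finite(se) && se > 0 && abs(m1 - m2) > 3 * se * sqrt(2))
        warning(sprintf(
          "run %d (P = %d, kIn = %.3g, %s start) may not be equilibrated; extend burn-in",
          i, r$P, r$kIn, r$start))
    }
    data.frame(run = i, P = r$P, kIn = r$kIn, start = r$start,
               Bbar = r$Bbar, CV = r$CV, occupancy = r$Bbar / r$P)
  }))
  rates <- do.call(rbind, lapply(sort(unique(Ps)), function(P) {
    sel <- runs[Ps == P]
    cnt <- Reduce(`+`, lapply(sel, `[[`, "cnt"))
    sUB <- Reduce(`+`, lapply(sel, `[[`, "sUB"))
    sBU <- Reduce(`+`, lapply(sel, `[[`, "sBU"))
    B <- 0:P
    ok <- cnt >= minCount
    data.frame(P = P, B = B[ok], n = cnt[ok],
               kUBMean = (sUB / cnt)[ok], kBUMean = (sBU / cnt)[ok])
  }))
  out <- list(rates = rates, occupancy = occ,
              kUB = runs[[1]]$kUB, kBU = runs[[1]]$kBU,
              alpha = runs[[1]]$alpha)
  class(out) <- "latticeStats"
  out
}

#' Per-slot mean dwell times of bound receptors
#'
#' The mean time a receptor stays bound at each slot, computed as the
#' cumulative bound time divided by the number of completed (plus one
#' ongoing) binding episodes. With cooperative binding the dwell times
#' are strongly non-uniform across the PSD: slots at cluster cores hold
#' receptors for orders of magnitude longer than isolated slots.
#'
#' @param run a `latticeRun`
#' @return N x N matrix of mean dwell times (s); NA for never-bound
#'   slots
#' @export
dwellTimes <- function(run) {
  episodes <- run$unbindCount +
    (run$boundTime > 0 & run$bindCount > run$unbindCount)
  dwell <- run$boundTime / pmax(episodes, 1)
  dwell[run$boundTime == 0] <- NA_real_
  dwell
}

#' Simulate fluorescence recovery after photobleaching (FRAP)
#'
#' At `bleachTime` every receptor currently in the spine (mobile and
#' bound) is marked bleached; recovery is driven by unbleached receptor
#' influx via lateral diffusion and exocytosis. The recovery curve is
#' the unbleached fraction of the chosen observable, averaged over
#' trials.
#'
#' @inheritParams latticeRun
#' @param trials number of independent stochastic trials
#' @param tAfter recorded duration after the bleach (s)
#' @param observable `"UB"` counts mobile plus bound unbleached
#'   receptors (total fluorescence); `"B"` counts bound only
#' @return data.frame with columns `t` (time since bleach, s),
#'   `recovery` (mean unbleached fraction) and `se` (standard error
#'   across trials)
#' @export
simulateFRAP <- function(P = 81, kIn = 0.2, coop = coopParams(dt = 0.2),
                         params = traffickingParams(),
                         bleachTime = 900, tAfter = 600, trials = 100,
                         observable = c("UB", "B")) {
  observable <- match.arg(observable)
  if (bleachTime < 300)
    warning("bleachTime may precede equilibration of the lattice")
  curves <- NULL
  for (i in seq_len(trials)) {
    r <- latticeRun(P = P, kIn = kIn, coop = coop, params = params,
                    tEnd = bleachTime + tAfter, burnIn = 0,
                    bleachTime = bleachTime)
    ser <- r$series
    post <- ser[ser$t > bleachTime, , drop = FALSE]
    unb <- if (observable == "UB") post$Uu + post$Bu else post$Bu
    tot <- if (observable == "UB") post$U + post$B else post$B
    frac <- ifelse(tot > 0, unb / tot, 0)
    if (is.null(curves)) curves <- matrix(NA_real_, trials, length(frac))
    curves[i, seq_along(frac)] <- frac
  }
  tRel <- post$t - bleachTime
  data.frame(t = tRel,
             recovery = colMeans(curves),
             se = apply(curves, 2, stats::sd) / sqrt(trials))
}
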