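#' Right-hand side of the two-pool trafficking model
#'
#' The basal model follows the mobile pool U (on the spine membrane) and
#' the bound pool B (at PSD slots):
#' \deqn{dU/dt = k_{exo} S_{exo} + k_{in} + k_{BU} B -
#'   (k_{endo} + k_{out} + k_{UB}(P - B)) U / A_{spine},}
#' \deqn{dB/dt = k_{UB} (P - B) U / A_{spine} - k_{BU} B.}
#' Time-dependent rates during LTP induction are obtained by evaluating
#' the supplied pulses at `t`.
#'
#' @param U,B mobile and bound receptor numbers
#' @param p a [TraffickingParams-class]
#' @param t time since induction (s); only used when pulses are given
#' @param pulses optional list with `exo` and `ub` pulses
#'   (see [ltpPulses()]) applied multiplicatively to `kExo0` and `kUB0`
#' @param SExo exocytosis event size (defaults to the basal value)
#' @param ASpine spine surface area (defaults to the basal value)
#' @return named vector `c(dU, dB)` (receptors/s)
#' @examples
#' p <- traffickingParams()
#' rhsBasic(p$UStar, p$BStar, p)  # (0, 0): the closed steady state
#' @export
rhsBasic <- function(U, B, p, t = 0, pulses = NULL, SExo = p@SExo0,
                     ASpine = p@ASpine0) {
  kExo <- p@kExo0
  kUB <- p@kUB0
  if (!is.null(pulses)) {
    if (!is.null(pulses$exo)) kExo <- kExo * pulseValue(pulses$exo, t)
    if (!is.null(pulses$ub)) kUB <- kUB * pulseValue(pulses$ub, t)
  }
  bind <- kUB * (p@P - B) * U / ASpine
  unbind <- p@kBU * B
  c(dU = kExo * SExo + p@kIn + unbind -
      (p@kEndo + p@kOut) * U / ASpine - bind,
    dB = bind - unbind)
}

# free-pool steady-state concentration U*/A implied by the trafficking
# balance (binding and unbinding cancel at the joint fixed point)
.freeConc <- function(p, SExoStar) {
  (p@kExo0 * SExoStar + p@kIn) / (p@kEndo + p@kOut)
}

# solve the bound-pool fixed point at a given mobile concentration
.solveBStar <- function(conc, P, kUB0, kBU, fit = NULL) {
  if (is.null(fit)) {
    x <- kUB0 * conc / kBU
    return(P * x / (1 + x))
  }
  g <- function(B) {
    r <- meanFieldRates(fit, B, P)
    kUB0 * r$gUB * (P - B) * conc - kBU * r$gBU * B
  }
  stats::uniroot(g, c(1e-9, P - 1e-9), tol = 1e-12)$root
}

#' Simulate a model variant under an experimental protocol
#'
#' Integrates the chosen model with the classical 4th-order Runge-Kutta
#' method at a fixed step. Model variants: `"basic"` (two-pool
#' trafficking), `"sltp"` (adds spine-volume dynamics and
#' volume-coupled exocytosis event size), `"coop"` (cooperative binding
#' via the calibrated mean-field rates) and `"combined"` (sLTP +
#' cooperative). Protocols: `"baseline"` (no induction), `"ltp"`
#' (induction at t = 0 with the exocytosis and binding-rate pulses) and
#' `"ltp_noexo"` (induction with exocytosis blocked from t = 0 onward;
#' the binding-rate pulse is still applied and, in sLTP variants, the
#' sustained volume change is abolished).
#'
#' Simulations start at the variant's own fixed point, so the baseline
#' protocol holds (U, B) constant to integrator tolerance.
#'
#' @param variant one of `"basic"`, `"sltp"`, `"coop"`, `"combined"`
#' @param protocol one of `"baseline"`, `"ltp"`, `"ltp_noexo"`
#' @param params a [TraffickingParams-class]
#' @param sltp an [SLTPParams-class] (used by sLTP variants)
#' @param fit a [MeanFieldFit-class] (used by cooperative variants);
#'   defaults to the shipped calibration
#' @param pulses LTP pulses; defaults to [ltpPulses()] with the
#'   amplitude appropriate for the variant
#' @param tEnd simulation length (s)
#' @param dt integration step (s); 0.1 s resolves the fastest pulse
#'   time constant (5 s) fifty-fold
#' @param outDt output sampling interval (s)
#' @param P slot count for this spine (defaults to `params$P`)
#' @param VSpine0 initial spine volume (um^3)
#' @param SExoStar basal exocytosis event size for this spine; the RE
#'   efflux rate is re-closed so this is a fixed point
#' @param instArea use the instantaneous spherical area implied by
#'   V(t) in the concentration terms (`TRUE`) or freeze the basal area
#' @param init optional named vector `c(U=, B=)` overriding the
#'   computed fixed-point initial condition
#' @return a data.frame of class `"spineTrajectory"` with columns
#'   `t`, `U`, `B`, `VSpine`, `SExo`, `ASpine`, `BPctBaseline`
#'   (100 B / B at baseline) and `UConc` (U / ASpine, #/um^2), plus
#'   attributes `baseline` (list with U0, B0), `variant`, `protocol`,
#'   `dt` and `paramsSnapshot`
#' @examples
#' tr <- simulateSpine("basic", "ltp", tEnd = 1200)
#' max(tr$BPctBaseline)
#' @export
simulateSpine <- function(variant = c("basic", "sltp", "coop", "combined"),
                          protocol = c("baseline", "ltp", "ltp_noexo"),
                          params = traffickingParams(),
                          sltp = sltpParams(),
                          fit = defaultMeanFieldFit(),
                          pulses = NULL,
                          tEnd = 7200, dt = 0.1, outDt = 1,
                          P = params@P,
                          VSpine0 = params@VSpine0,
                          SExoStar = params@SExo0,
                          instArea = TRUE,
                          init = NULL) {
  variant <- match.arg(variant)
  protocol <- match.arg(protocol)
  stopifnot(dt > 0, tEnd > 0)
  coop <- variant %in% c("coop", "combined")
  sltpOn <- variant %in% c("sltp", "combined")
  ltp <- protocol != "baseline"
  noexo <- protocol == "ltp_noexo"
  if (is.null(pulses)) pulses <- ltpPulses(cooperative = coop)

  kUB0 <- if (coop) {
    if (!is.na(params@kUB0Coop)) params@kUB0Coop else coopKUB0(params, fit)
  } else params@kUB0
  mfc <- if (coop) {
    list(mP = mAt(fit, P), lambdaP = lambdaAt(fit, P), betaP = betaAt(fit, P))
  } else list(mP = 0, lambdaP = 1, betaP = 1.5)

  dVLong <- if (sltpOn && ltp && !noexo) deltaVLong(VSpine0, sltp) else 0
  kOutRE <- deriveKOutRE(sltp@kInRE, VSpine0, SExoStar)

  conc0 <- .freeConc(params, SExoStar)
  A0 <- areaFromVolume(VSpine0)
  if (is.finite(conc0)) {
    U0 <- conc0 * A0
    B0 <- .solveBStar(conc0, P, kUB0, params@kBU, if (coop) fit else NULL)
  } else {
    # all exchange with the dendrite switched off: no free-pool balance,
    # the caller must supply the initial condition
    if (is.null(init) || anyNA(init[c("U", "B")]))
      stop("no free-pool steady state exists for these rates; supply init")
    U0 <- B0 <- NA_real_
  }
  if (!is.null(init)) {
    if (!is.na(init["U"])) U0 <- init[["U"]]
    if (!is.na(init["B"])) B0 <- init[["B"]]
  }

  pars <- list(
    kExo0 = params@kExo0, SExo0 = SExoStar, kIn = params@kIn,
    kOut = params@kOut, kEndo = params@kEndo, kBU = params@kBU,
    kUB0 = kUB0, P = P, VSpine0 = VSpine0,
    ltp = ltp, noexo = noexo, coop = coop, sltp = sltpOn,
    AExo = pulses$exo@A, tExo1 = pulses$exo@tau1, tExo2 = pulses$exo@tau2,
    AUB = pulses$ub@A, tUB1 = pulses$ub@tau1, tUB2 = pulses$ub@tau2,
    mP = mfc$mP, lambdaP = mfc$lambdaP, betaP = mfc$betaP,
    dVLong = dVLong,
    tauS1 = sltp@tauShort1, tauS2 = sltp@tauShort2,
    tauL1 = sltp@tauLong1, tauL2 = sltp@tauLong2,
    anS = 0, anL = 0, shortAmp = sltp@shortAmpFactor,
    kInRE = sltp@kInRE, kOutRE = kOutRE, instArea = instArea)

  res <- .rk4_spine(pars, c(U0, B0, SExoStar), tEnd, dt, outDt)
  if (res$nClipped > 0)
    warning(sprintf("state clipped at zero in %d sub-steps", res$nClipped))
  out <- as.data.frame(res$trajectory)
  out$BPctBaseline <- 100 * out$B / B0
  out$UConc <- out$U / out$ASpine
  attr(out, "baseline") <- list(U0 = U0, B0 = B0)
  attr(out, "variant") <- variant
  attr(out, "protocol") <- protocol
  attr(out, "dt") <- dt
  attr(out, "paramsSnapshot") <- pars
  class(out) <- c("spineTrajectory", "data.frame")
  out
}

#' Time for the bound pool to return to baseline after induction
#'
#' Operationalises "falls back to the basal level": the first time
#' after the post-induction peak at which B re-enters a relative band
#' around its baseline. The default band of 2% simultaneously
#' reproduces the return windows of all ODE model variants (see the
#' package vignette); it is exposed for sensitivity analyses.
#'
#' @param traj a trajectory from [simulateSpine()] under an LTP
#'   protocol
#' @param thresholdFrac half-width of the relative baseline band
#' @return return time (s); `Inf` if B never re-enters the band
#' @export
findReturnTime <- function(traj, thresholdFrac = 0.02) {
  stopifnot(thresholdFrac > 0, thresholdFrac < 1)
  B0 <- attr(traj, "baseline")$B0
  if (is.null(B0)) stop("trajectory carries no baseline attribute")
  ip <- which.max(traj$B)
  if (traj$B[ip] <= B0 * (1 + thresholdFrac))
    stop("not applicable: trajectory has no peak above the baseline band")
  rel <- abs(traj$B - B0) / B0
  idx <- which(seq_along(rel) > ip & rel <= thresholdFrac)
  if (!length(idx)) return(Inf)
  traj$t[idx[1]]
}
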