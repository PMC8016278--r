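#' @import methods
NULL

#' Basal trafficking parameters of the spine model
#'
#' Holds all rate constants and steady-state targets of the two-pool
#' receptor-trafficking model of an average dendritic spine: exocytosis
#' event rate and size, endocytosis, lateral diffusion in/out of the
#' spine, binding/unbinding at PSD slots, slot number, spine geometry and
#' the target steady state (mobile receptors \code{UStar}, bound
#' receptors \code{BStar}). Rates that multiply a surface concentration
#' carry units of um^2/s. Use [traffickingParams()] to construct objects;
#' the constructor closes the parameter set analytically so that
#' (UStar, BStar) is an exact fixed point.
#'
#' @slot kExo0 exocytosis event rate under basal conditions (events/s)
#' @slot SExo0 receptors delivered per exocytosis event (#)
#' @slot kEndo endocytosis rate (um^2/s)
#' @slot kIn diffusive influx from the dendrite (#/s)
#' @slot kOut diffusive efflux rate (um^2/s)
#' @slot kBU unbinding rate from PSD slots (1/s)
#' @slot kUB0 basal binding rate at the PSD (um^2/(# s))
#' @slot kUB0Coop basal binding rate in the cooperative model
#'   (um^2/(# s)); \code{NA} until calibrated, see [coopKUB0()]
#' @slot P number of PSD slots (#)
#' @slot UStar,BStar steady-state mobile and bound receptor numbers (#)
#' @slot VSpine0 basal spine volume (um^3)
#' @slot ASpine0 basal spine surface area (um^2), spherical geometry
#' @export
setClass("TraffickingParams",
  representation(kExo0 = "numeric", SExo0 = "numeric", kEndo = "numeric",
                 kIn = "numeric", kOut = "numeric", kBU = "numeric",
                 kUB0 = "numeric", kUB0Coop = "numeric", P = "numeric",
                 UStar = "numeric", BStar = "numeric", VSpine0 = "numeric",
                 ASpine0 = "numeric"))

setValidity("TraffickingParams", function(object) {
  msg <- character()
  nn <- c("kExo0", "SExo0", "kEndo", "kIn", "kOut", "kBU", "kUB0")
  for (s in nn)
    if (slot(object, s) < 0) msg <- c(msg, paste0(s, " must be >= 0"))
  if (object@UStar < 0) msg <- c(msg, "UStar must be >= 0")
  if (object@BStar < 0 || object@BStar > object@P)
    msg <- c(msg, "need P >= BStar >= 0")
  if (object@VSpine0 <= 0) msg <- c(msg, "VSpine0 must be > 0")
  a <- areaFromVolume(object@VSpine0)
  if (abs(object@ASpine0 - a) > 1e-8 * a)
    msg <- c(msg, "ASpine0 inconsistent with spherical VSpine0")
  if (length(msg)) msg else TRUE
})

#' Transient multiplicative change of a rate during LTP induction
#'
#' The double-exponential time course \eqn{f(t) = C + A (e^{-t/\tau_2} -
#' e^{-t/\tau_1})/A_{norm}} applied multiplicatively to a basal rate.
#' \code{ANorm} is chosen so the bump's maximum is exactly \code{C + A}.
#'
#' @slot C baseline multiplier (1 for rate pulses, 0 for pure transients)
#' @slot A amplitude factor of the transient
#' @slot tau1,tau2 rise and decay time constants (s)
#' @slot ANorm the normalising factor (computed)
#' @export
setClass("PulseSpec",
  representation(C = "numeric", A = "numeric", tau1 = "numeric",
                 tau2 = "numeric", ANorm = "numeric"),
  prototype(C = 1, A = 0, tau1 = 1, tau2 = 2, ANorm = 1))

setValidity("PulseSpec", function(object) {
  msg <- character()
  if (object@tau1 <= 0 || object@tau2 <= 0)
    msg <- c(msg, "time constants must be > 0")
  if (object@tau1 == object@tau2)
    msg <- c(msg, "degenerate time scales: tau1 == tau2 leaves ANorm undefined")
  if (object@A < 0) msg <- c(msg, "A must be >= 0")
  if (object@C < 0) msg <- c(msg, "C must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Structural plasticity (sLTP) parameters
#'
#' Parameters of the spine-volume time course after LTP induction and of
#' the recycling-endosome (RE) exocytosis event size that is slaved to
#' the volume. The sustained relative volume change is
#' \eqn{\Delta V_{long}(V_0) = (a e^{V_0/b} + c)/100}; the transient
#' phase has amplitude \eqn{1 + 1.75\,\Delta V_{long}}.
#'
#' @slot a,c size-dependence coefficients on the percent scale
#' @slot b size-dependence decay scale (um^3; negative for decay with V0)
#' @slot tauShort1,tauShort2 rise/decay of the transient phase (s)
#' @slot tauLong1,tauLong2 rise/decay of the sustained phase (s);
#'   \code{tauLong2} is very large when late-phase LTP is modelled
#' @slot kInRE receptor supply rate from REs (#/s)
#' @slot kOutRE volume-scaled relaxation rate of the event size (um^3/s)
#' @slot shortAmpFactor multiplier linking transient amplitude to
#'   \eqn{\Delta V_{long}} (1.75)
#' @export
setClass("SLTPParams",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 tauShort1 = "numeric", tauShort2 = "numeric",
                 tauLong1 = "numeric", tauLong2 = "numeric",
                 kInRE = "numeric", kOutRE = "numeric",
                 shortAmpFactor = "numeric"))

setValidity("SLTPParams", function(object) {
  msg <- character()
  if (object@tauShort1 <= 0 || object@tauShort2 <= object@tauShort1)
    msg <- c(msg, "need tauShort2 > tauShort1 > 0")
  if (object@tauLong1 <= 0 || object@tauLong2 <= object@tauLong1)
    msg <- c(msg, "need tauLong2 > tauLong1 > 0")
  if (object@kInRE < 0 || object@kOutRE < 0)
    msg <- c(msg, "RE rates must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Parameters of the stochastic cooperative lattice
#'
#' @slot alpha cooperativity strength (dimensionless); 0 switches
#'   cooperativity off
#' @slot kUB basal per-slot binding rate constant (um^2/(# s))
#' @slot kBU basal unbinding rate (1/s)
#' @slot dt lattice time step (s)
#' @export
setClass("CoopParams",
  representation(alpha = "numeric", kUB = "numeric", kBU = "numeric",
                 dt = "numeric"))

setValidity("CoopParams", function(object) {
  msg <- character()
  if (object@alpha < 0) msg <- c(msg, "alpha must be >= 0")
  if (object@kUB < 0 || object@kBU < 0) msg <- c(msg, "rates must be >= 0")
  if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
  if (length(msg)) msg else TRUE
})

#' Mean-field reduction of the cooperative lattice
#'
#' The fitted coefficients that turn lattice statistics into effective
#' occupancy-dependent binding/unbinding rates:
#' \deqn{k^{coop}_{BU}/k_{BU} = \lambda(P) / (\beta(P) + B - 0.5), \quad
#'       k^{coop}_{UB}/k_{UB} = m(P) B^{0.8} + 1,}
#' with \eqn{\beta(P) = m_\beta P + c_\beta},
#' \eqn{\lambda(P) = m_\lambda P + c_\lambda} and
#' \eqn{m(P) = a_m/(P + b_m)}.
#'
#' @slot mBeta,cBeta linear coefficients of beta(P)
#' @slot mLambda,cLambda linear coefficients of lambda(P)
#' @slot aM,bM hyperbolic coefficients of m(P)
#' @slot perP data.frame of the per-lattice-size fits
#'   (columns P, m, lambda, beta, rssUB, rssBU)
#' @export
setClass("MeanFieldFit",
  representation(mBeta = "numeric", cBeta = "numeric", mLambda = "numeric",
                 cLambda = "numeric", aM = "numeric", bM = "numeric",
                 perP = "data.frame"))

setMethod("show", "TraffickingParams", function(object) {
  cat("TraffickingParams (basal spine model)\n")
  cat(sprintf("  spine: V0 = %.3g um^3, A0 = %.4g um^2, P = %g slots\n",
              object@VSpine0, object@ASpine0, object@P))
  cat(sprintf("  steady state: U* = %g, B* = %g (occupancy %.1f%%)\n",
              object@UStar, object@BStar, 100 * object@BStar / object@P))
  cat(sprintf("  kExo0 = %g /s, SExo0 = %g, kIn = %g #/s, kOut = %g um^2/s\n",
              object@kExo0, object@SExo0, object@kIn, object@kOut))
  cat(sprintf("  kEndo = %.4g um^2/s, kUB0 = %.4g, kBU = %g /s",
              object@kEndo, object@kUB0, object@kBU))
  if (!is.na(object@kUB0Coop))
    cat(sprintf(", kUB0 (coop) = %.4g", object@kUB0Coop))
  cat("\n")
})

setMethod("show", "PulseSpec", function(object) {
  cat(sprintf("PulseSpec: f(t) = %g + %g * bump(t; tau1 = %g s, tau2 = %g s)\n",
              object@C, object@A, object@tau1, object@tau2))
})

setMethod("show", "SLTPParams", function(object) {
  cat("SLTPParams (structural plasticity)\n")
  cat(sprintf("  DeltaV_long(V0) = (%.4g * exp(V0/%.4g) + %.4g)/100\n",
              object@a, object@b, object@c))
  cat(sprintf("  transient: tau = (%g, %g) s; sustained: tau = (%g, %g) s\n",
              object@tauShort1, object@tauShort2, object@tauLong1,
              object@tauLong2))
  cat(sprintf("  RE coupling: kInRE = %g #/s, kOutRE = %.4g um^3/s\n",
              object@kInRE, object@kOutRE))
})

setMethod("show", "CoopParams", function(object) {
  cat(sprintf(
    "CoopParams: alpha = %g, kUB = %g um^2/(# s), kBU = %g /s, dt = %g s\n",
    object@alpha, object@kUB, object@kBU, object@dt))
})

setMethod("show", "MeanFieldFit", function(object) {
  cat("MeanFieldFit (cooperative mean-field coefficients)\n")
  cat(sprintf("  beta(P)   = %.4g P + %.4g\n", object@mBeta, object@cBeta))
  cat(sprintf("  lambda(P) = %.4g P + %.4g\n", object@mLambda, object@cLambda))
  cat(sprintf("  m(P)      = %.4g / (P + %.4g)\n", object@aM, object@bM))
  cat(sprintf("  fitted on %d lattice sizes (P = %s)\n", nrow(object@perP),
              paste(object@perP$P, collapse = ", ")))
})

#' @describeIn MeanFieldFit-class the six global coefficients as a named
#'   vector
#' @param object a \code{MeanFieldFit}
#' @export
setMethod("coef", "MeanFieldFit", function(object) {
  c(mBeta = object@mBeta, cBeta = object@cBeta, mLambda = object@mLambda,
    cLambda = object@cLambda, aM = object@aM, bM = object@bM)
})

# slot access with `$` for the parameter containers (read-only convenience)
.dollar <- function(x, name) methods::slot(x, name)
#' @export
setMethod("$", "TraffickingParams", .dollar)
#' @export
setMethod("$", "PulseSpec", .dollar)
#' @export
setMethod("$", "SLTPParams", .dollar)
#' @export
setMethod("$", "CoopParams", .dollar)
#' @export
setMethod("$", "MeanFieldFit", .dollar)
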