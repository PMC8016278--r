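#' Reference EPSP decay curves (stand-in parameterisation)
#'
#' The fitting stage compares simulated bound-receptor time courses to
#' reference EPSP decay curves expressed in percent of baseline. Each
#' curve is the sum of two normalised double-exponential transients — a
#' short initial phase and a long-lasting phase. The shipped
#' coefficients are *stand-ins, not experimental data*: they are chosen
#' so the curves respect the experimentally reported envelopes
#' (induction rise within a minute; E-LTP decays toward baseline on the
#' 1-6 h scale; with exocytosis blocked, decay within 10-20 min) and
#' all live in this one constructor.
#'
#' @param condition `"ltp"` (E-LTP, exocytosis intact) or `"noexo"`
#'   (exocytosis blocked at induction)
#' @param short,long optional [PulseSpec-class] overrides for the two
#'   components; their `C` values must sum to 100 (%)
#' @return list of class `"referenceParams"` with elements `short`,
#'   `long`, `condition`
#' @export
referenceParams <- function(condition = c("ltp", "noexo"),
                            short = NULL, long = NULL) {
  condition <- match.arg(condition)
  if (is.null(short))
    short <- if (condition == "ltp")
      pulseSpec(A = 80, tau1 = 20, tau2 = 600, C = 50)
    else
      pulseSpec(A = 100, tau1 = 20, tau2 = 300, C = 50)
  if (is.null(long))
    long <- if (condition == "ltp")
      pulseSpec(A = 60, tau1 = 60, tau2 = 9000, C = 50)
    else
      pulseSpec(A = 0, tau1 = 60, tau2 = 900, C = 50)
  if (abs(short@C + long@C - 100) > 1e-9)
    stop("component baselines must sum to 100%")
  structure(list(short = short, long = long, condition = condition),
            class = "referenceParams")
}

#' Evaluate a reference EPSP curve
#'
#' @param t time since induction (s)
#' @param rp a [referenceParams()] object
#' @return EPSP in percent of baseline (100 at t = 0)
#' @export
epspReference <- function(t, rp = referenceParams("ltp")) {
  pulseValue(rp$short, t) + pulseValue(rp$long, t)
}

#' Convert a percent-of-baseline curve to bound receptor counts
#'
#' \eqn{B_{ref}(t) = EPSP(t)/100\% \cdot B^*}: the reference curves are
#' compared to the model in units of bound receptors assuming the same
#' baseline as the model.
#'
#' @param pct curve in percent of baseline
#' @param BStar baseline bound receptor number
#' @return receptor counts
#' @export
toReceptorCounts <- function(pct, BStar) {
  if (BStar <= 0) stop("BStar must be > 0")
  pct / 100 * BStar
}

#' Reference curve sampled on a time grid
#'
#' @param rp a [referenceParams()] object
#' @param tEnd duration (s); defaults to 2 h for the E-LTP condition
#'   and 30 min with blocked exocytosis, matching the spans over which
#'   the respective experiments are reported
#' @param by sampling interval (s)
#' @return data.frame with columns `t`, `pct`, `condition`
#' @export
referenceCurve <- function(rp = referenceParams("ltp"),
                           tEnd = if (rp$condition == "ltp") 7200 else 1800,
                           by = 1) {
  t <- seq(0, tEnd, by = by)
  data.frame(t = t, pct = epspReference(t, rp), condition = rp$condition)
}

#' Noisy synthetic variants of a reference curve
#'
#' Gaussian-perturbed replicates used to exercise the fitting stage.
#'
#' @param rp a [referenceParams()] object
#' @param noiseSd standard deviation of the additive noise (percent
#'   points)
#' @param n number of replicates
#' @param tEnd,by sampling grid (s)
#' @return matrix (n x time points) of percent-of-baseline values; the
#'   time grid is attached as attribute `t`
#' @export
synthNoisyCurves <- function(rp = referenceParams("ltp"), noiseSd = 5,
                             n = 10, tEnd = 7200, by = 10) {
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  t <- seq(0, tEnd, by = by)
  base <- epspReference(t, rp)
  out <- matrix(rep(base, each = n), nrow = n) +
    matrix(stats::rnorm(n * length(t), sd = noiseSd), nrow = n)
  attr(out, "t") <- t
  out
}
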