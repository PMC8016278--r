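#' Construct an LTP-induction pulse
#'
#' @param A amplitude factor (the rate transiently rises to `C + A`
#'   times its basal value)
#' @param tau1 rise time constant (s)
#' @param tau2 decay time constant (s)
#' @param C baseline multiplier (default 1)
#' @return a [PulseSpec-class]
#' @examples
#' exo <- pulseSpec(A = 5, tau1 = 25, tau2 = 60)
#' pulseValue(exo, 0)    # baseline
#' @export
pulseSpec <- function(A, tau1, tau2, C = 1) {
  # "C = C" would partially match new()'s Class formal; set the slot after
  obj <- new("PulseSpec", A = A, tau1 = tau1, tau2 = tau2,
             ANorm = .anorm(tau1, tau2))
  obj@C <- C
  validObject(obj)
  obj
}

# normalising factor such that max_t (e^{-t/tau2} - e^{-t/tau1})/ANorm = 1
.anorm <- function(tau1, tau2) {
  r <- tau2 / tau1
  r^(tau1 / (tau1 - tau2)) - r^(tau2 / (tau1 - tau2))
}

#' Evaluate a pulse time course
#'
#' \eqn{f(t) = C + A (e^{-t/\tau_2} - e^{-t/\tau_1})/A_{norm}},
#' multiplied onto the basal rate by the caller. At t = 0 the value is
#' `C`; the maximum over t is `C + A`.
#'
#' @param spec a [PulseSpec-class]
#' @param t time since induction (s), vector allowed; negative times
#'   return `C`
#' @return dimensionless multiplier
#' @export
pulseValue <- function(spec, t) {
  stopifnot(is(spec, "PulseSpec"))
  v <- spec@C + spec@A * (exp(-t / spec@tau2) - exp(-t / spec@tau1)) /
    spec@ANorm
  v[t < 0] <- spec@C
  v
}

#' The LTP-induction pulses on exocytosis and binding rate
#'
#' Exocytosis events speed up 5-fold for about a minute
#' (tau = 25 s / 60 s); the binding rate rises sharply (tau = 5 s) and
#' decays within about two minutes (tau = 60 s), with amplitude 30 in
#' the non-cooperative models and 5 in the cooperative ones (where
#' cooperativity itself amplifies binding).
#'
#' @param cooperative use the cooperative-model binding amplitude (5)
#'   instead of the basic-model value (30)
#' @param AExo,AUB optional amplitude overrides
#' @return list with elements `exo` and `ub`, both [PulseSpec-class]
#' @export
ltpPulses <- function(cooperative = FALSE, AExo = 5,
                      AUB = if (cooperative) 5 else 30) {
  list(exo = pulseSpec(A = AExo, tau1 = 25, tau2 = 60),
       ub = pulseSpec(A = AUB, tau1 = 5, tau2 = 60))
}
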