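# Independent oracle implementations used to cross-check the package.
# They are deliberately written differently from the package code paths.

# flux-by-flux assembly of the two-pool derivatives (independent of rhsBasic)
oracleFluxSum <- function(U, B, p, kExo = p$kExo0, kUB = p$kUB0,
                          SExo = p$SExo0, A = p$ASpine0) {
  influx <- c(exo = kExo * SExo, lateral = p$kIn, unbind = p$kBU * B)
  efflux <- c(endo = p$kEndo * U / A, lateral = p$kOut * U / A,
              bind = kUB * (p$P - B) * U / A)
  c(dU = sum(influx) - sum(efflux),
    dB = unname(efflux["bind"] - influx["unbind"]))
}

# dense-grid maximiser of the normalised transient
oraclePulseMax <- function(spec, tMax = 50 * spec$tau2, n = 2e5) {
  t <- seq(0, tMax, length.out = n)
  v <- pulseValue(spec, t)
  list(value = max(v), t = t[which.max(v)])
}

# second implementation of the spine-volume time course (no PulseSpec reuse)
oracleVSpine <- function(t, V0, sl, dV) {
  an <- function(t1, t2) (t2 / t1)^(t1 / (t1 - t2)) - (t2 / t1)^(t2 / (t1 - t2))
  bump <- function(t, t1, t2) (exp(-t / t2) - exp(-t / t1)) / an(t1, t2)
  V0 * ((1 + (1 + sl$shortAmpFactor * dV) * bump(t, sl$tauShort1, sl$tauShort2)) +
          dV * bump(t, sl$tauLong1, sl$tauLong2))
}

# loop-based neighbour counting on an N x N grid, no boundary wrap
oracleNeighbours <- function(M) {
  N1 <- nrow(M); N2 <- ncol(M)
  out <- matrix(0L, N1, N2)
  for (r in seq_len(N1)) for (co in seq_len(N2)) {
    s <- 0L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- co + dc
      if (rr >= 1 && rr <= N1 && cc >= 1 && cc <= N2) s <- s + M[rr, cc]
    }
    out[r, co] <- s
  }
  out
}

# fine-grid Riemann-sum version of the two-condition L1 cost
oracleCost <- function(simLtp, simNoexo, refLtp, refNoexo, T, n = 2e5) {
  one <- function(sim, ref) {
    tg <- seq(0, T, length.out = n)
    d <- abs(approx(ref$t, ref$B, tg, rule = 2)$y -
               approx(sim$t, sim$B, tg, rule = 2)$y)
    mean(d) * T
  }
  (one(simLtp, refLtp) + one(simNoexo, refNoexo)) / T
}

# build a trajectory-shaped object from closed-form curves
fakeTrajectory <- function(t, B, B0) {
  out <- data.frame(t = t, B = B)
  attr(out, "baseline") <- list(U0 = NA, B0 = B0)
  class(out) <- c("spineTrajectory", "data.frame")
  out
}
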