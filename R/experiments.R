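#' Compare E-LTP time courses across the model hierarchy
#'
#' Runs all four model variants under the LTP and blocked-exocytosis
#' protocols and tabulates the bound-receptor time courses (percent of
#' baseline) together with return-time and trough diagnostics.
#'
#' @param params,sltp,fit model building blocks
#' @param tEnd,dt integration settings (s)
#' @param returnBand baseline band used by [findReturnTime()]
#' @param variants subset of variants to run
#' @return list with `trajectories` (long data.frame: variant,
#'   protocol, t, BPct, UConcPct) and `diagnostics` (one row per
#'   variant x protocol: peak, return time, trough, end level)
#' @export
experimentELTPComparison <- function(params = traffickingParams(),
                                     sltp = sltpParams(),
                                     fit = defaultMeanFieldFit(),
                                     tEnd = 7200, dt = 0.1,
                                     returnBand = 0.02,
                                     variants = c("basic", "sltp", "coop",
                                                  "combined")) {
  traj <- list(); diag <- list()
  for (v in variants) {
    for (pr in c("ltp", "ltp_noexo")) {
      tr <- simulateSpine(v, pr, params = params, sltp = sltp, fit = fit,
                          tEnd = tEnd, dt = dt)
      traj[[paste(v, pr)]] <- data.frame(
        variant = v, protocol = pr, t = tr$t, BPct = tr$BPctBaseline,
        UConcPct = 100 * tr$UConc / tr$UConc[1])
      rt <- tryCatch(findReturnTime(tr, returnBand), error = function(e) NA)
      diag[[paste(v, pr)]] <- data.frame(
        variant = v, protocol = pr,
        peakPct = max(tr$BPctBaseline),
        returnTimeMin = rt / 60,
        troughPct = min(tr$BPctBaseline[tr$t > 300]),
        endPct = tr$BPctBaseline[nrow(tr)])
    }
  }
  list(trajectories = do.call(rbind, c(traj, make.row.names = FALSE)),
       diagnostics = do.call(rbind, c(diag, make.row.names = FALSE)))
}

#' E-LTP metrics across spine and PSD sizes
#'
#' Sweeps the spine/PSD size in one of three modes and reports E-LTP
#' metrics for the combined (cooperative + sLTP) model:
#' \describe{
#'   \item{`P_only`}{vary the slot number only, keeping the spine
#'     volume at its reference value (decoupled PSD size).}
#'   \item{`P_with_area`}{scale the spine so its area matches the slot
#'     number (P proportional to the area) while the basal exocytosis
#'     event size stays fixed at 13 receptors.}
#'   \item{`SExo_scaled`}{as `P_with_area`, but the basal event size
#'     scales with the initial volume through the RE fixed point, so
#'     larger spines receive proportionally more receptors per event.}
#' }
#'
#' @param mode sweep mode, see above
#' @param grid P values (`P_only`, `P_with_area`) or initial volumes in
#'   um^3 (`SExo_scaled`)
#' @param variant model variant (default combined)
#' @param params,sltp,fit model building blocks
#' @param tEnd,dt integration settings
#' @param returnBand baseline band for the return time
#' @param sustainedPct threshold (percent of baseline at 2 h) above
#'   which E-LTP counts as sustained
#' @return data.frame with one row per size: P, VSpine0, SExoStar,
#'   baseline occupancy, peak occupancy (percent of P), return time
#'   (min), B at 1 and 20 min (percent of baseline), end level and
#'   sustained flag
#' @export
experimentSizeSweep <- function(mode = c("P_with_area", "P_only",
                                         "SExo_scaled"),
                                grid = NULL,
                                variant = "combined",
                                params = traffickingParams(),
                                sltp = sltpParams(),
                                fit = defaultMeanFieldFit(),
                                tEnd = 7200, dt = 0.1,
                                returnBand = 0.02, sustainedPct = 110) {
  mode <- match.arg(mode)
  if (is.null(grid))
    grid <- if (mode == "SExo_scaled") c(0.02, 0.05, 0.08, 0.1, 0.2, 0.4)
            else c(40, 70, 100, 200)
  rows <- lapply(grid, function(g) {
    if (mode == "P_only") {
      P <- g; V0 <- params@VSpine0; SStar <- params@SExo0
    } else if (mode == "P_with_area") {
      P <- g
      V0 <- volumeFromArea(params@ASpine0 * P / params@P)
      SStar <- params@SExo0          # exocytosis supply held constant
    } else {
      V0 <- g
      P <- scaleSlots(areaFromVolume(V0), params@P, params@ASpine0)
      SStar <- params@SExo0 * V0 / params@VSpine0  # RE fixed-point scaling
    }
    tr <- simulateSpine(variant, "ltp", params = params, sltp = sltp,
                        fit = fit, tEnd = tEnd, dt = dt, P = P,
                        VSpine0 = V0, SExoStar = SStar)
    B0 <- attr(tr, "baseline")$B0
    rt <- tryCatch(findReturnTime(tr, returnBand), error = function(e) NA)
    at <- function(tt) tr$BPctBaseline[which.min(abs(tr$t - tt))]
    data.frame(mode = mode, P = P, VSpine0 = V0, SExoStar = SStar,
               occupancyPct = 100 * B0 / P,
               peakOccPct = 100 * max(tr$B) / P,
               returnTimeMin = rt / 60,
               BPct1min = at(60), BPct20min = at(1200),
               endPct = tr$BPctBaseline[nrow(tr)],
               sustained = tr$BPctBaseline[nrow(tr)] > sustainedPct)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
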