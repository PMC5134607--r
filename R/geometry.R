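# Phenophase line-intersection geometry (Gu method), shared by the
# ROI-average double-logistic path and the per-pixel spline path.
#
# Given a fitted seasonal curve y(t) and its derivative on a grid:
#   * recovery line  = tangent at the maximum of dy/dt,
#   * senescence line = tangent at the minimum of dy/dt,
#   * baseline / maxline = horizontal lines at the curve minimum / maximum,
#   * UD = recovery x baseline, SD = recovery x maxline,
#   * provisional DD = senescence x maxline,
#   * plateau line = least-squares line through the curve on [SD, prov. DD]
#     (captures the mid-season greendown), final DD = senescence x plateau,
#   * RD = senescence x baseline, GSL = RD - UD.

phases_from_grid <- function(tg, yg, dg, plateau = TRUE) {
  out <- list(UD = NA_real_, SD = NA_real_, DD = NA_real_, RD = NA_real_,
              gsl = NA_real_, baseline = min(yg), maxline = max(yg),
              plateau_slope = NA_real_, plateau_intercept = NA_real_,
              min_gcc = min(yg), max_gcc = max(yg),
              range_gcc = max(yg) - min(yg), flag = "ok")
  n <- length(tg)
  ir <- which.max(dg)
  is <- which.min(dg)
  if (ir %in% c(1L, n) || is %in% c(1L, n)) {
    out$flag <- "derivative-extremum-at-endpoint"
    return(out)
  }
  sr <- dg[ir]; ss <- dg[is]
  if (sr <= 0 || ss >= 0) {
    out$flag <- "no-seasonal-cycle"
    return(out)
  }
  # A senescence extremum before the recovery extremum (noisy, weak-signal
  # fits) is not rejected: the crossed tangents then date RD before UD and
  # GSL comes out negative, which downstream histogram filtering removes.
  if (tg[is] < tg[ir]) out$flag <- "inverted-cycle"
  tr <- tg[ir]; yr <- yg[ir]
  ts <- tg[is]; ys <- yg[is]
  base <- out$baseline; maxv <- out$maxline
  out$UD <- tr + (base - yr) / sr
  out$SD <- tr + (maxv - yr) / sr
  dd_prov <- ts + (maxv - ys) / ss
  out$RD <- ts + (base - ys) / ss
  out$DD <- dd_prov
  out$plateau_slope <- 0
  out$plateau_intercept <- maxv
  if (plateau && dd_prov > out$SD) {
    sel <- tg >= out$SD & tg <= dd_prov
    if (sum(sel) >= 2 && diff(range(tg[sel])) > 0) {
      pl <- lm(y ~ t, data = data.frame(t = tg[sel], y = yg[sel]))
      ps <- coef(pl)[[2]]; pi0 <- coef(pl)[[1]]
      # a flat plateau means no greendown: leave DD at the max-line crossing
      if (is.finite(ps) && abs(ps) > 1e-6 && abs(ps - ss) > 1e-12) {
        dd_adj <- (ys - ss * ts - pi0) / (ps - ss)
        # keep the adjustment only when the crossing is in-season
        if (is.finite(dd_adj) && dd_adj > out$SD && dd_adj <= out$RD) {
          out$DD <- dd_adj
          out$plateau_slope <- ps
          out$plateau_intercept <- pi0
        }
      }
    }
  }
  out$gsl <- out$RD - out$UD
  out
}

phases_as_tibble <- function(ph) {
  tibble::tibble(phase = c("UD", "SD", "DD", "RD", "GSL"),
                 doy = c(ph$UD, ph$SD, ph$DD, ph$RD, ph$gsl))
}
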