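# Independent brute-force oracles. These deliberately share no code with the
# package internals they check.

# Winding-number point-in-polygon, one point at a time (angle summation).
oracle_point_in_polygon <- function(py, px, vy, vx, eps = 1e-9) {
  n <- length(vy)
  # on-boundary check by explicit segment distance
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ay <- vy[i]; ax <- vx[i]; by <- vy[j]; bx <- vx[j]
    L2 <- (by - ay)^2 + (bx - ax)^2
    t <- if (L2 == 0) 0 else ((py - ay) * (by - ay) + (px - ax) * (bx - ax)) / L2
    t <- min(1, max(0, t))
    d2 <- (py - (ay + t * (by - ay)))^2 + (px - (ax + t * (bx - ax)))^2
    if (d2 <= eps) return(TRUE)
  }
  total <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a1 <- atan2(vy[i] - py, vx[i] - px)
    a2 <- atan2(vy[j] - py, vx[j] - px)
    d <- a2 - a1
    if (d > pi) d <- d - 2 * pi
    if (d < -pi) d <- d + 2 * pi
    total <- total + d
  }
  abs(total) > pi
}

oracle_roi_mask <- function(vertices, h, w) {
  mask <- matrix(FALSE, h, w)
  for (r in 0:(h - 1)) for (cc in 0:(w - 1)) {
    mask[r + 1, cc + 1] <- oracle_point_in_polygon(r, cc,
                                                   vertices[, 1], vertices[, 2])
  }
  mask
}

# Per-day window percentile, naive loop.
oracle_window_percentile <- function(doy, gcc, half = 1, p = 0.9) {
  day <- floor(doy)
  days <- seq(min(day), max(day))
  out <- data.frame(doy = integer(), gcc = numeric())
  for (d in days) {
    v <- gcc[day >= d - half & day <= d + half]
    if (length(v) == 0) next
    out <- rbind(out, data.frame(doy = d,
                                 gcc = unname(quantile(v, p, type = 7))))
  }
  out
}

# Exhaustive single-breakpoint segmented regression on sorted values:
# minimizes RSS(lm left) + RSS(lm right) over all admissible splits.
oracle_single_breakpoint <- function(g, min_seg = 4) {
  y <- sort(g); n <- length(y); x <- seq_len(n) / n
  best <- list(rss = Inf, k = NA_integer_)
  for (k in min_seg:(n - min_seg)) {
    r <- sum(resid(lm(y[1:k] ~ x[1:k]))^2) +
      sum(resid(lm(y[(k + 1):n] ~ x[(k + 1):n]))^2)
    if (r < best$rss) best <- list(rss = r, k = k)
  }
  best$threshold <- (y[best$k] + y[best$k + 1]) / 2
  best$rss_one <- sum(resid(lm(y ~ x))^2)
  best
}

# Exhaustive single mean-changepoint on a sorted vector: minimizes summed
# within-segment SSE.
oracle_mean_changepoint <- function(x) {
  x <- sort(x); n <- length(x)
  best <- list(sse = Inf, k = NA_integer_)
  for (k in 1:(n - 1)) {
    l <- x[1:k]; r <- x[(k + 1):n]
    s <- sum((l - mean(l))^2) + sum((r - mean(r))^2)
    if (s < best$sse) best <- list(sse = s, k = k)
  }
  best
}

# Dense-grid phenophase oracle for an analytic Gu trajectory, written as a
# plain numerical procedure (finite differences + explicit intersections).
oracle_phases <- function(params, span = c(1, 365), step = 0.02,
                          plateau = TRUE) {
  tg <- seq(span[1], span[2], by = step)
  yg <- phenodesert::gu_curve(tg, params)
  h <- step / 10
  dg <- (phenodesert::gu_curve(tg + h, params) -
           phenodesert::gu_curve(tg - h, params)) / (2 * h)
  ir <- which.max(dg); is <- which.min(dg)
  base <- min(yg); maxv <- max(yg)
  ud <- tg[ir] + (base - yg[ir]) / dg[ir]
  sd_ <- tg[ir] + (maxv - yg[ir]) / dg[ir]
  dd <- tg[is] + (maxv - yg[is]) / dg[is]
  rd <- tg[is] + (base - yg[is]) / dg[is]
  if (plateau && dd > sd_) {
    sel <- tg >= sd_ & tg <= dd
    cf <- coef(lm(yg[sel] ~ tg[sel]))
    if (abs(cf[2]) > 1e-6) {
      cand <- (yg[is] - dg[is] * tg[is] - cf[1]) / (cf[2] - dg[is])
      if (is.finite(cand) && cand > sd_ && cand <= rd) dd <- cand
    }
  }
  list(UD = ud, SD = sd_, DD = dd, RD = rd, GSL = rd - ud)
}
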