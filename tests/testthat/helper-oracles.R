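# Independent oracles, deliberately coded without reuse of package internals.

# Forward-Euler integration of the pool-depletion trace model on a grid
# `refine` x finer than the package integrator's sub-steps (package: 10
# sub-steps per frame; oracle default: 1000).
oracle_nprr_dff <- function(protocol, params, refine = 100, substeps = 10) {
  times <- nprrquant::protocol_frames(protocol)
  gains <- params$trial_gain_schedule
  if (length(gains) == 1) gains <- rep(gains, nrow(protocol))
  dff <- numeric(length(times))
  P <- 1; R <- 0
  for (i in seq_along(times)[-1]) {
    h <- (times[i] - times[i - 1]) / (substeps * refine)
    tt <- times[i - 1]
    for (j in seq_len(substeps * refine)) {
      k <- which(tt >= protocol$onset_s & tt < protocol$offset_s)
      if (length(k)) {
        k <- k[1]
        drv <- stats::plogis((protocol$frequency_hz[k] - params$freq_threshold) *
                               params$freq_slope) * gains[k]
        dP <- -params$pool_depletion_rate * drv * P
        dR <- params$release_gain_per_hz * protocol$frequency_hz[k] * drv * P -
          R / params$signal_clearance_tau
      } else {
        dP <- (1 - P) / params$pool_replenish_tau
        dR <- -R / params$signal_clearance_tau
      }
      P <- P + h * dP
      R <- R + h * dR
      tt <- tt + h
    }
    dff[i] <- R - params$undershoot_coupling * (1 - P)
  }
  dff
}

# Ray-casting point-in-polygon (crossing number), coded independently of the
# package's pracma-based test. Boundary handling may differ on exact edges;
# callers use points off the boundary.
oracle_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  for (p in seq_along(px)) {
    cross <- FALSE
    j <- n
    for (i in seq_len(n)) {
      xi <- poly[i, 1]; yi <- poly[i, 2]
      xj <- poly[j, 1]; yj <- poly[j, 2]
      if ((yi > py[p]) != (yj > py[p])) {
        xint <- (xj - xi) * (py[p] - yi) / (yj - yi) + xi
        if (px[p] < xint) cross <- !cross
      }
      j <- i
    }
    inside[p] <- cross
  }
  inside
}

# Minimum distance from a point to the closed polyline of a polygon.
oracle_boundary_dist <- function(px, py, poly) {
  n <- nrow(poly)
  out <- numeric(length(px))
  for (p in seq_along(px)) {
    best <- Inf
    j <- n
    for (i in seq_len(n)) {
      ax <- poly[j, 1]; ay <- poly[j, 2]
      bx <- poly[i, 1]; by <- poly[i, 2]
      vx <- bx - ax; vy <- by - ay
      L2 <- vx^2 + vy^2
      t <- if (L2 > 0) max(0, min(1, ((px[p] - ax) * vx + (py[p] - ay) * vy) / L2)) else 0
      d <- sqrt((px[p] - ax - t * vx)^2 + (py[p] - ay - t * vy)^2)
      best <- min(best, d)
      j <- i
    }
    out[p] <- best
  }
  out
}

# Compartment label by the priority rule, from the independent geometry above.
oracle_compartment <- function(px, py, centres, r, poly, h) {
  lab <- character(length(px))
  for (p in seq_along(px)) {
    in_dcv <- FALSE
    if (nrow(centres)) {
      d2 <- (centres[, 1] - px[p])^2 + (centres[, 2] - py[p])^2
      in_dcv <- any(d2 <= r^2)
    }
    lab[p] <- if (in_dcv) {
      "dcv"
    } else if (oracle_boundary_dist(px[p], py[p], poly) <= h) {
      "membrane"
    } else if (oracle_in_polygon(px[p], py[p], poly)) {
      "cytoplasm"
    } else {
      "outside"
    }
  }
  lab
}

# Exact Mann-Whitney p by direct enumeration over value assignments.
oracle_mw_p <- function(a, b, sided) {
  pooled <- c(a, b)
  n_a <- length(a)
  idx <- utils::combn(length(pooled), n_a)
  u_of <- function(av, bv) {
    sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  }
  u_obs <- u_of(a, b)
  u_all <- apply(idx, 2, function(ii) u_of(pooled[ii], pooled[-ii]))
  p_le <- mean(u_all <= u_obs + 1e-9)
  p_ge <- mean(u_all >= u_obs - 1e-9)
  switch(sided,
         less = p_le,
         greater = p_ge,
         two = min(1, 2 * min(p_le, p_ge)))
}

# 95% interval for a ratio of two Poisson-estimated densities around a true
# ratio, given the expected counts in numerator and denominator (delta
# method on the log ratio).
poisson_ratio_interval <- function(true_ratio, lambda_num, lambda_den) {
  se_log <- sqrt(1 / lambda_num + 1 / lambda_den)
  true_ratio * exp(c(-1, 1) * 1.96 * se_log)
}
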