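# Independent oracles, written from the documented model rather than the
# package internals: a vertex-enumeration LP solver for small FBA
# problems, a self-contained fixed-step RK4 integrator with its own copy
# of the Monod rate laws, and plain trapezoidal quadrature.

# --- vertex enumeration LP oracle -------------------------------------------
# max biomass over {v : S v = 0, lb <= v <= ub}; enumerates all basic
# solutions obtained by fixing (n - rank(S)) coordinates at a bound.
oracle_fba_vertex <- function(net, bounds = NULL, big_m = 1000) {
  S <- net$S
  ids <- vapply(net$reactions, `[[`, "", "id")
  rev <- vapply(net$reactions, `[[`, NA, "reversible")
  bio <- vapply(net$reactions, `[[`, NA, "is_biomass")
  lb <- ifelse(rev, -big_m, 0); ub <- rep(big_m, length(ids))
  names(lb) <- names(ub) <- ids
  if (!is.null(bounds)) {
    lb[names(bounds$lb)] <- bounds$lb
    ub[names(bounds$ub)] <- bounds$ub
  }
  qrS <- qr(t(S))
  Sr <- S[sort(qrS$pivot[seq_len(qrS$rank)]), , drop = FALSE]
  n <- ncol(S)
  d <- n - nrow(Sr)
  stopifnot(d >= 0)
  best <- -Inf; best_v <- NULL
  tol <- 1e-9
  for (J in utils::combn(n, d, simplify = FALSE)) {
    for (mask in seq_len(2^d) - 1L) {
      fixed <- ifelse(bitwAnd(mask, 2^(seq_len(d) - 1L)) > 0, ub[J], lb[J])
      A <- rbind(Sr, diag(n)[J, , drop = FALSE])
      b <- c(rep(0, nrow(Sr)), fixed)
      v <- tryCatch(solve(A, b), error = function(e) NULL)
      if (is.null(v)) next
      if (all(v >= lb - tol) && all(v <= ub + tol)) {
        obj <- sum(v[bio])
        if (obj > best) { best <- obj; best_v <- v }
      }
    }
  }
  list(objective = best, v = best_v)
}

# --- independent twin rhs + RK4 ---------------------------------------------
# Re-derived from the documented model equations; shares no code with the
# package's R or C right-hand sides.
oracle_rhs <- function(t, y, p, pol) {
  V <- y[1]; Xv <- y[2]; Xd <- y[3]
  C <- pmax(y[4:9], 0)
  P <- y[10]
  glc <- C[1]; gln <- C[2]; asn <- C[3]; lac <- C[4]; nh4 <- C[5]
  monod <- function(c, k) c / (k + c)
  mu <- p$mu_max * monod(glc, p$K_glc) * monod(gln, p$K_gln) *
    monod(asn, p$K_asn) *
    (p$KI_lac / (p$KI_lac + lac)) * (p$KI_amm / (p$KI_amm + nh4))
  mud <- p$kd0 + p$kd_amm * nh4
  qg <- mu / p$Y_xg + p$m_glc * monod(glc, p$K_mglc)
  qq <- mu / p$Y_xgln + p$m_gln * monod(gln, p$K_mgln)
  sw <- plogis((glc - p$glc_switch) / p$switch_width)
  q <- c(-qg, -qq, -p$q_asn_max * monod(asn, p$K_asn_up),
         sw * p$Y_lg * qg - (1 - sw) * p$q_lac_max * monod(lac, p$K_lac),
         p$Y_ag * qq, p$Y_ala * qq)
  qP <- p$alpha * mu + p$beta * monod(glc, p$K_glc)
  lin <- function(vals) approx(pol$knots, vals, t, rule = 2)$y
  F_in <- lin(pol$F_in); F_out <- lin(pol$F_out); cg <- lin(pol$C_feed_glc)
  Cf <- c(cg, pol$C_feed_other[c("gln", "asn", "lac", "nh4", "ala")])
  dil <- F_in / V
  c(F_in - F_out,
    (mu - mud) * Xv - dil * Xv,
    mud * Xv - dil * Xd,
    dil * (Cf - C) + q * Xv,
    qP * Xv - dil * P,
    F_in * cg)
}

oracle_rk4 <- function(x0, pol, p, t_end, dt = 0.01) {
  y <- c(x0$V, x0$Xv, x0$Xd, as.numeric(x0$C), x0$P, 0)
  t <- x0$t
  nstep <- round((t_end - t) / dt)
  stopifnot(abs(nstep * dt - (t_end - t)) < 1e-9)
  for (i in seq_len(nstep)) {
    k1 <- oracle_rhs(t, y, p, pol)
    k2 <- oracle_rhs(t + dt / 2, y + dt / 2 * k1, p, pol)
    k3 <- oracle_rhs(t + dt / 2, y + dt / 2 * k2, p, pol)
    k4 <- oracle_rhs(t + dt, y + dt * k3, p, pol)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + dt
  }
  names(y) <- c("V", "Xv", "Xd", "glc", "gln", "asn", "lac", "nh4", "ala",
                "P", "glc_fed")
  y
}

oracle_trapz <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1L))
    s <- s + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
  s
}
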