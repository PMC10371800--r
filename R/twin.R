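# Monod-kinetic digital twin of the fed-batch reactor.
#
# States: volume V (L), viable cells Xv and dead cells Xd (1e9 cells/L),
# extracellular concentrations C_i (mmol/L) and antibody P (mg/L).
# Specific rates use the exchange sign convention (positive = secretion,
# negative = uptake), matching the FBA target tables.

#' Kinetic parameter set of the digital twin
#'
#' Canonical Monod-type CHO structure: multiplicative Monod limitation on
#' glucose, glutamine and asparagine; multiplicative lactate and ammonia
#' inhibition of growth; linear ammonia contribution to the death rate;
#' growth-linked glucose uptake with a maintenance term; lactate shift
#' from production (yield on glucose uptake) to consumption (Monod in
#' lactate) as glucose drops through a threshold, blended by a smooth
#' sigmoid; ammonia and alanine secretion yield-linked to glutamine
#' uptake; Luedeking-Piret antibody production with the non-growth term
#' gated by glucose availability. All rate laws live behind
#' [specific_rates()] so alternative forms can be swapped in.
#'
#' Units: h, L, mmol/L, 1e9 cells/L, mg/L; specific rates in
#' mmol per 1e9 cells per hour, antibody production in mg per 1e9 cells
#' per hour.
#'
#' @param mu_max Maximum specific growth rate (1/h).
#' @param K_glc,K_gln,K_asn Monod saturation constants for growth (mmol/L).
#' @param KI_lac,KI_amm Growth inhibition constants (mmol/L).
#' @param kd0 Basal specific death rate (1/h).
#' @param kd_amm Ammonia death coefficient (1/h per mmol/L).
#' @param Y_xg Biomass yield on glucose (1e9 cells/mmol); growth-linked
#'   glucose uptake is `mu / Y_xg`.
#' @param m_glc Maintenance glucose uptake ceiling (mmol/1e9 cells/h).
#' @param K_mglc Saturation constant of the maintenance term (mmol/L).
#' @param Y_lg Lactate yield on glucose uptake (mol/mol), active above the
#'   glucose switch.
#' @param q_lac_max Maximum lactate consumption rate (mmol/1e9 cells/h).
#' @param K_lac Lactate consumption saturation constant (mmol/L).
#' @param glc_switch Glucose concentration of the lactate shift (mmol/L).
#' @param switch_width Sigmoid blend width of the shift (mmol/L).
#' @param Y_xgln Biomass yield on glutamine (1e9 cells/mmol).
#' @param m_gln Maintenance glutamine uptake ceiling (mmol/1e9 cells/h).
#' @param K_mgln Saturation constant of glutamine maintenance (mmol/L).
#' @param Y_ag Ammonia yield on glutamine uptake (mol/mol).
#' @param q_asn_max Maximum asparagine uptake rate (mmol/1e9 cells/h).
#' @param K_asn_up Asparagine uptake saturation constant (mmol/L).
#' @param Y_ala Alanine secretion yield on glutamine uptake (mol/mol).
#' @param alpha Growth-associated antibody yield (mg/1e9 cells).
#' @param beta Non-growth-associated antibody production
#'   (mg/1e9 cells/h), gated by glucose availability.
#' @return Object of class `kinetic_parameters` (a validated named list).
#' @export
kinetic_parameters <- function(mu_max = 0.045,
                               K_glc = 1.0, K_gln = 0.3, K_asn = 0.3,
                               KI_lac = 40, KI_amm = 10,
                               kd0 = 0.002, kd_amm = 8e-4,
                               Y_xg = 0.3, m_glc = 0.02, K_mglc = 0.5,
                               Y_lg = 1.4, q_lac_max = 0.06, K_lac = 5,
                               glc_switch = 2.0, switch_width = 0.5,
                               Y_xgln = 1.5, m_gln = 0.004, K_mgln = 0.3,
                               Y_ag = 0.7,
                               q_asn_max = 0.02, K_asn_up = 0.5,
                               Y_ala = 0.25,
                               alpha = 2, beta = 0.4) {
  p <- as.list(environment())
  sat <- c("K_glc", "K_gln", "K_asn", "KI_lac", "KI_amm", "K_mglc",
           "K_lac", "K_mgln", "K_asn_up", "switch_width")
  for (nm in sat)
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop("saturation/inhibition constant ", nm, " must be > 0")
  if (p$mu_max <= 0) stop("mu_max must be > 0")
  if (any(!vapply(p, is.finite, NA))) stop("non-finite kinetic parameter")
  structure(p, class = "kinetic_parameters")
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat("Kinetic parameter set (", length(unclass(x)), " parameters)\n", sep = "")
  print(unlist(unclass(x)))
  invisible(x)
}

#' Extracellular species tracked by the twin
#' @return Character vector of metabolite ids.
#' @export
twin_species <- function() c("glc", "gln", "asn", "lac", "nh4", "ala")

#' Reactor state
#'
#' @param t Time (h).
#' @param V Volume (L), > 0.
#' @param Xv,Xd Viable/dead cell density (1e9 cells/L), >= 0.
#' @param C Named concentration vector (mmol/L) over [twin_species()].
#' @param P Antibody concentration (mg/L).
#' @return Object of class `reactor_state`.
#' @export
reactor_state <- function(t = 0, V, Xv, Xd = 0, C, P = 0) {
  if (V <= 0) stop("volume must be positive")
  if (Xv < 0 || Xd < 0 || P < 0) stop("cell densities and titre must be >= 0")
  miss <- setdiff(twin_species(), names(C))
  if (length(miss)) stop("missing concentration(s): ", paste(miss, collapse = ", "))
  C <- C[twin_species()]
  if (any(C < 0)) stop("concentrations must be >= 0")
  structure(list(t = t, V = V, Xv = Xv, Xd = Xd, C = C, P = P),
            class = "reactor_state")
}

#' @export
print.reactor_state <- function(x, ...) {
  cat(sprintf("Reactor state at t = %g h: V = %.4g L, Xv = %.4g, Xd = %.4g (1e9 cells/L), P = %.4g mg/L\n",
              x$t, x$V, x$Xv, x$Xd, x$P))
  print(round(x$C, 4))
  invisible(x)
}

#' Specific growth rate
#'
#' `mu = mu_max * glc/(K_glc+glc) * gln/(K_gln+gln) * asn/(K_asn+asn)
#'  * KI_lac/(KI_lac+lac) * KI_amm/(KI_amm+amm)`. Zero whenever a
#' limiting substrate is exhausted; bounded by `mu_max`.
#'
#' @param state A [reactor_state()] (or a bare named concentration vector).
#' @param p A [kinetic_parameters()].
#' @return Growth rate (1/h).
#' @export
growth_rate <- function(state, p) {
  C <- pmax(if (inherits(state, "reactor_state")) state$C else state, 0)
  p$mu_max *
    (C[["glc"]] / (p$K_glc + C[["glc"]])) *
    (C[["gln"]] / (p$K_gln + C[["gln"]])) *
    (C[["asn"]] / (p$K_asn + C[["asn"]])) *
    (p$KI_lac / (p$KI_lac + C[["lac"]])) *
    (p$KI_amm / (p$KI_amm + C[["nh4"]]))
}

#' Specific death rate
#'
#' `mu_d = kd0 + kd_amm * [amm]`: basal death plus a linear ammonia
#' contribution.
#'
#' @inheritParams growth_rate
#' @return Death rate (1/h).
#' @export
death_rate <- function(state, p) {
  C <- pmax(if (inherits(state, "reactor_state")) state$C else state, 0)
  p$kd0 + p$kd_amm * C[["nh4"]]
}

#' Specific exchange rates of the tracked metabolites
#'
#' Returns the per-cell rates in exchange sign convention (positive =
#' secretion, negative = uptake), one entry per [twin_species()]. Every
#' rate vanishes as its driving concentration vanishes; negative
#' concentrations are clipped at zero before evaluation.
#'
#' @inheritParams growth_rate
#' @return Named numeric vector (mmol/1e9 cells/h).
#' @export
specific_rates <- function(state, p) {
  C <- pmax(if (inherits(state, "reactor_state")) state$C else state, 0)
  mu <- growth_rate(C, p)
  glc <- C[["glc"]]; gln <- C[["gln"]]; asn <- C[["asn"]]
  lac <- C[["lac"]]
  q_glc_up <- mu / p$Y_xg + p$m_glc * glc / (p$K_mglc + glc)  # >= 0
  q_gln_up <- mu / p$Y_xgln + p$m_gln * gln / (p$K_mgln + gln)
  s <- 1 / (1 + exp(-(glc - p$glc_switch) / p$switch_width))  # ~1 above switch
  q_lac <- s * p$Y_lg * q_glc_up -
    (1 - s) * p$q_lac_max * lac / (p$K_lac + lac)
  c(glc = -q_glc_up,
    gln = -q_gln_up,
    asn = -p$q_asn_max * asn / (p$K_asn_up + asn),
    lac = unname(q_lac),
    nh4 = p$Y_ag * q_gln_up,
    ala = p$Y_ala * q_gln_up)
}

#' Specific antibody production rate
#'
#' Luedeking-Piret with the non-growth term gated by glucose:
#' `qP = alpha * mu + beta * glc/(K_glc+glc)` (mg/1e9 cells/h).
#'
#' @inheritParams growth_rate
#' @return Production rate (mg/1e9 cells/h).
#' @export
antibody_rate <- function(state, p) {
  C <- pmax(if (inherits(state, "reactor_state")) state$C else state, 0)
  p$alpha * growth_rate(C, p) +
    p$beta * C[["glc"]] / (p$K_glc + C[["glc"]])
}

#' Piecewise-linear feed policy
#'
#' Manipulated variables on a shared knot grid, interpolated linearly
#' between knots: glucose concentration in the feed (mmol/L), inlet flow
#' and outlet flow (L/h). Non-glucose feed concentrations are constant.
#'
#' @param knots Strictly increasing knot times (h).
#' @param C_feed_glc,F_in,F_out Numeric vectors of knot values (lengths
#'   matching `knots`, or scalars to recycle).
#' @param C_feed_other Named vector of fixed feed concentrations (mmol/L)
#'   for the non-glucose species; missing species default to 0.
#' @return Object of class `feed_policy`.
#' @export
feed_policy <- function(knots, C_feed_glc = 0, F_in = 0, F_out = 0,
                        C_feed_other = c(gln = 0, asn = 0)) {
  knots <- as.numeric(knots)
  if (length(knots) < 2L || any(diff(knots) <= 0))
    stop("policy needs >= 2 strictly increasing knot times")
  rec <- function(x) {
    x <- as.numeric(x)
    if (length(x) == 1L) rep(x, length(knots))
    else if (length(x) == length(knots)) x
    else stop("knot value length must be 1 or length(knots)")
  }
  other <- stats::setNames(numeric(length(twin_species())), twin_species())
  other[names(C_feed_other)] <- C_feed_other
  other[["glc"]] <- 0
  structure(list(knots = knots, C_feed_glc = rec(C_feed_glc),
                 F_in = rec(F_in), F_out = rec(F_out),
                 C_feed_other = other),
            class = "feed_policy")
}

#' Evaluate a feed policy at given times
#'
#' @param policy A [feed_policy()].
#' @param t Numeric vector of times within the knot span.
#' @return data.frame with columns `t`, `C_feed_glc`, `F_in`, `F_out`.
#' @export
policy_at <- function(policy, t) {
  k <- policy$knots
  if (any(t < k[1] - 1e-9) || any(t > k[length(k)] + 1e-9))
    stop("policy undefined at requested time(s): policy spans [",
         k[1], ", ", k[length(k)], "] h")
  t <- pmin(pmax(t, k[1]), k[length(k)])
  data.frame(t = t,
             C_feed_glc = stats::approx(k, policy$C_feed_glc, t)$y,
             F_in = stats::approx(k, policy$F_in, t)$y,
             F_out = stats::approx(k, policy$F_out, t)$y)
}

#' Concatenate feed policies in time
#'
#' Joins consecutive policy segments (e.g. the implemented first intervals
#' of a receding-horizon run) into one policy. Segment boundaries must
#' coincide; re-optimization steps at the seams are preserved as jump
#' discontinuities by shifting the earlier segment's end knot back by
#' 1e-9 h, so each segment's interior interpolation is unchanged.
#'
#' @param policies List of [feed_policy()] in chronological order.
#' @return A single [feed_policy()].
#' @export
concat_policies <- function(policies) {
  stopifnot(length(policies) >= 1L)
  out <- policies[[1]]
  for (pol in policies[-1]) {
    m <- length(out$knots)
    if (abs(pol$knots[1] - out$knots[m]) > 1e-9)
      stop("policy segments do not abut in time")
    jump <- any(vapply(c("C_feed_glc", "F_in", "F_out"), function(fld)
      abs(pol[[fld]][1] - out[[fld]][m]) > 1e-12, NA))
    if (jump) {
      out$knots[m] <- out$knots[m] - 1e-9
      out$knots <- c(out$knots, pol$knots)
      for (fld in c("C_feed_glc", "F_in", "F_out"))
        out[[fld]] <- c(out[[fld]], pol[[fld]])
    } else {
      out$knots <- c(out$knots[-m], pol$knots)
      for (fld in c("C_feed_glc", "F_in", "F_out"))
        out[[fld]] <- c(out[[fld]][-m], pol[[fld]])
    }
  }
  out
}

# deSolve state vector layout
pack_state <- function(state) {
  c(V = state$V, Xv = state$Xv, Xd = state$Xd, state$C, P = state$P,
    glc_fed = 0)
}

# Vectorized tracked-flux evaluation over a matrix of concentration rows
# (columns in twin_species() order). Returns cbind(biomass, q columns).
rates_matrix <- function(Cmat, p) {
  Cmat <- pmax(Cmat, 0)
  glc <- Cmat[, 1L]; gln <- Cmat[, 2L]; asn <- Cmat[, 3L]
  lac <- Cmat[, 4L]; nh4 <- Cmat[, 5L]
  mu <- p$mu_max * (glc / (p$K_glc + glc)) * (gln / (p$K_gln + gln)) *
    (asn / (p$K_asn + asn)) * (p$KI_lac / (p$KI_lac + lac)) *
    (p$KI_amm / (p$KI_amm + nh4))
  q_glc_up <- mu / p$Y_xg + p$m_glc * glc / (p$K_mglc + glc)
  q_gln_up <- mu / p$Y_xgln + p$m_gln * gln / (p$K_mgln + gln)
  s <- 1 / (1 + exp(-(glc - p$glc_switch) / p$switch_width))
  cbind(biomass = mu,
        glc = -q_glc_up,
        gln = -q_gln_up,
        asn = -p$q_asn_max * asn / (p$K_asn_up + asn),
        lac = s * p$Y_lg * q_glc_up -
          (1 - s) * p$q_lac_max * lac / (p$K_lac + lac),
        nh4 = p$Y_ag * q_gln_up,
        ala = p$Y_ala * q_gln_up)
}

# Fast linear interpolators for the three manipulated profiles.
policy_interp <- function(policy) {
  list(cglc = stats::approxfun(policy$knots, policy$C_feed_glc, rule = 2),
       fin = stats::approxfun(policy$knots, policy$F_in, rule = 2),
       fout = stats::approxfun(policy$knots, policy$F_out, rule = 2),
       cfo = policy$C_feed_other,
       span = range(policy$knots))
}

# Lean rate+balance core shared by the public rhs and the integrator.
# y = (V, Xv, Xd, C[species], P, glc_fed); small negative concentrations
# from the integrator are clipped at zero in the rate laws.
rhs_core <- function(t, y, p, ip) {
  V <- y[[1L]]; Xv <- y[[2L]]; Xd <- y[[3L]]
  nC <- 6L
  C <- pmax(y[4L:(3L + nC)], 0)
  P <- y[[4L + nC]]
  glc <- C[[1L]]; gln <- C[[2L]]; asn <- C[[3L]]
  lac <- C[[4L]]; nh4 <- C[[5L]]; ala <- C[[6L]]
  mu <- p$mu_max * (glc / (p$K_glc + glc)) * (gln / (p$K_gln + gln)) *
    (asn / (p$K_asn + asn)) * (p$KI_lac / (p$KI_lac + lac)) *
    (p$KI_amm / (p$KI_amm + nh4))
  mud <- p$kd0 + p$kd_amm * nh4
  q_glc_up <- mu / p$Y_xg + p$m_glc * glc / (p$K_mglc + glc)
  q_gln_up <- mu / p$Y_xgln + p$m_gln * gln / (p$K_mgln + gln)
  s <- 1 / (1 + exp(-(glc - p$glc_switch) / p$switch_width))
  q <- c(-q_glc_up,
         -q_gln_up,
         -p$q_asn_max * asn / (p$K_asn_up + asn),
         s * p$Y_lg * q_glc_up - (1 - s) * p$q_lac_max * lac / (p$K_lac + lac),
         p$Y_ag * q_gln_up,
         p$Y_ala * q_gln_up)
  qP <- p$alpha * mu + p$beta * glc / (p$K_glc + glc)
  F_in <- ip$fin(t); F_out <- ip$fout(t); cglc <- ip$cglc(t)
  Cf <- ip$cfo
  Cf[[1L]] <- cglc
  dil <- F_in / V
  c(F_in - F_out,
    (mu - mud) * Xv - dil * Xv,
    mud * Xv - dil * Xd,
    dil * (Cf - C) + q * Xv,
    qP * Xv - dil * P,
    F_in * cglc)
}

#' Twin mass-balance right-hand side
#'
#' `dV/dt = F_in - F_out`; `d(V Xv)/dt = (mu - mu_d) V Xv - F_out Xv`;
#' `d(V C_i)/dt = F_in C_feed_i - F_out C_i + q_i Xv V`;
#' `d(V P)/dt = (alpha mu + beta_g) Xv V - F_out P`. Integrated in the
#' expanded concentration form (dilution terms). An auxiliary state
#' accumulates the glucose fed, `F_in * C_feed_glc`.
#'
#' @param state A [reactor_state()].
#' @param policy A [feed_policy()] defined at `state$t`.
#' @param p A [kinetic_parameters()].
#' @return Named derivative vector over `(V, Xv, Xd, C..., P, glc_fed)`.
#' @export
twin_rhs <- function(state, policy, p) {
  k <- policy$knots
  if (state$t < k[1] - 1e-9 || state$t > k[length(k)] + 1e-9)
    stop("policy undefined at t = ", state$t, " h (policy spans [",
         k[1], ", ", k[length(k)], "])")
  y <- pack_state(state)
  stats::setNames(rhs_core(state$t, y, p, policy_interp(policy)), names(y))
}

#' Simulate the digital twin
#'
#' Adaptive stiff-capable integration (deSolve, lsoda) of the twin mass
#' balances under a feed policy. Concentrations are clipped at zero in
#' the rate laws; output points where the integrator state dipped below
#' `-1e-9` are recorded in the `clip_events` attribute.
#'
#' @param x0 Initial [reactor_state()].
#' @param policy A [feed_policy()] spanning `[x0$t, t_end]`.
#' @param p A [kinetic_parameters()].
#' @param t_end End time (h), > `x0$t`.
#' @param output_dt Output grid spacing (h), default 1.
#' @param rtol,atol Integrator tolerances (default 1e-8).
#' @return Object of class `twin_trajectory`: `grid` (times), `states`
#'   (data.frame of V, Xv, Xd, concentrations, P), `fluxes` (matrix of
#'   realised specific fluxes incl. `biomass`, exchange sign convention;
#'   zero where no viable cells), `totals` (cumulative glucose fed in
#'   mmol, integrated viable cell density in 1e9 cells h/L, final
#'   antibody mass in mg).
#' @export
simulate_twin <- function(x0, policy, p, t_end, output_dt = 1,
                          rtol = 1e-8, atol = 1e-8) {
  stopifnot(inherits(x0, "reactor_state"), inherits(policy, "feed_policy"),
            inherits(p, "kinetic_parameters"))
  if (t_end <= x0$t) stop("t_end must exceed the initial time")
  k <- policy$knots
  if (k[1] > x0$t + 1e-9 || k[length(k)] < t_end - 1e-9)
    stop("policy must span the simulation window [", x0$t, ", ", t_end, "] h")
  times <- unique(c(seq(x0$t, t_end, by = output_dt), t_end))
  y0 <- pack_state(x0)
  pv <- c(as.numeric(unlist(unclass(p))), policy$C_feed_other)
  k <- policy$knots
  forcings <- list(cbind(k, policy$C_feed_glc),
                   cbind(k, policy$F_in),
                   cbind(k, policy$F_out))
  sol <- deSolve::ode(y = y0, times = times, func = "twin_derivs",
                      parms = pv, dllname = "fluxmpc",
                      initfunc = "twin_init", initforc = "twin_forc",
                      forcings = forcings,
                      fcontrol = list(method = "linear", rule = 2),
                      method = "lsoda",
                      rtol = rtol, atol = atol, maxsteps = 100000)
  if (attr(sol, "istate")[1] < 0)
    stop("twin integration failed at t = ", max(sol[, "time"]),
         " h; last good state retained in the error condition")
  out <- as.data.frame(sol)
  names(out)[1] <- "t"
  nC <- length(twin_species())
  conc_cols <- twin_species()
  clip <- which(apply(out[conc_cols] < -1e-9, 1, any))
  out[conc_cols] <- pmax(as.matrix(out[conc_cols]), 0)
  out$Xv <- pmax(out$Xv, 0); out$Xd <- pmax(out$Xd, 0)
  out$P <- pmax(out$P, 0)
  fluxes <- rates_matrix(as.matrix(out[conc_cols]), p)
  fluxes[out$Xv <= 1e-12, ] <- 0
  grid <- out$t
  ivcd <- sum(diff(grid) * (utils::head(out$Xv, -1) + utils::tail(out$Xv, -1)) / 2)
  totals <- list(glucose_fed = out$glc_fed[nrow(out)],
                 IVCD = ivcd,
                 antibody_mass = out$P[nrow(out)] * out$V[nrow(out)])
  structure(list(grid = grid,
                 states = out[c("t", "V", "Xv", "Xd", conc_cols, "P", "glc_fed")],
                 fluxes = fluxes, totals = totals,
                 policy = policy, parameters = p),
            class = "twin_trajectory",
            clip_events = grid[clip])
}

#' Realised specific fluxes of a trajectory
#'
#' The tracked flux series in the same ids, units and sign convention as
#' the stage target table: `biomass` (= mu, 1/h) plus one column per
#' extracellular species (mmol/1e9 cells/h). Zero where the culture has
#' no viable cells.
#'
#' @param traj A `twin_trajectory`.
#' @return Matrix `length(grid) x (1 + n species)`.
#' @export
observed_fluxes <- function(traj) {
  stopifnot(inherits(traj, "twin_trajectory"))
  traj$fluxes
}

#' Final-state accessor
#' @param traj A `twin_trajectory`.
#' @return The [reactor_state()] at the last output point.
#' @export
final_state <- function(traj) {
  s <- traj$states[nrow(traj$states), ]
  C <- as.numeric(s[twin_species()]); names(C) <- twin_species()
  reactor_state(t = s$t, V = s$V, Xv = s$Xv, Xd = s$Xd, C = C, P = s$P)
}

#' @export
print.twin_trajectory <- function(x, ...) {
  n <- nrow(x$states)
  cat(sprintf("Twin trajectory: %d points over [%g, %g] h\n",
              n, x$grid[1], x$grid[n]))
  cat(sprintf("  final: V = %.4g L, Xv = %.4g 1e9/L, P = %.4g mg/L, antibody mass = %.6g mg\n",
              x$states$V[n], x$states$Xv[n], x$states$P[n],
              x$totals$antibody_mass))
  cat(sprintf("  glucose fed = %.6g mmol, IVCD = %.5g 1e9 cells.h/L\n",
              x$totals$glucose_fed, x$totals$IVCD))
  invisible(x)
}

#' Write a trajectory to CSV (wide and tidy forms)
#'
#' @param traj A `twin_trajectory`.
#' @param path Output path for the wide CSV; a `_tidy.csv` sibling and a
#'   `_totals.json` summary are written next to it.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(traj$states, path, row.names = FALSE)
  tidy <- stats::reshape(traj$states, direction = "long",
                         varying = setdiff(names(traj$states), "t"),
                         v.names = "value",
                         times = setdiff(names(traj$states), "t"),
                         timevar = "variable", idvar = "t")
  tidy <- tidy[order(tidy$t), c("t", "variable", "value")]
  base <- sub("\\.csv$", "", path)
  utils::write.csv(tidy, paste0(base, "_tidy.csv"), row.names = FALSE)
  jsonlite::write_json(traj$totals, paste0(base, "_totals.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
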