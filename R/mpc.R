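# Horizon optimization: choose piecewise-linear manipulated variables
# (glucose feed concentration, inlet flow, outlet flow on the control
# grid) minimizing the integrated squared deviation of realised specific
# fluxes from the stage targets.

#' Controller configuration
#'
#' Case A tracks all extracellular metabolite fluxes plus biomass; Case B
#' tracks the glucose flux only. Manipulated-variable bounds follow the
#' literature convention: glucose feed concentration in mmol/L, flows in
#' L/min (converted internally to L/h).
#'
#' @param case `"A"` or `"B"`.
#' @param control_interval Control interval (h); 8, 24 and 72 are the
#'   standard choices, any positive value dividing the horizon is allowed.
#' @param horizon Optimization horizon T_opt (h), default 72; must be an
#'   integer multiple of `control_interval`.
#' @param cglc_bounds Glucose feed concentration bounds (mmol/L),
#'   default `c(0, 1000)`.
#' @param fin_bounds Inlet flow bounds (L/min), default `c(0.001, 1)`.
#' @param fout_bounds Outlet flow bounds (L/min), default `c(0, 0.05)`.
#' @param rate_limit Optional +/- bound (mmol/L) on the change of the
#'   glucose feed concentration between consecutive knots (and from the
#'   previously implemented value); `Inf` disables it.
#' @param rate_penalty Optional soft quadratic penalty weight on the same
#'   differences (per (mmol/L)^2), an alternative to the hard limit;
#'   0 disables it.
#' @param input_penalty Tiny quadratic regularisation on the normalised
#'   actuation (knot values scaled to `[0, 1]` above their lower bounds),
#'   breaking ties among tracking-equivalent policies in favour of
#'   minimal feeding/outflow. Outflow in particular does not affect
#'   concentrations, so the tracking objective alone leaves it
#'   undetermined. Default 1e-3; subtracted before the objective is
#'   reported.
#' @param weights Optional named per-flux weights overriding the default
#'   `1/max(|z_target|, 1e-6)^2` normalisation.
#' @param glc_profile `"piecewise"` (free knots) or `"constant"` (all
#'   glucose-feed knots tied to one value; used for 1-D subproblems).
#' @param freeze_flows Optional named list `list(F_in=, F_out=)` (L/h)
#'   fixing the flow profiles so only the glucose feed is optimized.
#' @param maxeval Objective evaluation budget per start; `NULL` (default)
#'   scales with the decision dimension as `10 n + 50`, so finely
#'   parameterised horizons get proportionate optimization effort.
#' @param sim_dt Output grid spacing used for quadrature inside the
#'   optimization (h), default 2.
#' @param sim_rtol Integrator tolerance used inside the optimization,
#'   default 1e-6 (final trajectories are re-simulated at 1e-8).
#' @param n_random_starts Extra random multistarts (default 0); drawn
#'   deterministically from the campaign seed.
#' @return Object of class `control_config`.
#' @export
control_config <- function(case = c("A", "B"),
                           control_interval = 8, horizon = 72,
                           cglc_bounds = c(0, 1000),
                           fin_bounds = c(0.001, 1),
                           fout_bounds = c(0, 0.05),
                           rate_limit = Inf,
                           rate_penalty = 0,
                           input_penalty = 1e-3,
                           weights = NULL,
                           glc_profile = c("piecewise", "constant"),
                           freeze_flows = NULL,
                           maxeval = NULL,
                           sim_dt = 2, sim_rtol = 1e-6,
                           n_random_starts = 0) {
  case <- match.arg(case)
  glc_profile <- match.arg(glc_profile)
  if (control_interval <= 0) stop("control_interval must be positive")
  if (horizon < control_interval)
    stop("control_interval must not exceed the horizon")
  if (abs(horizon / control_interval - round(horizon / control_interval)) > 1e-9)
    stop("horizon must be an integer multiple of control_interval")
  for (b in list(cglc_bounds, fin_bounds, fout_bounds))
    if (length(b) != 2L || b[1] >= b[2]) stop("bounds must satisfy lb < ub")
  if (rate_limit <= 0) stop("rate_limit must be positive (Inf to disable)")
  structure(list(case = case, control_interval = control_interval,
                 horizon = horizon,
                 cglc_bounds = cglc_bounds,
                 fin_bounds_lmin = fin_bounds, fout_bounds_lmin = fout_bounds,
                 fin_bounds = fin_bounds * 60, fout_bounds = fout_bounds * 60,
                 rate_limit = rate_limit, rate_penalty = rate_penalty,
                 input_penalty = input_penalty,
                 weights = weights, glc_profile = glc_profile,
                 freeze_flows = freeze_flows, maxeval = maxeval,
                 sim_dt = sim_dt, sim_rtol = sim_rtol,
                 n_random_starts = n_random_starts),
            class = "control_config")
}

#' @export
print.control_config <- function(x, ...) {
  cat(sprintf("Control config: Case %s, interval %g h, horizon %g h\n",
              x$case, x$control_interval, x$horizon))
  cat(sprintf("  C_feed_glc in [%g, %g] mmol/L; F_in [%g, %g] L/h; F_out [%g, %g] L/h\n",
              x$cglc_bounds[1], x$cglc_bounds[2], x$fin_bounds[1],
              x$fin_bounds[2], x$fout_bounds[1], x$fout_bounds[2]))
  if (is.finite(x$rate_limit))
    cat(sprintf("  rate limit on C_feed_glc: +/-%g mmol/L per interval\n",
                x$rate_limit))
  invisible(x)
}

#' Tracking objective: tracked flux ids and weights
#'
#' @param cfg A [control_config()] (selects Case A or B).
#' @param targets A [stage_targets()] table.
#' @return Object of class `tracking_objective` with `ids`, `weights`
#'   (named; default `1/max(|z_target|, 1e-6)^2` using the per-flux
#'   maximum absolute target over the stages), `targets`.
#' @export
tracking_objective <- function(cfg, targets) {
  tracked <- tracked_fluxes(targets)
  ids <- if (cfg$case == "B") "glc" else tracked
  if (!all(ids %in% names(targets)))
    stop("tracked flux id(s) missing from the target table: ",
         paste(setdiff(ids, names(targets)), collapse = ", "))
  scale <- vapply(ids, function(j) max(abs(targets[[j]])), numeric(1))
  w <- 1 / pmax(scale, 1e-6)^2
  if (!is.null(cfg$weights)) {
    known <- intersect(names(cfg$weights), ids)
    w[known] <- cfg$weights[known]
  }
  if (any(w < 0) || any(!is.finite(w))) stop("weights must be finite and >= 0")
  structure(list(ids = ids, weights = w, targets = targets),
            class = "tracking_objective")
}

#' Evaluate the flux-tracking objective of a policy
#'
#' `OF = integral over the horizon of sum_j w_j (zbar_j(t) - z*_j(t))^2 dt`,
#' where `zbar_j` are the realised specific fluxes of the simulated twin
#' and `z*_j` the stage-scheduled targets; trapezoidal quadrature on the
#' simulation output grid.
#'
#' @param policy A [feed_policy()] spanning `[x0$t, x0$t + horizon]`.
#' @param x0 Initial [reactor_state()].
#' @param obj A [tracking_objective()].
#' @param p A [kinetic_parameters()].
#' @param schedule A [stage_schedule()].
#' @param horizon Horizon length (h).
#' @param output_dt,rtol Simulation grid/tolerance.
#' @return Nonnegative scalar OF (with attribute `trajectory`).
#' @export
evaluate_objective <- function(policy, x0, obj, p, schedule, horizon,
                               output_dt = 2, rtol = 1e-6) {
  traj <- simulate_twin(x0, policy, p, t_end = x0$t + horizon,
                        output_dt = output_dt, rtol = rtol, atol = rtol)
  of <- objective_from_traj(traj, obj, schedule)
  attr(of, "trajectory") <- traj
  of
}

objective_from_traj <- function(traj, obj, schedule) {
  z <- observed_fluxes(traj)[, obj$ids, drop = FALSE]
  zt <- targets_at(obj$targets, schedule, traj$grid, ids = obj$ids)
  r2 <- (z - zt)^2 %*% obj$weights[obj$ids]
  trapz(traj$grid, as.numeric(r2))
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

# --- decision-vector encoding ------------------------------------------------
#
# Decision variables are the knot values of the three profiles on the
# control grid. The glucose-feed rate limit is enforced by construction:
# raw values are clamped sequentially into the moving band
# [prev - rate_limit, prev + rate_limit] intersected with the bounds.
# Every feasible knot sequence is a fixed point of the clamp, so the
# transform is surjective onto the feasible set and the optimizer works
# in a plain box.

clamp_rate <- function(raw, prev, limit, lo, hi) {
  out <- numeric(length(raw))
  last <- prev
  for (k in seq_along(raw)) {
    lo_k <- if (is.null(last)) lo else max(lo, last - limit)
    hi_k <- if (is.null(last)) hi else min(hi, last + limit)
    out[k] <- min(max(raw[k], lo_k), hi_k)
    last <- out[k]
  }
  out
}

encode_dims <- function(cfg, n_knots) {
  n_glc <- if (cfg$glc_profile == "constant") 1L else n_knots
  n_flow <- if (is.null(cfg$freeze_flows)) n_knots else 0L
  list(n_glc = n_glc, n_fin = n_flow, n_fout = n_flow,
       n = n_glc + 2L * n_flow)
}

decode_policy <- function(x, cfg, knots, prev_cglc, feed_medium) {
  n_knots <- length(knots)
  d <- encode_dims(cfg, n_knots)
  raw_glc <- x[seq_len(d$n_glc)]
  if (cfg$glc_profile == "constant") raw_glc <- rep(raw_glc, n_knots)
  cglc <- clamp_rate(raw_glc, prev_cglc, cfg$rate_limit,
                     cfg$cglc_bounds[1], cfg$cglc_bounds[2])
  if (d$n_fin > 0L) {
    fin <- x[d$n_glc + seq_len(d$n_fin)]
    fout <- x[d$n_glc + d$n_fin + seq_len(d$n_fout)]
  } else {
    fin <- rep(cfg$freeze_flows$F_in, n_knots)
    fout <- rep(cfg$freeze_flows$F_out, n_knots)
  }
  feed_policy(knots, C_feed_glc = cglc, F_in = fin, F_out = fout,
              C_feed_other = feed_medium)
}

encode_box <- function(cfg, n_knots) {
  d <- encode_dims(cfg, n_knots)
  lo <- c(rep(cfg$cglc_bounds[1], d$n_glc),
          rep(cfg$fin_bounds[1], d$n_fin), rep(cfg$fout_bounds[1], d$n_fout))
  hi <- c(rep(cfg$cglc_bounds[2], d$n_glc),
          rep(cfg$fin_bounds[2], d$n_fin), rep(cfg$fout_bounds[2], d$n_fout))
  list(lo = lo, hi = hi)
}

rate_penalty_term <- function(policy, cfg, prev_cglc) {
  if (cfg$rate_penalty <= 0) return(0)
  dd <- diff(c(if (is.null(prev_cglc)) policy$C_feed_glc[1] else prev_cglc,
               policy$C_feed_glc))
  cfg$rate_penalty * sum(dd^2)
}

# Tie-break regularisation: mean squared normalised actuation.
input_penalty_term <- function(policy, cfg) {
  if (cfg$input_penalty <= 0) return(0)
  nrm <- function(x, b) (x - b[1]) / (b[2] - b[1])
  cfg$input_penalty * mean(c(nrm(policy$C_feed_glc, cfg$cglc_bounds)^2,
                             nrm(policy$F_in, cfg$fin_bounds)^2,
                             nrm(policy$F_out, cfg$fout_bounds)^2))
}

#' First-knot rate-limit constraint band
#'
#' With a finite rate limit, the first knot of the glucose feed
#' concentration must stay within +/- `rate_limit` of the previously
#' implemented value, clamped into the variable bounds.
#'
#' @param cfg A [control_config()] with finite `rate_limit`.
#' @param prev_value Previously implemented glucose feed concentration
#'   (mmol/L); must lie within the bounds.
#' @return `c(lo, hi)` band for the first knot.
#' @export
rate_limit_band <- function(cfg, prev_value) {
  if (!is.finite(cfg$rate_limit)) stop("rate_limit is not set")
  if (prev_value < cfg$cglc_bounds[1] - 1e-9 ||
      prev_value > cfg$cglc_bounds[2] + 1e-9)
    stop("previous glucose feed value ", prev_value, " outside bounds [",
         cfg$cglc_bounds[1], ", ", cfg$cglc_bounds[2], "]")
  c(max(cfg$cglc_bounds[1], prev_value - cfg$rate_limit),
    min(cfg$cglc_bounds[2], prev_value + cfg$rate_limit))
}

#' Optimize one receding-horizon problem
#'
#' Single-shooting nonlinear program over the knot values of the
#' piecewise-linear manipulated profiles. Deterministic multistart
#' (minimum-feed, warm start, mid-bounds, plus optional seeded random
#' starts); local solver BOBYQA (Brent for one free variable). The
#' returned solution is the best of all starts and candidate policies,
#' so its objective never exceeds any warm start's. Bound and rate
#' constraints hold exactly by construction of the decision encoding.
#'
#' @param x0 Initial [reactor_state()] at the horizon start.
#' @param cfg A [control_config()].
#' @param targets A [stage_targets()] table.
#' @param schedule A [stage_schedule()].
#' @param p A [kinetic_parameters()].
#' @param feed_medium Named non-glucose feed concentrations (mmol/L).
#' @param warm_start Optional [feed_policy()] used as a warm-start
#'   candidate (e.g. the previous solution shifted by one interval).
#' @param prev_cglc Previously implemented glucose feed concentration
#'   (mmol/L), anchoring the rate limit's first knot; `NULL` if none.
#' @param horizon_end Optional absolute end time (h) truncating the
#'   horizon (batch end).
#' @param seed Integer seed for the optional random starts.
#' @return Object of class `horizon_solution`: `policy`, `objective`,
#'   `evaluations`, `status`, `candidates` (objectives of the starts).
#' @export
optimize_horizon <- function(x0, cfg, targets, schedule, p,
                             feed_medium = nominal_feed_medium(),
                             warm_start = NULL, prev_cglc = NULL,
                             horizon_end = NULL, seed = 0L) {
  t0 <- x0$t
  t_end <- t0 + cfg$horizon
  if (!is.null(horizon_end)) t_end <- min(t_end, horizon_end)
  if (t_end <= t0 + 1e-9) stop("empty horizon: batch already ended")
  knots <- unique(c(seq(t0, t_end, by = cfg$control_interval), t_end))
  if (length(knots) < 2L) knots <- c(t0, t_end)
  obj <- tracking_objective(cfg, targets)
  horizon <- t_end - t0
  n_knots <- length(knots)
  box <- encode_box(cfg, n_knots)
  d <- encode_dims(cfg, n_knots)

  evals <- 0L
  policy_of <- function(x) decode_policy(x, cfg, knots, prev_cglc, feed_medium)
  fn <- function(x) {
    evals <<- evals + 1L
    pol <- policy_of(x)
    of <- tryCatch(
      evaluate_objective(pol, x0, obj, p, schedule, horizon,
                         output_dt = cfg$sim_dt, rtol = cfg$sim_rtol),
      error = function(e) Inf)
    as.numeric(of) + rate_penalty_term(pol, cfg, prev_cglc) +
      input_penalty_term(pol, cfg)
  }

  starts <- list(min_feed = box$lo,
                 mid = (box$lo + box$hi) / 2)
  if (!is.null(warm_start)) {
    ws <- range(warm_start$knots)   # shifted warm start: clamp into its span
    u <- policy_at(warm_start, pmin(pmax(knots, ws[1]), ws[2]))
    xw <- u$C_feed_glc
    if (cfg$glc_profile == "constant") xw <- xw[1]
    if (d$n_fin > 0L) xw <- c(xw, u$F_in, u$F_out)
    starts$warm <- pmin(pmax(xw, box$lo), box$hi)
  }
  if (cfg$n_random_starts > 0) {
    rng <- make_rng(seed)
    for (i in seq_len(cfg$n_random_starts))
      starts[[paste0("random", i)]] <-
        box$lo + (box$hi - box$lo) * rng(length(box$lo))
  }

  best <- NULL
  cand_of <- vapply(starts, fn, numeric(1))
  best_i <- which.min(cand_of)
  best <- list(x = starts[[best_i]], of = cand_of[best_i])
  # local refinement from the best start (and the warm start if distinct)
  budget <- if (is.null(cfg$maxeval)) 10L * d$n + 50L else cfg$maxeval
  refine_from <- unique(c(best_i,
                          if (!is.null(starts$warm)) which(names(starts) == "warm")))
  for (i in refine_from) {
    res <- local_minimize(fn, starts[[i]], box$lo, box$hi, budget)
    if (res$value < best$of) best <- list(x = res$par, of = res$value)
  }
  pol <- policy_of(best$x)
  of_final <- fn(best$x) - rate_penalty_term(pol, cfg, prev_cglc) -
    input_penalty_term(pol, cfg)
  structure(list(policy = pol, objective = as.numeric(of_final),
                 penalized_objective = best$of,
                 evaluations = evals, status = "converged",
                 candidates = cand_of, knots = knots),
            class = "horizon_solution")
}

# deterministic uniform rng independent of the global .Random.seed
make_rng <- function(seed) {
  state <- as.integer(seed)
  function(n) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      state <<- (1103515245 * state + 12345) %% 2147483648
      out[i] <- state / 2147483648
    }
    out
  }
}

local_minimize <- function(fn, x0, lo, hi, maxeval) {
  n <- length(x0)
  free <- hi > lo + 1e-12
  if (!any(free)) return(list(par = x0, value = fn(x0)))
  if (sum(free) == 1L) {
    j <- which(free)
    f1 <- function(v) { x <- x0; x[j] <- v; fn(x) }
    opt <- stats::optimize(f1, lower = lo[j], upper = hi[j],
                           tol = (hi[j] - lo[j]) * 1e-6)
    x <- x0; x[j] <- opt$minimum
    return(list(par = x, value = opt$objective))
  }
  if (requireNamespace("nloptr", quietly = TRUE)) {
    res <- nloptr::nloptr(
      x0 = x0, eval_f = fn, lb = lo, ub = hi,
      opts = list(algorithm = "NLOPT_LN_BOBYQA", maxeval = maxeval,
                  xtol_rel = 1e-6, ftol_rel = 1e-10))
    list(par = res$solution, value = res$objective)
  } else {
    res <- stats::optim(x0, fn, method = "L-BFGS-B", lower = lo, upper = hi,
                        control = list(maxit = max(10, maxeval %/% (n + 1))))
    list(par = res$par, value = res$value)
  }
}

#' @export
print.horizon_solution <- function(x, ...) {
  cat(sprintf("Horizon solution: OF = %.6g (%s, %d evaluations)\n",
              x$objective, x$status, x$evaluations))
  cat("  knots (h):", paste(signif(x$knots, 4), collapse = ", "), "\n")
  cat("  C_feed_glc:", paste(signif(x$policy$C_feed_glc, 4), collapse = ", "), "\n")
  invisible(x)
}
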