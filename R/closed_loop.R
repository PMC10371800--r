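# Receding-horizon closed loop against the digital twin:
# measure -> optimize -> implement the first control interval -> repeat,
# plus the open-loop baseline runner and comparison metrics.

#' Campaign configuration
#'
#' @param batch_end Batch duration (h); must equal the last schedule
#'   breakpoint.
#' @param schedule A [stage_schedule()].
#' @param cfg A [control_config()].
#' @param p A [kinetic_parameters()].
#' @param x0 Initial [reactor_state()].
#' @param targets A [stage_targets()] table.
#' @param baseline A [feed_policy()] spanning the batch (open-loop
#'   reference).
#' @param feed_medium Named non-glucose feed concentrations (mmol/L).
#' @param reoptimize `"interval"` (every control interval; default) or
#'   `"stage"` (once per culture stage).
#' @param initial_cglc Glucose feed concentration (mmol/L) implemented
#'   before the first cycle; anchors the rate-of-change limit's first
#'   knot. Default 0 (no feed running at inoculation).
#' @param seed Integer seed forwarded to the optimizer's random starts.
#' @return Object of class `campaign_config`.
#' @export
campaign_config <- function(batch_end = 360,
                            schedule = stage_schedule(),
                            cfg = control_config(),
                            p = nominal_parameters(),
                            x0 = nominal_state(),
                            targets,
                            baseline = baseline_policy(batch_end),
                            feed_medium = nominal_feed_medium(),
                            reoptimize = c("interval", "stage"),
                            initial_cglc = 0,
                            seed = 0L) {
  reoptimize <- match.arg(reoptimize)
  bp <- schedule$breakpoints
  if (abs(batch_end - bp[length(bp)]) > 1e-9)
    stop("batch_end must equal the last stage-schedule breakpoint")
  if (baseline$knots[1] > x0$t + 1e-9 ||
      baseline$knots[length(baseline$knots)] < batch_end - 1e-9)
    stop("baseline policy must span the batch")
  structure(list(batch_end = batch_end, schedule = schedule, cfg = cfg,
                 p = p, x0 = x0, targets = targets, baseline = baseline,
                 feed_medium = feed_medium, reoptimize = reoptimize,
                 initial_cglc = initial_cglc,
                 seed = as.integer(seed)),
            class = "campaign_config")
}

campaign_metrics <- function(traj, baseline_traj = NULL) {
  n <- nrow(traj$states)
  m <- list(antibody_mass = traj$states$P[n] * traj$states$V[n],
            antibody_conc = traj$states$P[n],
            glucose_fed = traj$totals$glucose_fed,
            IVCD = traj$totals$IVCD,
            final_volume = traj$states$V[n])
  if (!is.null(baseline_traj)) {
    nb <- nrow(baseline_traj$states)
    base_mass <- baseline_traj$states$P[nb] * baseline_traj$states$V[nb]
    base_conc <- baseline_traj$states$P[nb]
    m$improvement_mass_pct <- 100 * (m$antibody_mass - base_mass) / base_mass
    m$improvement_conc_pct <- 100 * (m$antibody_conc - base_conc) / base_conc
  }
  m
}

#' Run the receding-horizon closed loop
#'
#' At each control-interval boundary the twin state is read, a horizon
#' problem is solved ([optimize_horizon()], horizon truncated at batch
#' end), only the first interval of the optimal policy is implemented,
#' and the twin advances one interval. The concatenated implemented
#' segments form one continuous [feed_policy()]. Deterministic for a
#' fixed seed.
#'
#' @param cc A [campaign_config()].
#' @param verbose Print per-cycle progress.
#' @return Object of class `campaign_result`: `trajectory` (full-batch
#'   twin trajectory under the implemented policy, integrated at the
#'   reporting tolerance), `implemented_policy`, `cycles` (per-cycle
#'   [optimize_horizon()] solutions), `metrics`, `config`.
#' @export
run_closed_loop <- function(cc, verbose = FALSE) {
  stopifnot(inherits(cc, "campaign_config"))
  cfg <- cc$cfg
  t_grid <- seq(cc$x0$t, cc$batch_end, by = cfg$control_interval)
  if (t_grid[length(t_grid)] < cc$batch_end - 1e-9)
    t_grid <- c(t_grid, cc$batch_end)
  state <- cc$x0
  segments <- list()
  cycles <- list()
  warm <- NULL
  prev_cglc <- cc$initial_cglc
  glc_fed <- 0
  for (k in seq_len(length(t_grid) - 1L)) {
    t_a <- t_grid[k]; t_b <- t_grid[k + 1L]
    reuse <- cc$reoptimize == "stage" && k > 1L &&
      stage_at(cc$schedule, t_a) == stage_at(cc$schedule, t_grid[k - 1L])
    if (reuse) {
      sol <- cycles[[length(cycles)]]$solution
    } else {
      sol <- tryCatch(
        optimize_horizon(state, cfg, cc$targets, cc$schedule, cc$p,
                         feed_medium = cc$feed_medium, warm_start = warm,
                         prev_cglc = prev_cglc, horizon_end = cc$batch_end,
                         seed = cc$seed + k),
        error = function(e)
          stop("closed loop aborted at cycle ", k, " (t = ", t_a,
               " h): ", conditionMessage(e), call. = FALSE))
    }
    seg_t <- c(t_a, t_b)
    u <- policy_at(sol$policy, seg_t)
    seg <- feed_policy(seg_t, C_feed_glc = u$C_feed_glc, F_in = u$F_in,
                       F_out = u$F_out, C_feed_other = cc$feed_medium)
    traj <- simulate_twin(state, seg, cc$p, t_end = t_b,
                          output_dt = cfg$sim_dt,
                          rtol = cfg$sim_rtol, atol = cfg$sim_rtol)
    glc_fed <- glc_fed + traj$totals$glucose_fed
    state <- final_state(traj)
    segments[[k]] <- seg
    cycles[[k]] <- list(t = t_a, solution = sol, state_end = state)
    warm <- sol$policy
    prev_cglc <- u$C_feed_glc[length(u$C_feed_glc)]
    if (verbose)
      message(sprintf("cycle %d  t=%5.0f h  OF=%.4g  Xv=%.3g  P=%.3g",
                      k, t_a, sol$objective, state$Xv, state$P))
  }
  implemented <- concat_policies(segments)
  # reporting-quality replay of the implemented policy from the start
  traj <- simulate_twin(cc$x0, implemented, cc$p, t_end = cc$batch_end,
                        output_dt = 1, rtol = 1e-8, atol = 1e-8)
  structure(list(trajectory = traj, implemented_policy = implemented,
                 cycles = cycles, metrics = campaign_metrics(traj),
                 config = cc, kind = "closed_loop"),
            class = "campaign_result")
}

#' Run an open-loop campaign (pure simulation + metrics)
#'
#' @param cc A [campaign_config()].
#' @param policy A [feed_policy()] spanning the batch; defaults to the
#'   configured baseline.
#' @return A `campaign_result` (no cycles).
#' @export
run_open_loop <- function(cc, policy = cc$baseline) {
  stopifnot(inherits(cc, "campaign_config"))
  traj <- simulate_twin(cc$x0, policy, cc$p, t_end = cc$batch_end,
                        output_dt = 1, rtol = 1e-8, atol = 1e-8)
  structure(list(trajectory = traj, implemented_policy = policy,
                 cycles = list(), metrics = campaign_metrics(traj),
                 config = cc, kind = "open_loop"),
            class = "campaign_result")
}

#' @export
print.campaign_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("%s campaign: antibody %.6g mg (%.4g mg/L), glucose fed %.6g mmol\n",
              if (x$kind == "closed_loop") "Closed-loop" else "Open-loop",
              m$antibody_mass, m$antibody_conc, m$glucose_fed))
  if (length(x$cycles))
    cat(sprintf("  %d optimization cycles (Case %s, interval %g h)\n",
                length(x$cycles), x$config$cfg$case,
                x$config$cfg$control_interval))
  invisible(x)
}

#' Compare campaigns
#'
#' @param results Named list of >= 2 `campaign_result`s on the same twin
#'   parameters.
#' @param baseline Name (or index) of the baseline entry for percent
#'   improvements; default the first.
#' @return data.frame: one row per campaign with final antibody mass and
#'   concentration, total glucose fed, and percent improvements vs the
#'   baseline (`100 * (x - base) / base`, computed at batch end).
#' @export
compare_campaigns <- function(results, baseline = 1L) {
  stopifnot(length(results) >= 2L)
  if (is.null(names(results)) || any(names(results) == ""))
    names(results) <- paste0("campaign", seq_along(results))
  pars <- lapply(results, function(r) unlist(unclass(r$config$p)))
  for (i in seq_along(pars)[-1])
    if (!isTRUE(all.equal(pars[[1]], pars[[i]])))
      stop("campaigns were run on different twin parameter sets")
  base <- results[[baseline]]$metrics
  rows <- lapply(results, function(r) {
    m <- r$metrics
    data.frame(antibody_mass = m$antibody_mass,
               antibody_conc = m$antibody_conc,
               glucose_fed = m$glucose_fed,
               improvement_mass_pct =
                 100 * (m$antibody_mass - base$antibody_mass) / base$antibody_mass,
               improvement_conc_pct =
                 100 * (m$antibody_conc - base$antibody_conc) / base$antibody_conc)
  })
  out <- do.call(rbind, rows)
  out <- cbind(campaign = names(results), out)
  rownames(out) <- NULL
  out
}

#' Per-flux tracking report
#'
#' For each tracked flux: the integrated squared deviation between
#' realised and target flux over the batch (trapezoidal quadrature, unit
#' weight) and the per-stage mean deviation.
#'
#' @param result A `campaign_result`.
#' @param targets A [stage_targets()] table (defaults to the campaign's).
#' @return data.frame with columns `flux`, `integrated_sq_dev`, and one
#'   `mean_dev_<stage>` column per stage.
#' @export
tracking_report <- function(result, targets = result$config$targets) {
  traj <- result$trajectory
  schedule <- result$config$schedule
  ids <- tracked_fluxes(targets)
  z <- observed_fluxes(traj)[, ids, drop = FALSE]
  zt <- targets_at(targets, schedule, traj$grid, ids = ids)
  dev <- z - zt
  st <- stage_at(schedule, traj$grid)
  rows <- lapply(ids, function(j) {
    row <- data.frame(flux = j,
                      integrated_sq_dev = trapz(traj$grid, dev[, j]^2))
    for (s in culture_stages())
      row[[paste0("mean_dev_", s)]] <- mean(dev[st == s, j])
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
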