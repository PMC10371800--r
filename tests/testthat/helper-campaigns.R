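# Shared fixture objects and memoised heavy computations (closed-loop
# campaigns are reused by several acceptance assertions).

fx_net <- toy_network()
fx_bounds <- toy_stage_bounds()
fx_targets <- stage_targets(fx_net, fx_bounds)
fx_schedule <- stage_schedule()
fx_p <- nominal_parameters()
fx_x0 <- nominal_state()

.campaign_cache <- new.env(parent = emptyenv())

cached_campaign <- function(key, fun) {
  if (!exists(key, envir = .campaign_cache))
    assign(key, fun(), envir = .campaign_cache)
  get(key, envir = .campaign_cache)
}

fx_campaign_config <- function(case = "A", interval = 8, rate_limit = Inf) {
  campaign_config(
    cfg = fixture_control_config(case = case, control_interval = interval,
                                 rate_limit = rate_limit),
    targets = fx_targets, schedule = fx_schedule, p = fx_p, x0 = fx_x0,
    seed = 0L)
}

fx_closed_loop <- function(case, interval, rate_limit = Inf) {
  key <- paste("cl", case, interval, rate_limit, sep = "_")
  cached_campaign(key, function()
    run_closed_loop(fx_campaign_config(case, interval, rate_limit)))
}

fx_baseline <- function() {
  cached_campaign("baseline", function()
    run_open_loop(fx_campaign_config()))
}
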