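# Configuration loading with explicit units, policy files, manifests.

# canonical internal units: h, L, mmol/L, 1e9 cells/L, mg/L, L/h for flows
UNIT_TABLE <- list(
  "h" = 1, "hour" = 1, "hours" = 1, "d" = 24, "day" = 24,
  "L" = 1, "l" = 1,
  "mmol/L" = 1, "mM" = 1,
  "L/h" = 1, "l/h" = 1, "L/min" = 60, "l/min" = 60,
  "mmol/min" = 60, "mmol/h" = 1,
  "1e9 cells/L" = 1, "mg/L" = 1)

#' Convert a quantity to internal units
#'
#' Accepts either a bare number (assumed already internal) or a list
#' `list(value=, unit=)`. Known units: h, d, L, mmol/L (mM), L/h, L/min,
#' mmol/h, mmol/min, 1e9 cells/L, mg/L. Per-minute quantities are
#' multiplied by 60 exactly once at this boundary.
#'
#' @param x Number or `list(value, unit)`.
#' @param what Label used in error messages.
#' @return Numeric value in internal units.
#' @export
to_internal_units <- function(x, what = "quantity") {
  if (is.numeric(x)) return(as.numeric(x))
  if (is.list(x) && !is.null(x$value)) {
    if (is.null(x$unit)) return(as.numeric(x$value))
    f <- UNIT_TABLE[[as.character(x$unit)]]
    if (is.null(f))
      stop("unknown unit key '", x$unit, "' for ", what)
    return(as.numeric(x$value) * f)
  }
  stop("cannot interpret ", what, ": expected a number or {value, unit}")
}

#' Load a twin configuration (YAML/JSON)
#'
#' Expects keys `parameters` (the [kinetic_parameters()] fields),
#' `initial_state` (t, V, Xv, Xd, C map, P) and `feed_medium`. Scalar
#' entries may be annotated as `{value, unit}`.
#'
#' @param path YAML or JSON file.
#' @return List with `p` ([kinetic_parameters()]), `x0`
#'   ([reactor_state()]), `feed_medium` (named numeric).
#' @export
load_twin_config <- function(path) {
  cfg <- read_config_file(path)
  for (req in c("parameters", "initial_state"))
    if (is.null(cfg[[req]])) stop("twin config missing '", req, "': ", path)
  pars <- lapply(cfg$parameters, to_internal_units, what = "kinetic parameter")
  p <- do.call(kinetic_parameters, pars)
  s <- cfg$initial_state
  C <- vapply(s$C, to_internal_units, numeric(1), what = "concentration")
  x0 <- reactor_state(t = to_internal_units(s$t %||% 0, "t"),
                      V = to_internal_units(s$V, "V"),
                      Xv = to_internal_units(s$Xv, "Xv"),
                      Xd = to_internal_units(s$Xd %||% 0, "Xd"),
                      C = C, P = to_internal_units(s$P %||% 0, "P"))
  fm <- vapply(cfg$feed_medium %||% list(),
               to_internal_units, numeric(1), what = "feed concentration")
  list(p = p, x0 = x0, feed_medium = fm)
}

#' Load a control configuration (YAML/JSON)
#'
#' Keys mirror [control_config()] arguments; bounds may be unit-annotated
#' (`{value, unit}` per element or a two-element list). An absent
#' `rate_limit` leaves the rate of change unconstrained.
#'
#' @param path YAML or JSON file.
#' @return A [control_config()].
#' @export
load_control_config <- function(path) {
  cfg <- read_config_file(path)
  args <- list()
  for (nm in c("case", "control_interval", "horizon", "rate_limit",
               "rate_penalty", "glc_profile", "maxeval", "sim_dt",
               "sim_rtol", "n_random_starts"))
    if (!is.null(cfg[[nm]])) args[[nm]] <- cfg[[nm]]
  # flow bounds are passed to control_config in L/min (it converts to L/h)
  if (!is.null(cfg$cglc_bounds))
    args$cglc_bounds <- vapply(cfg$cglc_bounds, to_internal_units,
                               numeric(1), "glucose feed bound")
  if (!is.null(cfg$fin_bounds))
    args$fin_bounds <- vapply(cfg$fin_bounds, to_internal_units,
                              numeric(1), "inlet flow bound") / 60
  if (!is.null(cfg$fout_bounds))
    args$fout_bounds <- vapply(cfg$fout_bounds, to_internal_units,
                               numeric(1), "outlet flow bound") / 60
  if (!is.null(cfg$weights)) args$weights <- unlist(cfg$weights)
  do.call(control_config, args)
}

read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a feed policy (CSV, internal units)
#'
#' Columns: `t` (h), `C_feed_glc` (mmol/L), `F_in`, `F_out` (L/h), plus
#' constant feed-medium columns `feed_<species>` (mmol/L) on every row.
#'
#' @param policy A [feed_policy()].
#' @param path Output path.
#' @return `path` (write) / a [feed_policy()] (read).
#' @export
write_policy <- function(policy, path) {
  tab <- data.frame(t = policy$knots, C_feed_glc = policy$C_feed_glc,
                    F_in = policy$F_in, F_out = policy$F_out)
  for (sp in names(policy$C_feed_other))
    if (sp != "glc") tab[[paste0("feed_", sp)]] <- policy$C_feed_other[[sp]]
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_policy
#' @export
read_policy <- function(path) {
  if (!file.exists(path)) stop("policy file not found: ", path)
  tab <- utils::read.csv(path)
  need <- c("t", "C_feed_glc", "F_in", "F_out")
  if (!all(need %in% names(tab)))
    stop("policy CSV must have columns: ", paste(need, collapse = ", "))
  fm_cols <- grep("^feed_", names(tab), value = TRUE)
  fm <- vapply(fm_cols, function(cl) tab[[cl]][1], numeric(1))
  names(fm) <- sub("^feed_", "", fm_cols)
  feed_policy(tab$t, C_feed_glc = tab$C_feed_glc, F_in = tab$F_in,
              F_out = tab$F_out, C_feed_other = fm)
}

#' Write a run manifest (JSON)
#'
#' Records the fixture/config checksums, seed and package version so a
#' deterministic run can be reproduced bit-identically.
#'
#' @param path Output path.
#' @param seed Integer seed used.
#' @param files Character vector of input files to checksum.
#' @param extra Optional named list merged into the manifest.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, seed, files = character(0), extra = list()) {
  sums <- tools::md5sum(files)
  names(sums) <- basename(files)
  m <- c(list(package = "fluxmpc",
              version = as.character(utils::packageVersion("fluxmpc")),
              seed = as.integer(seed),
              files = as.list(sums)),
         extra)
  jsonlite::write_json(m, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
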