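# Self-contained illustrative fixture bundle: a reduced CHO-like
# metabolic network, five stage-bound sets reproducing the qualitative
# stage pattern (decreasing growth, lactate shift, product peak in early
# stationary), a nominal kinetic parameter set at production scale and a
# pre-designed baseline ("original") feed policy. All values are
# illustrative and chosen for a small, well-conditioned test problem;
# none are measured or published values.

FIXTURE_VERSION <- "fluxmpc-fixtures-1"

#' Reduced toy metabolic network
#'
#' 11 metabolites, 14 reactions: glucose/glutamine/asparagine uptake,
#' a lumped glycolysis step, reversible lactate dehydrogenase (carries
#' the lactate shift), glutaminolysis and asparaginase lumps releasing
#' ammonia, alanine transaminase, a biomass drain and an antibody
#' synthesis/secretion pair. Small enough for exhaustive
#' vertex-enumeration LP checks.
#'
#' @return A [flux_network()].
#' @export
toy_network <- function() {
  mets <- data.frame(
    id = c("glc", "gln", "asn", "lac", "nh4", "ala",
           "glu", "asp", "pyr", "akg", "mab"),
    name = c("glucose", "glutamine", "asparagine", "lactate", "ammonia",
             "alanine", "glutamate", "aspartate", "pyruvate",
             "alpha-ketoglutarate", "antibody"),
    extracellular = c(rep(TRUE, 6), FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  rxn <- function(id, st, reversible = FALSE, exchange = FALSE,
                  biomass = FALSE, product = FALSE)
    list(id = id, stoichiometry = st, reversible = reversible,
         is_exchange = exchange, is_biomass = biomass, is_product = product)
  reactions <- list(
    rxn("EX_glc", c(glc = -1), reversible = TRUE, exchange = TRUE),
    rxn("EX_gln", c(gln = -1), reversible = TRUE, exchange = TRUE),
    rxn("EX_asn", c(asn = -1), reversible = TRUE, exchange = TRUE),
    rxn("EX_lac", c(lac = -1), reversible = TRUE, exchange = TRUE),
    rxn("EX_nh4", c(nh4 = -1), reversible = TRUE, exchange = TRUE),
    rxn("EX_ala", c(ala = -1), reversible = TRUE, exchange = TRUE),
    rxn("EX_mab", c(mab = -1), exchange = TRUE, product = TRUE),
    rxn("GLYC", c(glc = -1, pyr = 2)),
    rxn("LDH", c(pyr = -1, lac = 1), reversible = TRUE),
    rxn("GLNASE", c(gln = -1, glu = 1, nh4 = 1)),
    rxn("ASNASE", c(asn = -1, asp = 1, nh4 = 1)),
    rxn("ALATA", c(pyr = -1, glu = -1, ala = 1, akg = 1)),
    rxn("GROWTH", c(pyr = -2, akg = -0.75, asp = -0.5, glu = -0.375),
        biomass = TRUE),
    rxn("MABS", c(akg = -0.2, asp = -0.15, asn = -0.1, mab = 1)))
  flux_network(mets, reactions)
}

#' Stage bounds for the toy network
#'
#' Five bound sets emulating the expected flux limits per culture stage:
#' glucose uptake is fixed at the stage's measured-style rate, glutamine
#' and asparagine uptake ceilings shrink as the culture ages, lactate is
#' restricted to secretion in the exponential stages and forced to (mild)
#' uptake in the stationary stages, and a minimum antibody synthesis
#' commitment peaks in early stationary phase.
#'
#' @return Named list of five [stage_bounds()] keyed by stage.
#' @export
toy_stage_bounds <- function() {
  glc_fix <- c(-0.20, -0.16, -0.12, -0.015, -0.010)
  gln_max <- c(0.050, 0.042, 0.035, 0.020, 0.012)
  asn_max <- c(0.030, 0.026, 0.022, 0.015, 0.010)
  lac_lb <- c(0, 0, 0, -0.05, -0.04)
  lac_ub <- c(1, 1, 1, -0.01, -0.005)
  mab_lb <- c(2e-4, 5e-4, 1e-3, 4e-3, 2e-3)
  mab_ub <- c(1e-3, 1.5e-3, 3e-3, 8e-3, 5e-3)
  stages <- culture_stages()
  out <- list()
  for (i in 1:5) {
    lb <- c(EX_glc = glc_fix[i], EX_gln = -gln_max[i], EX_asn = -asn_max[i],
            EX_lac = lac_lb[i], EX_nh4 = 0, EX_ala = 0, EX_mab = mab_lb[i],
            LDH = -1, GLYC = 0, GLNASE = 0, ASNASE = 0, ALATA = 0,
            GROWTH = 0, MABS = 0)
    ub <- c(EX_glc = glc_fix[i], EX_gln = 0, EX_asn = 0,
            EX_lac = lac_ub[i], EX_nh4 = 1, EX_ala = 1, EX_mab = mab_ub[i],
            LDH = 1, GLYC = 10, GLNASE = 10, ASNASE = 10, ALATA = 10,
            GROWTH = 1, MABS = 1)
    out[[stages[i]]] <- stage_bounds(stages[i], lb = lb, ub = ub)
  }
  out
}

#' Nominal kinetic parameter set of the fixture twin
#'
#' The [kinetic_parameters()] defaults: a reduced-scale 25-parameter
#' Monod structure whose maximum rates are commensurate with the toy
#' network's early-exponential targets (mu_max 0.045/h vs biomass target
#' ~0.044/h; saturated glucose uptake ~0.17 vs target 0.20
#' mmol/1e9 cells/h, deliberately slightly unattainable).
#'
#' @return A [kinetic_parameters()].
#' @export
nominal_parameters <- function() kinetic_parameters()

#' Nominal initial reactor state
#'
#' Production-scale seed: 1000 L, 0.3e9 viable cells/L, typical basal
#' medium concentrations. At this scale the literature manipulated-
#' variable bounds (inlet 0.001-1 L/min etc.) are physically sensible.
#'
#' @return A [reactor_state()].
#' @export
nominal_state <- function() {
  reactor_state(t = 0, V = 1000, Xv = 0.3, Xd = 0,
                C = c(glc = 20, gln = 6, asn = 3, lac = 0.5,
                      nh4 = 0.5, ala = 0.2),
                P = 0)
}

#' Feed medium composition of the fixture (non-glucose species)
#' @return Named vector (mmol/L).
#' @export
nominal_feed_medium <- function() c(gln = 40, asn = 30)

#' Baseline ("original"-style) feed policy
#'
#' A fixed a-priori fed-batch recipe: constant 400 mmol/L glucose feed at
#' 0.5 L/h with no outflow, knots every 24 h. Deliberately conservative:
#' it sustains the early culture but underfeeds once the cell density
#' grows, leaving headroom for the controller.
#'
#' @param batch_end Batch duration (h), default 360.
#' @return A [feed_policy()].
#' @export
baseline_policy <- function(batch_end = 360) {
  knots <- seq(0, batch_end, by = 24)
  feed_policy(knots, C_feed_glc = 400, F_in = 0.5, F_out = 0,
              C_feed_other = nominal_feed_medium())
}

#' No-feed (batch-culture) policy
#'
#' Zero flows over the batch; the fixture culture then depletes glucose
#' well before batch end.
#'
#' @param batch_end Batch duration (h), default 360.
#' @return A [feed_policy()].
#' @export
no_feed_policy <- function(batch_end = 360) {
  feed_policy(c(0, batch_end), C_feed_glc = 0, F_in = 0, F_out = 0,
              C_feed_other = nominal_feed_medium())
}

#' Control configuration of the fixture campaigns
#'
#' The [control_config()] defaults carry the literature manipulated-
#' variable bounds; at the fixture's 1000 L vessel scale the inlet bound
#' of 1 L/min would admit a twenty-fold volume expansion over a 360 h
#' batch, which is no longer a fed-batch. The fixture campaigns
#' therefore cap the inlet at 0.05 L/min (at most ~2x volume per batch)
#' and the outlet at 0.002 L/min (sampling/bleed scale), keeping the
#' closed-loop study in the fed-batch regime. All other settings are the
#' package defaults.
#'
#' @param case,control_interval,rate_limit Passed to [control_config()].
#' @param ... Further [control_config()] overrides.
#' @return A [control_config()].
#' @export
fixture_control_config <- function(case = "A", control_interval = 8,
                                   rate_limit = Inf, ...) {
  control_config(case = case, control_interval = control_interval,
                 rate_limit = rate_limit,
                 fin_bounds = c(0.001, 0.05),
                 fout_bounds = c(0, 0.002), ...)
}

#' Materialise the fixture bundle on disk
#'
#' Writes the toy network (TSV), stage bounds (TSV), twin configuration
#' (YAML: parameters, initial state, feed medium), baseline policy (CSV)
#' and a manifest (JSON: version, file checksums). Regeneration under the
#' same fixture version is byte-identical.
#'
#' @param dir Output directory (created if missing).
#' @return Named vector of file paths, invisibly.
#' @export
write_fixture_bundle <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(network = file.path(dir, "network.tsv"),
             bounds = file.path(dir, "stage_bounds.tsv"),
             twin = file.path(dir, "twin.yaml"),
             policy = file.path(dir, "baseline_policy.csv"),
             manifest = file.path(dir, "manifest.json"))
  write_network_tsv(toy_network(), paths[["network"]])
  write_stage_bounds(toy_stage_bounds(), paths[["bounds"]])
  x0 <- nominal_state()
  twin_cfg <- list(
    units = list(time = "h", volume = "L", concentration = "mmol/L",
                 cells = "1e9 cells/L", antibody = "mg/L"),
    parameters = unclass(nominal_parameters()),
    initial_state = list(t = x0$t, V = x0$V, Xv = x0$Xv, Xd = x0$Xd,
                         C = as.list(x0$C), P = x0$P),
    feed_medium = as.list(nominal_feed_medium()))
  writeLines(yaml::as.yaml(twin_cfg), paths[["twin"]])
  write_policy(baseline_policy(), paths[["policy"]])
  files <- paths[setdiff(names(paths), "manifest")]
  manifest <- list(version = FIXTURE_VERSION,
                   files = as.list(tools::md5sum(files)))
  names(manifest$files) <- basename(files)
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}
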