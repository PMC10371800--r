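# Stage-wise flux balance analysis.
#
# Problem: max v_biomass  s.t.  S v = 0, lb <= v <= ub (irreversible
# reactions have lb >= 0). The solution returned is the minimum-norm
# point of the optimal face (two-phase semantics), so it is unique and
# reproducible even under alternate optima; both phases are obtained at
# once from a single exact projection QP with escalating pull towards
# the biomass direction (see fba_proj_qp / fba_two_phase).

#' Stage flux bounds
#'
#' Bounds are maps reaction id -> value in mmol per 1e9 cells per hour
#' (biomass in 1/h). Reactions absent from both maps default to
#' `[-big_m, big_m]` (`[0, big_m]` if irreversible).
#'
#' @param stage Stage name (one of [culture_stages()]) or other label.
#' @param lb,ub Named numeric vectors of lower/upper bounds.
#' @return Object of class `stage_bounds`.
#' @export
stage_bounds <- function(stage, lb = numeric(0), ub = numeric(0)) {
  structure(list(stage = stage, lb = lb, ub = ub), class = "stage_bounds")
}

resolve_bounds <- function(net, bounds, big_m = 1000) {
  ids <- reaction_ids(net)
  rev <- reaction_field(net, "reversible")
  lb <- ifelse(rev, -big_m, 0)
  ub <- rep(big_m, length(ids))
  names(lb) <- names(ub) <- ids
  if (!is.null(bounds)) {
    stopifnot(inherits(bounds, "stage_bounds"))
    unknown <- setdiff(c(names(bounds$lb), names(bounds$ub)), ids)
    if (length(unknown))
      stop("bounds reference unknown reaction(s): ",
           paste(unknown, collapse = ", "))
    lb[names(bounds$lb)] <- bounds$lb
    ub[names(bounds$ub)] <- bounds$ub
  }
  if (any(!rev & lb < 0))
    stop("irreversible reaction(s) with negative lower bound: ",
         paste(ids[!rev & lb < 0], collapse = ", "))
  if (any(lb > ub))
    stop("infeasible bounds (lb > ub) for: ",
         paste(ids[lb > ub], collapse = ", "))
  list(lb = lb, ub = ub)
}

# Full-rank row subset of S (QR with pivoting), so equality constraints
# passed to the solvers are consistent and non-redundant.
independent_rows <- function(S) {
  if (nrow(S) == 0L) return(S)
  qr_t <- qr(t(S))
  r <- qr_t$rank
  if (r == 0L) return(S[0, , drop = FALSE])
  S[sort(qr_t$pivot[seq_len(r)]), , drop = FALSE]
}

# Projection QP: min 1/2||v||^2 - lambda c'v  s.t.  Sr v = 0,
# lb <= v <= ub. For a bounded polytope and lambda beyond a finite
# threshold this is the projection of lambda*c onto the feasible set,
# which lies on the optimal face of the LP max c'v and equals its
# minimum-norm point, i.e. both FBA phases at once (exact active-set
# solve via quadprog). Fixed variables (lb == ub) are substituted out;
# redundant equality rows are dropped (consistency is re-checked on the
# full S v = 0 residual by the caller).
fba_proj_qp <- function(Sr, cvec, lb, ub, lambda) {
  fixed <- (ub - lb) < 1e-12
  rhs <- as.numeric(-(Sr %*% ifelse(fixed, lb, 0)))
  v <- lb
  if (all(fixed)) return(v)
  Af <- Sr[, !fixed, drop = FALSE]
  piv <- sort(qr(t(Af))$pivot[seq_len(qr(t(Af))$rank)])
  zero_row <- setdiff(seq_len(nrow(Af)), piv)
  if (any(abs(rhs[zero_row]) > 1e-9))
    stop("infeasible bounds: fixed fluxes violate mass balance for ",
         "metabolite row(s) ", paste(rownames(Sr)[zero_row], collapse = ", "))
  Af <- Af[piv, , drop = FALSE]
  rhs <- rhs[piv]
  nf <- sum(!fixed)
  lo <- is.finite(lb[!fixed]); hi <- is.finite(ub[!fixed])
  Amat <- t(rbind(Af, diag(nf)[lo, , drop = FALSE],
                  -diag(nf)[hi, , drop = FALSE]))
  bvec <- c(rhs, lb[!fixed][lo], -ub[!fixed][hi])
  sol <- tryCatch(
    quadprog::solve.QP(Dmat = diag(nf), dvec = lambda * cvec[!fixed],
                       Amat = Amat, bvec = bvec, meq = nrow(Af)),
    error = function(e)
      stop("FBA infeasible: ", conditionMessage(e), call. = FALSE))
  v[!fixed] <- sol$solution
  v
}

# Escalate lambda until the LP value stabilises (finite convergence for
# bounded polytopes); diverging |v| signals an unbounded objective.
fba_two_phase <- function(Sr, cvec, lb, ub) {
  scale <- max(1, abs(lb[is.finite(lb)]), abs(ub[is.finite(ub)]))
  lambda <- 1e4 * scale
  v <- fba_proj_qp(Sr, cvec, lb, ub, lambda)
  for (i in 1:6) {
    v2 <- fba_proj_qp(Sr, cvec, lb, ub, lambda * 100)
    same_obj <- abs(sum(cvec * (v2 - v))) <=
      1e-10 * max(1, abs(sum(cvec * v)))
    if (same_obj && max(abs(v2 - v)) <= 1e-7 * max(1, max(abs(v))))
      return(v2)
    if (max(abs(v2)) > 10 * max(abs(v), 1))
      stop("FBA unbounded: biomass flux increases without limit ",
           "(add finite bounds)")
    v <- v2
    lambda <- lambda * 100
  }
  stop("FBA two-phase solve did not stabilise; problem may be unbounded")
}

#' Solve the biomass-maximisation FBA problem
#'
#' Maximises the biomass flux subject to steady-state mass balance
#' `S v = 0` and the stage bounds (irreversible fluxes nonnegative).
#' Among alternate optima, returns the flux vector of minimum sum of
#' squares at the fixed optimal biomass (two-phase solve), so targets are
#' unique and reproducible.
#'
#' @param net A [flux_network()].
#' @param bounds A [stage_bounds()], or `NULL` for default bounds only.
#' @param big_m Default bound magnitude for reactions without explicit
#'   bounds (default 1000).
#' @return Object of class `fba_solution`: `v` (named flux vector),
#'   `objective` (biomass flux), `status` (`"optimal"`), `stage`.
#' @export
solve_fba <- function(net, bounds = NULL, big_m = 1000) {
  stopifnot(inherits(net, "flux_network"))
  rb <- resolve_bounds(net, bounds, big_m = big_m)
  lb <- rb$lb; ub <- rb$ub
  n <- length(lb)
  cvec <- as.numeric(reaction_field(net, "is_biomass"))
  Sr <- independent_rows(net$S)
  v <- tryCatch(fba_two_phase(Sr, cvec, lb, ub), error = function(e)
    stop("stage '", if (!is.null(bounds)) bounds$stage else "default",
         "': ", conditionMessage(e), call. = FALSE))
  # tolerance polish: snap to bounds
  v <- pmin(pmax(v, lb), ub)
  resid <- max(abs(net$S %*% v))
  if (resid > 1e-8 * max(1, max(abs(v))))
    stop("FBA solution violates mass balance (residual ", format(resid), ")")
  structure(list(v = v, objective = sum(cvec * v), status = "optimal",
                 stage = if (!is.null(bounds)) bounds$stage else NA_character_),
            class = "fba_solution")
}

#' @export
print.fba_solution <- function(x, ...) {
  cat(sprintf("FBA solution (%s): biomass flux %.6g [%s]\n",
              if (is.na(x$stage)) "default bounds" else x$stage,
              x$objective, x$status))
  invisible(x)
}

#' Compute the stage target flux table
#'
#' Runs [solve_fba()] once per culture stage and extracts the tracked
#' fluxes: the exchange fluxes of the extracellular metabolites plus the
#' biomass flux (positive = secretion, negative = uptake). The product
#' exchange flux is reported alongside but is not part of the controller's
#' tracked set.
#'
#' @param net A [flux_network()].
#' @param all_bounds List of five [stage_bounds()], one per culture stage
#'   (any order; matched by the `stage` field).
#' @param big_m Default bound magnitude, as in [solve_fba()].
#' @return Object of class `stage_targets`: data.frame with one row per
#'   stage and one column per tracked flux id, plus attributes
#'   `tracked` (tracked flux ids) and `solutions` (full per-stage
#'   `fba_solution`s).
#' @export
stage_targets <- function(net, all_bounds, big_m = 1000) {
  stages <- culture_stages()
  got <- vapply(all_bounds, function(b) b$stage, "")
  if (!setequal(got, stages) || length(got) != 5L)
    stop("need exactly one stage_bounds per culture stage; got: ",
         paste(got, collapse = ", "))
  ex <- exchange_map(net)
  prod_rxn <- reaction_ids(net)[reaction_field(net, "is_product") &
                                  reaction_field(net, "is_exchange")]
  tracked_mets <- net$metabolites$id[net$metabolites$extracellular]
  tracked_mets <- intersect(tracked_mets, names(ex))
  tracked_mets <- setdiff(tracked_mets,
                          names(ex)[ex %in% prod_rxn])  # product reported, not tracked
  tracked <- c("biomass", tracked_mets)
  rows <- list()
  sols <- list()
  for (st in stages) {
    b <- all_bounds[[which(got == st)]]
    sol <- tryCatch(solve_fba(net, b, big_m = big_m), error = function(e)
      stop("stage '", st, "': ", conditionMessage(e), call. = FALSE))
    sols[[st]] <- sol
    row <- c(biomass = unname(sol$objective),
             stats::setNames(sol$v[ex[tracked_mets]], tracked_mets))
    if (length(prod_rxn))
      row <- c(row, product = unname(sol$v[prod_rxn[1]]))
    rows[[st]] <- row
  }
  tab <- as.data.frame(do.call(rbind, rows))
  tab <- cbind(stage = stages, tab, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(tab, tracked = tracked, solutions = sols,
            class = c("stage_targets", "data.frame"))
}

#' Tracked flux ids of a stage target table
#' @param targets A `stage_targets` table.
#' @return Character vector (biomass first, then metabolite ids).
#' @export
tracked_fluxes <- function(targets) attr(targets, "tracked")

#' Target fluxes at given times
#'
#' Resolves the stage schedule at each time and returns the per-time
#' target value of each tracked flux (targets are constant within a
#' stage).
#'
#' @param targets A `stage_targets` table.
#' @param schedule A [stage_schedule()].
#' @param t Numeric vector of times (h).
#' @param ids Flux ids to extract (default: all tracked).
#' @return Matrix `length(t) x length(ids)`.
#' @export
targets_at <- function(targets, schedule, t, ids = tracked_fluxes(targets)) {
  st <- stage_at(schedule, t)
  idx <- match(st, targets$stage)
  out <- as.matrix(targets[idx, ids, drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Read stage bounds from TSV
#'
#' Columns: `reaction_id`, `stage`, `lb`, `ub`. Missing reaction/stage
#' pairs default to the big-M bounds.
#'
#' @param path TSV file path.
#' @return List of [stage_bounds()], one per stage present in the file.
#' @export
read_stage_bounds <- function(path) {
  if (!file.exists(path)) stop("stage bounds file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("reaction_id", "stage", "lb", "ub")
  if (!all(need %in% names(tab)))
    stop("stage bounds TSV must have columns: ", paste(need, collapse = ", "))
  lapply(split(tab, tab$stage), function(d) {
    lb <- stats::setNames(suppressWarnings(as.numeric(d$lb)), d$reaction_id)
    ub <- stats::setNames(suppressWarnings(as.numeric(d$ub)), d$reaction_id)
    stage_bounds(d$stage[1], lb = lb[!is.na(lb)], ub = ub[!is.na(ub)])
  })
}

#' Write stage bounds to TSV
#' @param all_bounds List of [stage_bounds()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stage_bounds <- function(all_bounds, path) {
  fmt <- function(x) ifelse(is.na(x), "NA",
                            format(x, digits = 15, scientific = FALSE,
                                   trim = TRUE))
  rows <- do.call(rbind, lapply(all_bounds, function(b) {
    ids <- union(names(b$lb), names(b$ub))
    data.frame(reaction_id = ids, stage = b$stage,
               lb = fmt(as.numeric(b$lb[ids])),
               ub = fmt(as.numeric(b$ub[ids])))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a stage target table to CSV
#' @param targets A `stage_targets` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stage_targets <- function(targets, path) {
  utils::write.csv(as.data.frame(targets), path, row.names = FALSE)
  invisible(path)
}
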