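#' Culture stages of a fed-batch CHO run
#'
#' The five canonical fed-batch culture phases, in chronological order:
#' early exponential, mid-exponential, late exponential, early stationary
#' and late stationary. Stage-wise FBA produces one set of constant target
#' fluxes per stage.
#'
#' @return Character vector of the five stage names, in order.
#' @export
culture_stages <- function() {
  c("early_exponential", "mid_exponential", "late_exponential",
    "early_stationary", "late_stationary")
}

#' Stage schedule: breakpoints delimiting the five culture phases
#'
#' @param breakpoints Numeric vector of 6 strictly increasing times (h)
#'   delimiting the five stage windows. Windows are left-closed/right-open,
#'   the final window right-closed. Default `c(0, 72, 144, 216, 288, 360)`.
#' @return An object of class `stage_schedule`.
#' @export
stage_schedule <- function(breakpoints = c(0, 72, 144, 216, 288, 360)) {
  breakpoints <- as.numeric(breakpoints)
  if (length(breakpoints) != 6L)
    stop("stage schedule needs exactly 6 breakpoints (5 stages)")
  if (any(diff(breakpoints) <= 0))
    stop("stage schedule breakpoints must be strictly increasing")
  structure(list(breakpoints = breakpoints, stages = culture_stages()),
            class = "stage_schedule")
}

#' Look up the culture stage at a given time
#'
#' Total and deterministic: times before the first breakpoint map to the
#' first stage, times at or past the last breakpoint to the last stage.
#'
#' @param schedule A [stage_schedule()].
#' @param t Numeric vector of times (h).
#' @return Character vector of stage names, same length as `t`.
#' @export
stage_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "stage_schedule"))
  bp <- schedule$breakpoints
  idx <- findInterval(t, bp, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), 5L)
  schedule$stages[idx]
}

#' @export
print.stage_schedule <- function(x, ...) {
  cat("Stage schedule (h):\n")
  for (i in 1:5)
    cat(sprintf("  %-18s [%g, %g%s\n", x$stages[i], x$breakpoints[i],
                x$breakpoints[i + 1], if (i == 5) "]" else ")"))
  invisible(x)
}
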