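#' Cross-sectional state probabilities
#'
#' The probability of occupying each of the 16 states at horizon `t`, given
#' occupation of `from_state` at origin `s` (a single row of the
#' Aalen-Johansen matrix P(s, t), with standard errors and bands).
#'
#' @param fit A [waitlist_msm()] fit.
#' @param from_state Origin state index (1-16).
#' @param s Origin time (days).
#' @param t Horizon (days), `t >= s`.
#' @param level Confidence level.
#' @return A data frame of class `msm_cross_section` with one row per
#'   destination state.
#' @export
state_probabilities <- function(fit, from_state, s = 0, t, level = 0.95) {
  if (t < s) stop("horizon `t` must be at least the origin `s`")
  if (!from_state %in% fit$space$index) stop("unknown state index ", from_state)
  out <- predict(fit, s = s, t = t, from = from_state, level = level)
  out <- out[out$time == t, , drop = FALSE]
  out$state_label <- fit$space$label[out$to_index]
  rownames(out) <- NULL
  class(out) <- c("msm_cross_section", "data.frame")
  out
}

#' Dynamic prediction of absorbing outcomes
#'
#' Probability of each absorbing outcome by `horizon`, given the occupied
#' state at the prediction time `s`. Under the Markov assumption the whole
#' history up to `s` enters only through that state, so updating the
#' prediction as a patient moves (e.g. inactivation at day 60) amounts to
#' re-conditioning on the new state.
#'
#' @param fit A [waitlist_msm()] fit.
#' @param state_at_s Transient state occupied at `s`.
#' @param s Prediction time (days).
#' @param horizon Target time (days), `>= s`.
#' @param level Confidence level.
#' @return A data frame with one row per absorbing outcome.
#' @export
dynamic_prediction <- function(fit, state_at_s, s, horizon, level = 0.95) {
  if (fit$space$kind[state_at_s] != "transient") {
    stop("`state_at_s` must be a transient state")
  }
  cs <- state_probabilities(fit, state_at_s, s, horizon, level)
  out <- cs[fit$space$kind[cs$to_index] == "absorbing", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cumulative death probability curves by initial state
#'
#' The death-or-deterioration column of P(0, t) for every transient initial
#' state over the event grid (optionally restricted to requested horizons).
#'
#' @param fit A [waitlist_msm()] fit.
#' @param horizons Optional report times; defaults to the full event grid.
#' @param level Confidence level.
#' @return Long data frame: `initial_state`, `initial_label`, `time`,
#'   `estimate`, `se`, `lower`, `upper`.
#' @export
death_curves <- function(fit, horizons = NULL, level = 0.95) {
  traj <- predict(fit, s = 0, t = horizons, type = "trajectory",
                  level = level)
  k <- absorbing_index(fit$space, "death_or_deteriorated")
  times <- traj$times
  keep <- if (is.null(horizons)) seq_along(times) else match(horizons, times)
  origins <- fit$space$index[fit$space$kind == "transient"]
  out <- do.call(rbind, lapply(origins, function(o) {
    data.frame(initial_state = o, initial_label = fit$space$label[o],
               time = times[keep],
               estimate = traj$P[o, k, keep],
               se = sqrt(pmax(traj$var[o, k, keep], 0)),
               lower = traj$lower[o, k, keep],
               upper = traj$upper[o, k, keep])
  }))
  rownames(out) <- NULL
  out
}

#' Compare an outcome probability between two cohorts
#'
#' Paired Aalen-Johansen estimates with confidence intervals from two
#' independently fitted cohorts, with a descriptive interval-overlap flag
#' (no formal test is performed).
#'
#' @param fitA,fitB Two [waitlist_msm()] fits on the same state space.
#' @param from_state Origin state index.
#' @param target Absorbing-state label or index.
#' @param t Horizon (days).
#' @param s Origin time (days).
#' @param level Confidence level.
#' @return A list of class `msm_cohort_comparison` with both estimates, the
#'   difference (B - A) and the overlap indicator.
#' @export
compare_cohorts <- function(fitA, fitB, from_state, target, t, s = 0,
                            level = 0.95) {
  if (!identical(fitA$space$label, fitB$space$label)) {
    stop("fits use different state spaces")
  }
  k <- if (is.character(target)) absorbing_index(fitA$space, target)
       else as.integer(target)
  a <- state_probabilities(fitA, from_state, s, t, level)
  b <- state_probabilities(fitB, from_state, s, t, level)
  a <- a[a$to_index == k, ]; b <- b[b$to_index == k, ]
  overlap <- a$lower <= b$upper && b$lower <= a$upper
  structure(list(from_state = from_state, target = fitA$space$label[k],
                 s = s, t = t, level = level,
                 estimate_a = a$estimate, lower_a = a$lower, upper_a = a$upper,
                 estimate_b = b$estimate, lower_b = b$lower, upper_b = b$upper,
                 difference = b$estimate - a$estimate,
                 ci_overlap = overlap),
            class = "msm_cohort_comparison")
}

#' @export
print.msm_cohort_comparison <- function(x, ...) {
  cat(sprintf("P(%s) from state %d over (%g, %g] days\n", x$target,
              x$from_state, x$s, x$t))
  cat(sprintf("  cohort A: %.4f [%.4f, %.4f]\n", x$estimate_a, x$lower_a,
              x$upper_a))
  cat(sprintf("  cohort B: %.4f [%.4f, %.4f]\n", x$estimate_b, x$lower_b,
              x$upper_b))
  cat(sprintf("  difference (B - A): %.4f; %d%% CIs %s\n",
              x$difference, round(100 * x$level),
              if (x$ci_overlap) "overlap" else "do not overlap"))
  invisible(x)
}
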