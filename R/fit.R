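#' Fit the nonparametric multi-state waitlist model
#'
#' Central fitting function. Accepts either registrant records (one row per
#' subject, see [read_registrants()]) or an already-prepared long-format
#' transition table, and estimates all transition-specific Nelson-Aalen
#' cumulative hazards. Transition probabilities are obtained from the fit
#' with [predict()], which applies the Aalen-Johansen product-integral
#' estimator with Greenwood-type standard errors.
#'
#' @param data Registrant records or a transition table
#'   (`msm_transition_table`).
#' @param space State space from [build_state_space()].
#' @param struct Transition structure from [build_transition_structure()].
#' @param scheme Censoring scheme applied when `data` are records.
#' @param variance Hazard variance increment, `"greenwood"` or `"poisson"`.
#' @return An object of class `waitlist_msm`: a list with the transition
#'   table, risk profile, cumulative hazards, initial-state counts and the
#'   state space/structure.
#' @examples
#' scen <- scenario_registry_like(n_subjects = 200, seed = 7)
#' cohort <- simulate_cohort(scen)
#' fit <- waitlist_msm(cohort)
#' fit
#' head(predict(fit, t = 365, from = 1))
#' @export
waitlist_msm <- function(data, space = build_state_space(),
                         struct = build_transition_structure(space),
                         scheme = censoring_scheme(),
                         variance = c("greenwood", "poisson")) {
  variance <- match.arg(variance)
  cl <- match.call()
  if (inherits(data, "msm_transition_table") ||
      all(c("from_index", "to_index", "t_start", "t_stop", "status")
          %in% names(data))) {
    table <- data
    if (is.null(attr(table, "space"))) attr(table, "space") <- space
    if (is.null(attr(table, "struct"))) attr(table, "struct") <- struct
  } else {
    table <- prepare_transition_table(data, space, struct, scheme)
  }
  if (nrow(table) == 0) stop("empty cohort: no at-risk intervals")
  profile <- count_risk_and_events(table, space, struct)
  hazards <- nelson_aalen(profile, variance)
  entry <- table[table$t_start == 0, c("subject_id", "from_index")]
  entry <- entry[!duplicated(entry$subject_id), ]
  init <- table(factor(entry$from_index, levels = seq_len(n_transient(space))))
  structure(list(call = cl, table = table, profile = profile,
                 hazards = hazards, space = space, struct = struct,
                 scheme = scheme,
                 initial_counts = as.integer(init),
                 n_subjects = profile$n_subjects,
                 max_time = max(table$t_stop)),
            class = "waitlist_msm")
}

#' @export
print.waitlist_msm <- function(x, ...) {
  cat("Nonparametric multi-state waitlist model\n")
  cat("  states:", n_transient(x$space), "transient +",
      sum(x$space$kind == "absorbing"), "absorbing;",
      nrow(x$struct), "allowed transitions\n")
  cat("  subjects:", x$n_subjects, " events:", sum(x$profile$dN),
      " distinct event times:", length(x$profile$times), "\n")
  cat("  follow-up: 0 to", x$max_time, "days\n")
  invisible(x)
}

#' Summarize a fitted multi-state model
#'
#' @param object A `waitlist_msm` fit.
#' @param ... Ignored.
#' @return A list of class `summary.waitlist_msm` with per-transition event
#'   counts and cumulative hazards at the end of follow-up.
#' @export
summary.waitlist_msm <- function(object, ...) {
  ev <- rowSums(object$profile$dN)
  K <- ncol(object$hazards$A)
  tab <- data.frame(
    transition_id = object$struct$transition_id,
    from = object$struct$from, to = object$struct$to,
    from_label = object$space$label[object$struct$from],
    to_label = object$space$label[object$struct$to],
    events = ev,
    cumhaz = if (K) object$hazards$A[, K] else 0)
  structure(list(transitions = tab, n_subjects = object$n_subjects,
                 n_events = sum(ev), max_time = object$max_time,
                 initial_counts = object$initial_counts),
            class = "summary.waitlist_msm")
}

#' @export
print.summary.waitlist_msm <- function(x, ...) {
  cat("Multi-state fit:", x$n_subjects, "subjects,", x$n_events,
      "events, follow-up to day", x$max_time, "\n")
  cat("Transitions with events:\n")
  tab <- x$transitions[x$transitions$events > 0, ]
  tab <- tab[order(-tab$events), ]
  print.data.frame(utils::head(tab, 15L), row.names = FALSE, digits = 4)
  if (nrow(tab) > 15L) cat("...", nrow(tab) - 15L, "more transitions\n")
  invisible(x)
}

#' @export
coef.waitlist_msm <- function(object, ...) {
  K <- ncol(object$hazards$A)
  a <- if (K) object$hazards$A[, K] else rep(0, nrow(object$struct))
  names(a) <- paste0(object$struct$from, "->", object$struct$to)
  a
}

#' Predict transition probabilities from a fitted model
#'
#' @param object A `waitlist_msm` fit.
#' @param s Prediction origin in days.
#' @param t Report times (days, all >= `s`); defaults to the event grid.
#' @param from Optional origin state indices to keep.
#' @param type `"probability"` (long-format Aalen-Johansen estimates with
#'   bands) or `"trajectory"` (the full `msm_probtrans` object).
#' @param level Confidence level.
#' @param ci_method `"linear"` or `"log"` bands.
#' @param variance Compute standard errors (default TRUE).
#' @param ... Ignored.
#' @return A data frame (`origin_s`, `time`, `from_index`, `to_index`,
#'   `estimate`, `se`, `lower`, `upper`) or a `msm_probtrans` object.
#' @export
predict.waitlist_msm <- function(object, s = 0, t = NULL, from = NULL,
                                 type = c("probability", "trajectory"),
                                 level = 0.95,
                                 ci_method = c("linear", "log"),
                                 variance = TRUE, ...) {
  type <- match.arg(type)
  ci_method <- match.arg(ci_method)
  if (!is.null(t) && any(t < s)) stop("report times must be >= origin `s`")
  traj <- aalen_johansen(object$hazards, s = s, report_times = t,
                         variance = variance)
  if (variance) traj <- confidence_interval(traj, level, ci_method)
  if (type == "trajectory") return(traj)
  out <- as.data.frame(traj)
  if (!is.null(t)) out <- out[out$time %in% t, , drop = FALSE]
  if (!is.null(from)) out <- out[out$from_index %in% from, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Martingale residuals of a fitted multi-state model
#'
#' For subject m and transition (i, j), the residual is the observed number
#' of (i, j) transitions minus the integrated hazard accumulated while the
#' subject occupied state i. Residuals sum to zero over subjects within
#' every transition.
#'
#' @param object A `waitlist_msm` fit.
#' @param ... Ignored.
#' @return A subjects x transitions matrix of residuals.
#' @export
residuals.waitlist_msm <- function(object, ...) {
  tab <- object$table
  subj <- unique(tab$subject_id)
  haz <- object$hazards
  ntr <- nrow(object$struct)
  res <- matrix(0, length(subj), ntr,
                dimnames = list(subj, object$struct$transition_id))
  cumA <- cbind(0, haz$A)  # cumulative hazard just after each event time
  pos <- function(tt) findInterval(tt, haz$times) + 1L
  inc <- cumA[cbind(tab$transition_id, pos(tab$t_stop))] -
    cumA[cbind(tab$transition_id, pos(tab$t_start))]
  m <- match(tab$subject_id, subj)
  lin <- (tab$transition_id - 1L) * length(subj) + m  # column-major index
  add <- rowsum(tab$status - inc, lin)
  res[as.integer(rownames(add))] <- add
  res
}

#' Simulate cohorts from a fitted model
#'
#' Draws trajectories from the fitted discrete-jump chain: at every observed
#' event time a subject in transient state i moves to j with probability
#' equal to the Nelson-Aalen increment dA_ij, independently across subjects.
#' Initial states are drawn from the fitted entry distribution; subjects
#' still transient at the end of follow-up are censored there.
#'
#' @param object A `waitlist_msm` fit.
#' @param nsim Number of cohorts.
#' @param seed Optional integer seed.
#' @param n_subjects Cohort size (defaults to the fitted cohort size).
#' @param ... Ignored.
#' @return A list of registrant-record data frames (length `nsim`).
#' @export
simulate.waitlist_msm <- function(object, nsim = 1, seed = NULL,
                                  n_subjects = object$n_subjects, ...) {
  if (!is.null(seed)) set.seed(seed)
  haz <- object$hazards
  space <- object$space
  init_p <- object$initial_counts / sum(object$initial_counts)
  ns <- nrow(space)
  K <- length(haz$times)
  # per-state jump distributions at each event time
  lapply(seq_len(nsim), function(b) {
    recs <- vector("list", n_subjects)
    for (m in seq_len(n_subjects)) {
      state <- sample.int(n_transient(space), 1L, prob = init_p)
      path_day <- numeric(0); path_state <- integer(0)
      start_state <- state
      terminal <- NA_integer_; term_day <- NA_real_
      for (k in seq_len(K)) {
        sel <- which(object$struct$from == state & haz$dA[, k] > 0)
        if (!length(sel)) next
        pj <- haz$dA[sel, k]
        stay <- 1 - sum(pj)
        dest <- sample(c(state, object$struct$to[sel]), 1L,
                       prob = c(max(stay, 0), pj))
        if (dest != state) {
          if (space$kind[dest] == "absorbing") {
            terminal <- dest; term_day <- haz$times[k]
            break
          }
          path_day <- c(path_day, haz$times[k])
          path_state <- c(path_state, dest)
          state <- dest
        }
      }
      recs[[m]] <- record_from_path(
        subject_id = sprintf("F%05d", m), space = space,
        start_state = start_state, jump_days = path_day,
        jump_states = path_state, terminal = terminal,
        terminal_day = term_day,
        censor_day = if (is.na(terminal)) object$max_time else NA_real_,
        listing_date = as.Date("2015-01-01"))
    }
    do.call(rbind, recs)
  })
}

#' Plot outcome probability curves from a fitted model
#'
#' Step curves of the cumulative probability of one absorbing outcome from a
#' set of origin states, from listing (s = 0).
#'
#' @param x A `waitlist_msm` fit.
#' @param outcome Absorbing-state label (default death/deterioration).
#' @param from Origin state indices (default all transient states).
#' @param max_t Largest time plotted (defaults to end of follow-up).
#' @param col Line colours.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the matrix of plotted curves.
#' @export
plot.waitlist_msm <- function(x, outcome = "death_or_deteriorated",
                              from = which(x$space$kind == "transient"),
                              max_t = x$max_time, col = NULL, ...) {
  k <- absorbing_index(x$space, outcome)
  traj <- aalen_johansen(x$hazards, s = 0, variance = FALSE)
  keep <- traj$times <= max_t
  curves <- t(traj$P[from, k, keep, drop = TRUE])
  if (is.null(dim(curves))) curves <- matrix(curves, ncol = length(from))
  if (is.null(col)) col <- seq_along(from)
  graphics::matplot(traj$times[keep], curves, type = "s", lty = 1, col = col,
                    xlab = "days since listing",
                    ylab = paste("P(", outcome, ")"), ...)
  graphics::legend("topleft", legend = x$space$label[from], col = col,
                   lty = 1, cex = 0.7, bty = "n")
  invisible(curves)
}
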