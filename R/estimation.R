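#' Counting-process quantities behind the estimators
#'
#' Computes, at every observed event time u, the number at risk in each
#' transient state, Y_i(u) (subjects occupying i just before u, i.e. with
#' t_start < u <= t_stop), and the number of observed transitions dN_ij(u)
#' for every allowed transition. Ties are kept: all transitions observed at
#' the same time enter the same event time.
#'
#' @param table Transition table from [prepare_transition_table()].
#' @param space,struct State space and transition structure; taken from the
#'   table attributes when omitted.
#' @return A list of class `msm_risk_profile` with elements `times` (sorted
#'   event times), `Y` (transient-states x times at-risk matrix), `dN`
#'   (transitions x times event-count matrix) and `n_subjects`.
#' @export
count_risk_and_events <- function(table, space = attr(table, "space"),
                                  struct = attr(table, "struct")) {
  nt <- n_transient(space)
  times <- sort(unique(table$t_stop[table$status == 1]))
  K <- length(times)
  # one at-risk interval per (subject, from, t_start, t_stop), not per row
  key <- !duplicated(paste(table$subject_id, table$from_index,
                           table$t_start, table$t_stop))
  iv <- table[key, c("subject_id", "from_index", "t_start", "t_stop")]
  Y <- matrix(0, nrow = nt, ncol = K,
              dimnames = list(seq_len(nt), NULL))
  for (i in seq_len(nt)) {
    starts <- sort(iv$t_start[iv$from_index == i])
    stops <- sort(iv$t_stop[iv$from_index == i])
    if (length(starts) && K) {
      Y[i, ] <- findInterval(times, starts, left.open = TRUE) -
        findInterval(times, stops, left.open = TRUE)
    }
  }
  dN <- matrix(0, nrow = nrow(struct), ncol = K,
               dimnames = list(struct$transition_id, NULL))
  ev <- table[table$status == 1, c("transition_id", "t_stop")]
  if (nrow(ev) && K) {
    tab <- table(factor(ev$transition_id, levels = struct$transition_id),
                 factor(match(ev$t_stop, times), levels = seq_len(K)))
    dN[] <- as.numeric(tab)
  }
  structure(list(times = times, Y = Y, dN = dN,
                 n_subjects = length(unique(table$subject_id)),
                 space = space, struct = struct),
            class = "msm_risk_profile")
}

#' Nelson-Aalen cumulative transition hazards
#'
#' Each allowed transition's cumulative hazard is a step function jumping by
#' dN_ij(u) / Y_i(u) at every observed event time. The variance increment is
#' of Greenwood type, dN_ij (Y_i - dN_ij) / Y_i^3, by default; a Poisson-type
#' increment dN_ij / Y_i^2 is available for sensitivity checks.
#'
#' @param profile Risk profile from [count_risk_and_events()].
#' @param variance Variance increment type, `"greenwood"` (default) or
#'   `"poisson"`.
#' @return A list of class `msm_cumhaz` with `times`, jump matrices `dA` and
#'   `var_dA` (transitions x times), cumulative matrices `A` and `var_A`, and
#'   the space/structure.
#' @export
nelson_aalen <- function(profile, variance = c("greenwood", "poisson")) {
  variance <- match.arg(variance)
  struct <- profile$struct
  Yfrom <- profile$Y[struct$from, , drop = FALSE]
  dN <- profile$dN
  if (any(dN > 0 & Yfrom <= 0)) {
    stop("internal error: event observed with empty risk set")
  }
  dA <- ifelse(Yfrom > 0, dN / Yfrom, 0)
  var_dA <- if (variance == "greenwood") {
    ifelse(Yfrom > 0, dN * (Yfrom - dN) / Yfrom^3, 0)
  } else {
    ifelse(Yfrom > 0, dN / Yfrom^2, 0)
  }
  row_cumsum <- function(m) if (ncol(m) > 1L) t(apply(m, 1L, cumsum)) else m
  A <- row_cumsum(dA)
  var_A <- row_cumsum(var_dA)
  structure(list(times = profile$times, dA = dA, var_dA = var_dA,
                 A = A, var_A = var_A, dN = dN, Y = profile$Y,
                 n_subjects = profile$n_subjects,
                 space = profile$space, struct = struct,
                 variance = variance),
            class = "msm_cumhaz")
}

#' @export
print.msm_cumhaz <- function(x, ...) {
  cat("Nelson-Aalen cumulative hazards:", nrow(x$dA), "transitions,",
      length(x$times), "event times,", sum(x$dN), "events\n")
  invisible(x)
}

#' Long-format hazard increments
#'
#' @param x A `msm_cumhaz` object.
#' @param row.names,optional,... Ignored (S3 signature).
#' @return Data frame with columns `transition_id`, `time`, `dA`, `var_dA`,
#'   one row per observed jump of each transition.
#' @export
as.data.frame.msm_cumhaz <- function(x, row.names = NULL, optional = FALSE, ...) {
  idx <- which(x$dN > 0, arr.ind = TRUE)
  out <- data.frame(transition_id = x$struct$transition_id[idx[, 1]],
                    time = x$times[idx[, 2]],
                    dA = x$dA[idx], var_dA = x$var_dA[idx])
  out[order(out$transition_id, out$time), , drop = FALSE]
}

# covariance of the dA row of state i at one event time under multinomial
# sampling; coordinates are the 16 states, including the diagonal element
# dA_ii = -sum_j dA_ij.
row_increment_cov <- function(i, dn, y, nstate, greenwood = TRUE) {
  C <- matrix(0, nstate, nstate)
  j <- which(dn > 0)
  if (!length(j) || y <= 0) return(C)
  if (greenwood) {
    C[j, j] <- -outer(dn[j], dn[j]) / y^3
    diag(C)[j] <- dn[j] * (y - dn[j]) / y^3
  } else {
    diag(C)[j] <- dn[j] / y^2
  }
  C[i, ] <- -colSums(C[j, , drop = FALSE])
  C[, i] <- C[i, ]
  C[i, i] <- sum(C[j, j])
  C
}

#' Aalen-Johansen transition probabilities
#'
#' Estimates the matrix-valued transition probability P(s, t) as the finite
#' product over event times u in (s, t] of (I + dA(u)), where dA(u) carries
#' the Nelson-Aalen increments off-diagonal and minus their row sums on the
#' diagonal; absorbing states have identity rows. Variances are propagated
#' recursively per origin row (Greenwood-type plug-in): with B = I + dA(u)
#' and p the origin row of P(s, u-),
#' V(u) = B' V(u-) B + sum_i p_i^2 Cov(dA_i.(u)).
#'
#' @param hazards Cumulative hazards from [nelson_aalen()].
#' @param s Prediction origin in days (default 0).
#' @param report_times Additional times to include in the output grid.
#' @param variance Compute Greenwood-type standard errors (default TRUE).
#' @return A list of class `msm_probtrans` with `s`, `times` (grid, starting
#'   at `s`), `P` (states x states x times array) and `var` (same shape).
#' @export
aalen_johansen <- function(hazards, s = 0, report_times = NULL,
                           variance = TRUE) {
  if (s < 0) stop("prediction origin `s` must be non-negative")
  space <- hazards$space
  ns <- nrow(space)
  nt <- n_transient(space)
  struct <- hazards$struct
  ev <- hazards$times[hazards$times > s]
  if (length(hazards$times) && s > max(hazards$times) ) {
    warning("prediction origin beyond last observed event; returning identity")
  }
  grid <- sort(unique(c(s, ev, report_times[report_times >= s])))
  K <- length(grid)
  P <- array(0, dim = c(ns, ns, K))
  Varr <- array(0, dim = c(ns, ns, K))
  Pcur <- diag(ns)
  Vcur <- vector("list", nt)
  for (o in seq_len(nt)) Vcur[[o]] <- matrix(0, ns, ns)
  greenwood <- !identical(hazards$variance, "poisson")
  store <- function(k) {
    P[, , k] <<- Pcur
    if (variance) for (o in seq_len(nt)) Varr[o, , k] <<- diag(Vcur[[o]])
  }
  store(1L)
  if (K > 1L) for (k in 2:K) {
    u <- grid[k]
    j <- which(hazards$times == u)
    if (length(j)) {
      dn_col <- hazards$dN[, j]
      active_rows <- sort(unique(struct$from[dn_col > 0]))
      B <- diag(ns)
      for (i in active_rows) {
        sel <- struct$from == i
        dest <- struct$to[sel]
        da <- hazards$dA[sel, j]
        B[i, dest] <- B[i, dest] + da
        B[i, i] <- B[i, i] - sum(da)
      }
      if (variance && length(active_rows)) {
        Clist <- lapply(active_rows, function(i) {
          sel <- struct$from == i
          dn <- numeric(ns); dn[struct$to[sel]] <- dn_col[sel]
          row_increment_cov(i, dn, hazards$Y[i, j], ns, greenwood)
        })
        for (o in seq_len(nt)) {
          extra <- matrix(0, ns, ns)
          for (a in seq_along(active_rows)) {
            p <- Pcur[o, active_rows[a]]
            if (p > 0) extra <- extra + p^2 * Clist[[a]]
          }
          Vcur[[o]] <- crossprod(B, Vcur[[o]] %*% B) + extra
        }
      } else if (length(active_rows)) {
        if (variance) for (o in seq_len(nt))
          Vcur[[o]] <- crossprod(B, Vcur[[o]] %*% B)
      }
      Pcur <- Pcur %*% B
    }
    store(k)
  }
  structure(list(s = s, times = grid, P = P, var = Varr,
                 variance = variance, space = space, struct = struct),
            class = "msm_probtrans")
}

#' @export
print.msm_probtrans <- function(x, ...) {
  cat("Aalen-Johansen transition probabilities: origin s =", x$s,
      "days,", length(x$times), "grid times up to day", max(x$times), "\n")
  invisible(x)
}

# index of the last grid time <= t (right-continuous step function)
grid_index <- function(trajectory, t) {
  i <- findInterval(t, trajectory$times)
  if (any(i == 0)) stop("requested time before the prediction origin")
  i
}

#' Extract P(s, t) as a matrix
#'
#' @param trajectory Output of [aalen_johansen()].
#' @param t Time (days); the step function is right-continuous.
#' @return The states x states probability matrix P(s, t).
#' @export
transition_matrix <- function(trajectory, t) {
  trajectory$P[, , grid_index(trajectory, t)]
}

#' Greenwood-type standard errors for a probability trajectory
#'
#' Recomputes the recursive plug-in variance propagation for an existing
#' trajectory from its hazard set (used when the trajectory was built with
#' `variance = FALSE`). In the two-state reduction (one transient, one
#' absorbing state) the survival-entry variance equals the classical
#' Greenwood formula.
#'
#' @param hazards Cumulative hazards from [nelson_aalen()].
#' @param trajectory Trajectory produced from the same hazards.
#' @return The trajectory with the `var` array filled in.
#' @export
greenwood_variance <- function(hazards, trajectory) {
  full <- aalen_johansen(hazards, s = trajectory$s,
                         report_times = trajectory$times, variance = TRUE)
  idx <- match(trajectory$times, full$times)
  trajectory$var <- full$var[, , idx, drop = FALSE]
  trajectory$variance <- TRUE
  trajectory
}

#' Confidence bands for transition probabilities
#'
#' Symmetric normal-approximation bands truncated to \[0, 1\] (default), or
#' log-transformed bands p * exp(+/- z * se / p) for entries bounded away
#' from zero.
#'
#' @param trajectory Output of [aalen_johansen()] with variances.
#' @param level Confidence level in (0, 1).
#' @param method `"linear"` (default) or `"log"`.
#' @return The trajectory with `lower` and `upper` arrays and the level
#'   attached.
#' @export
confidence_interval <- function(trajectory, level = 0.95,
                                method = c("linear", "log")) {
  method <- match.arg(method)
  if (!(level > 0 && level < 1)) stop("`level` must be in (0, 1)")
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(pmax(trajectory$var, 0))
  p <- trajectory$P
  if (method == "linear") {
    lower <- pmax(p - z * se, 0)
    upper <- pmin(p + z * se, 1)
  } else {
    lower <- p; upper <- p
    pos <- p > 0 & se > 0
    lower[pos] <- p[pos] * exp(-z * se[pos] / p[pos])
    upper[pos] <- pmin(p[pos] * exp(z * se[pos] / p[pos]), 1)
  }
  trajectory$lower <- lower
  trajectory$upper <- upper
  trajectory$level <- level
  trajectory$ci_method <- method
  trajectory
}

#' Long-format probability estimates
#'
#' @param x A `msm_probtrans` object (run through [confidence_interval()] for
#'   bands).
#' @param row.names,optional,... Ignored (S3 signature).
#' @return Data frame with columns `origin_s`, `time`, `from_index`,
#'   `to_index`, `estimate`, `se`, `lower`, `upper`.
#' @export
as.data.frame.msm_probtrans <- function(x, row.names = NULL, optional = FALSE,
                                        ...) {
  ns <- dim(x$P)[1]; K <- dim(x$P)[3]
  out <- data.frame(
    origin_s = x$s,
    time = rep(x$times, each = ns * ns),
    from_index = rep(seq_len(ns), times = ns * K),
    to_index = rep(rep(seq_len(ns), each = ns), times = K),
    estimate = as.vector(x$P),
    se = sqrt(pmax(as.vector(x$var), 0)),
    lower = if (!is.null(x$lower)) as.vector(x$lower) else NA_real_,
    upper = if (!is.null(x$upper)) as.vector(x$upper) else NA_real_)
  out[order(out$time, out$from_index, out$to_index), , drop = FALSE]
}
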