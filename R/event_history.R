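#' Censoring scheme for the policy-change analysis
#'
#' Two schemes are used around an allocation-policy change date: (i) censor at
#' the policy date, so that follow-up of earlier registrants is cut at the
#' boundary and any later terminal event becomes censoring; (ii) lift the
#' policy censoring and follow registrants to an administrative horizon.
#'
#' @param policy_date Calendar date of the policy change (default the kidney
#'   allocation system effective date, 2014-12-04); used only when
#'   `censor_at_policy` is TRUE.
#' @param censor_at_policy Censor follow-up at `policy_date`?
#' @param admin_horizon_day Administrative horizon in days since listing
#'   (optional); applied whenever present.
#' @return A list of class `msm_censoring_scheme`.
#' @export
censoring_scheme <- function(policy_date = as.Date("2014-12-04"),
                             censor_at_policy = FALSE,
                             admin_horizon_day = NULL) {
  if (isTRUE(censor_at_policy) && is.null(policy_date)) {
    stop("`policy_date` must be given when `censor_at_policy` is TRUE")
  }
  if (!is.null(admin_horizon_day) && admin_horizon_day <= 0) {
    stop("`admin_horizon_day` must be positive")
  }
  structure(list(policy_date = policy_date,
                 censor_at_policy = isTRUE(censor_at_policy),
                 admin_horizon_day = admin_horizon_day),
            class = "msm_censoring_scheme")
}

#' Apply cohort eligibility filters
#'
#' Retains adult (age strictly greater than 18) first-time kidney-only
#' registrants listed within the window. Per-rule exclusion counts are
#' reported via `message()` and attached as attribute `exclusions`.
#'
#' @param records Registrant records data frame (see [read_registrants()]).
#' @param window_start,window_end Listing-date window (inclusive).
#' @return The filtered records.
#' @export
filter_cohort <- function(records, window_start, window_end) {
  window_start <- as.Date(window_start); window_end <- as.Date(window_end)
  need <- c("listing_date", "age_at_listing", "first_time", "multi_organ")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack eligibility fields: ",
                         paste(miss, collapse = ", "))
  ld <- as.Date(records$listing_date)
  bad_fields <- is.na(ld) | is.na(records$age_at_listing) |
    is.na(records$first_time) | is.na(records$multi_organ)
  in_window <- !bad_fields & ld >= window_start & ld <= window_end
  adult <- !bad_fields & records$age_at_listing > 18
  first <- !bad_fields & records$first_time
  single <- !bad_fields & !records$multi_organ
  keep <- in_window & adult & first & single
  excl <- c(missing_fields = sum(bad_fields),
            outside_window = sum(!in_window & !bad_fields),
            age_18_or_younger = sum(!adult & !bad_fields),
            repeat_registration = sum(!first & !bad_fields),
            multi_organ = sum(!single & !bad_fields))
  for (rule in names(excl)) {
    if (excl[[rule]] > 0)
      message("filter_cohort: excluded ", excl[[rule]], " record(s): ", rule)
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- excl
  out
}

parse_updates <- function(s) {
  # "day:cpra:status;day:cpra:status" ; empty cpra or status = unchanged
  if (is.na(s) || !nzchar(s)) {
    return(data.frame(day = numeric(0), cpra = numeric(0),
                      status = character(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  day <- vapply(parts, function(p) as.numeric(p[1]), 0)
  cpra <- vapply(parts, function(p)
    if (length(p) >= 2 && nzchar(p[2])) as.numeric(p[2]) else NA_real_, 0)
  status <- vapply(parts, function(p)
    if (length(p) >= 3 && nzchar(p[3])) p[3] else NA_character_, "")
  if (is.unsorted(day)) stop("update days must be non-decreasing")
  data.frame(day = day, cpra = cpra, status = status,
             stringsAsFactors = FALSE)
}

encode_updates <- function(day, cpra, status) {
  if (length(day) == 0) return("")
  paste(sprintf("%s:%s:%s", format(day, trim = TRUE, scientific = FALSE),
                ifelse(is.na(cpra), "",
                       format(cpra, trim = TRUE, scientific = FALSE)),
                ifelse(is.na(status), "", status)),
        collapse = ";")
}

#' Convert one registrant record into a state trajectory
#'
#' The entry state at day 0 is determined by the initial CPRA and activity
#' status. Updates that do not change the occupied state produce no interval
#' boundary; multiple updates on the same day are merged into a single change
#' to the combined new state (daily resolution is the registry's effective
#' granularity). A terminal event closes the last interval into its absorbing
#' destination; otherwise the last interval ends at the censoring day. A
#' terminal event falling exactly on the start of the current interval is
#' shifted by half a day so the subject contributes risk time; zero-length
#' intervals are dropped with a warning.
#'
#' @param record A single-row registrant data frame (or a list with the same
#'   fields).
#' @param space State space from [build_state_space()].
#' @return A data frame with columns `state`, `start`, `end`, `end_state`
#'   (absorbing/transient index reached, or NA when censored).
#' @export
trajectory_from_record <- function(record, space = build_state_space()) {
  rec <- as.list(record)
  categories <- attr(space, "categories")
  if (is.na(rec$initial_cpra)) {
    message("missing CPRA at listing for subject ", rec$subject_id,
            "; mapped to 0%")
    rec$initial_cpra <- 0
  }
  upd <- parse_updates(if (is.null(rec$updates)) "" else rec$updates)
  term_day <- if (is.null(rec$terminal_day)) NA_real_ else as.numeric(rec$terminal_day)
  term_state <- if (is.null(rec$terminal_state)) NA else rec$terminal_state
  cens_day <- if (is.null(rec$censor_day)) NA_real_ else as.numeric(rec$censor_day)
  has_term <- !is.na(term_day)
  if (has_term && !is.na(cens_day)) {
    stop("subject ", rec$subject_id, ": terminal event and censoring are mutually exclusive")
  }
  if (!has_term && is.na(cens_day)) {
    stop("subject ", rec$subject_id, ": record has neither terminal event nor censoring day")
  }
  end_day <- if (has_term) term_day else cens_day
  if (nrow(upd) && any(upd$day > end_day)) {
    stop("subject ", rec$subject_id, ": update after terminal/censoring day")
  }

  # merge same-day updates: last stated value of each field wins
  if (nrow(upd)) {
    upd <- do.call(rbind, lapply(split(upd, upd$day), function(d) {
      data.frame(day = d$day[1],
                 cpra = if (all(is.na(d$cpra))) NA_real_ else d$cpra[max(which(!is.na(d$cpra)))],
                 status = if (all(is.na(d$status))) NA_character_ else d$status[max(which(!is.na(d$status)))],
                 stringsAsFactors = FALSE)
    }))
    upd <- upd[order(upd$day), , drop = FALSE]
  }

  cur_cat <- categorize_cpra(rec$initial_cpra, categories)
  cur_status <- match.arg(rec$initial_status, c("active", "inactive"))
  cur_state <- state_index(space, cur_cat, cur_status)
  cur_start <- 0
  out_state <- integer(0); out_start <- numeric(0); out_end <- numeric(0)
  out_dest <- integer(0)

  if (nrow(upd)) for (i in seq_len(nrow(upd))) {
    new_cat <- if (is.na(upd$cpra[i])) cur_cat else categorize_cpra(upd$cpra[i], categories)
    new_status <- if (is.na(upd$status[i])) cur_status else
      match.arg(upd$status[i], c("active", "inactive"))
    new_state <- state_index(space, new_cat, new_status)
    if (new_state == cur_state) { cur_cat <- new_cat; cur_status <- new_status; next }
    if (upd$day[i] > cur_start) {
      out_state <- c(out_state, cur_state); out_start <- c(out_start, cur_start)
      out_end <- c(out_end, upd$day[i]); out_dest <- c(out_dest, new_state)
      cur_start <- upd$day[i]
    } else {
      warning("subject ", rec$subject_id,
              ": zero-length interval at day ", upd$day[i], " dropped")
    }
    cur_cat <- new_cat; cur_status <- new_status; cur_state <- new_state
  }

  if (has_term) {
    if (end_day <= cur_start) {
      end_day <- cur_start + 0.5
      warning("subject ", rec$subject_id,
              ": terminal event at interval start shifted by half a day")
    }
    dest <- if (is.character(term_state)) absorbing_index(space, term_state)
            else as.integer(term_state)
    out_state <- c(out_state, cur_state); out_start <- c(out_start, cur_start)
    out_end <- c(out_end, end_day); out_dest <- c(out_dest, dest)
  } else {
    if (end_day > cur_start) {
      out_state <- c(out_state, cur_state); out_start <- c(out_start, cur_start)
      out_end <- c(out_end, end_day); out_dest <- c(out_dest, NA_integer_)
    } else if (end_day == cur_start && length(out_state)) {
      # censoring exactly at a state change: the final state carries no risk time
      warning("subject ", rec$subject_id,
              ": zero-length final interval at day ", end_day, " dropped")
    } else if (length(out_state) == 0) {
      # censored at day 0 with no history: contributes nothing
      warning("subject ", rec$subject_id, ": censored at entry, no risk time")
    }
  }
  data.frame(state = out_state, start = out_start, end = out_end,
             end_state = out_dest)
}

#' Apply a censoring scheme to a trajectory
#'
#' Truncates the trajectory at the applicable boundary: the per-subject policy
#' boundary (`policy_date - listing_date`) when `censor_at_policy` is set, and
#' the administrative horizon when present. A terminal event beyond the
#' boundary becomes censoring. Idempotent. A boundary at or before listing
#' yields an empty trajectory (the subject contributes nothing).
#'
#' @param trajectory Output of [trajectory_from_record()].
#' @param record The matching registrant record (for its listing date).
#' @param scheme A [censoring_scheme()].
#' @return The truncated trajectory.
#' @export
apply_censoring <- function(trajectory, record, scheme = censoring_scheme()) {
  stopifnot(inherits(scheme, "msm_censoring_scheme"))
  bound <- Inf
  if (scheme$censor_at_policy) {
    rec <- as.list(record)
    bound <- as.numeric(as.Date(scheme$policy_date) - as.Date(rec$listing_date))
  }
  if (!is.null(scheme$admin_horizon_day)) {
    bound <- min(bound, scheme$admin_horizon_day)
  }
  if (!is.finite(bound)) return(trajectory)
  if (bound <= 0) return(trajectory[0, , drop = FALSE])
  keep <- trajectory$start < bound
  out <- trajectory[keep, , drop = FALSE]
  cut <- out$end > bound
  out$end[cut] <- bound
  out$end_state[cut] <- NA_integer_
  rownames(out) <- NULL
  out
}

#' Expand registrant records into the long-format transition table
#'
#' Each state interval contributes one at-risk row per allowed transition out
#' of its state; `status` is 1 only for the realized transition. Rows are
#' ordered by (subject_id, t_start, transition_id).
#'
#' @param records Registrant records data frame.
#' @param space State space.
#' @param struct Transition structure.
#' @param scheme Censoring scheme applied to every trajectory.
#' @return A data frame of class `msm_transition_table` with columns
#'   `subject_id`, `from_index`, `to_index`, `transition_id`, `t_start`,
#'   `t_stop`, `status`.
#' @export
prepare_transition_table <- function(records, space = build_state_space(),
                                     struct = build_transition_structure(space),
                                     scheme = censoring_scheme()) {
  categories <- attr(space, "categories")
  simple <- (is.na(records$updates) | !nzchar(records$updates)) &
    !is.na(records$initial_cpra) &
    xor(is.na(records$terminal_day), is.na(records$censor_day))
  ivs_fast <- NULL
  if (any(simple)) {
    # single-interval records: vectorized construction
    rs <- records[simple, , drop = FALSE]
    st <- state_index(space, categorize_cpra(rs$initial_cpra, categories),
                      rs$initial_status)
    has_term <- !is.na(rs$terminal_day)
    end <- ifelse(has_term, rs$terminal_day, rs$censor_day)
    shift <- has_term & end <= 0
    if (any(shift)) {
      end[shift] <- 0.5
      warning(sum(shift), " terminal event(s) at day 0 shifted by half a day")
    }
    dest <- rep(NA_integer_, nrow(rs))
    dest[has_term] <- absorbing_index(space, rs$terminal_state[has_term])
    ivs_fast <- data.frame(state = st, start = 0, end = end,
                           end_state = dest, subject_id = rs$subject_id)
    keep <- end > 0
    if (any(!keep)) warning(sum(!keep), " record(s) censored at entry dropped")
    ivs_fast <- ivs_fast[keep, , drop = FALSE]
  }
  slow_idx <- which(!simple)
  ivs <- vector("list", length(slow_idx))
  for (k in seq_along(slow_idx)) {
    i <- slow_idx[k]
    tr <- trajectory_from_record(records[i, , drop = FALSE], space)
    if (nrow(tr)) {
      tr$subject_id <- records$subject_id[i]
      ivs[[k]] <- tr
    }
  }
  ivs <- do.call(rbind, c(list(ivs_fast), ivs[!vapply(ivs, is.null, TRUE)]))
  if (!is.null(ivs) && nrow(ivs) &&
      (scheme$censor_at_policy || !is.null(scheme$admin_horizon_day))) {
    bound <- rep(Inf, nrow(ivs))
    if (scheme$censor_at_policy) {
      ld <- as.Date(records$listing_date[match(ivs$subject_id,
                                               records$subject_id)])
      bound <- as.numeric(as.Date(scheme$policy_date) - ld)
    }
    if (!is.null(scheme$admin_horizon_day)) {
      bound <- pmin(bound, scheme$admin_horizon_day)
    }
    keep <- ivs$start < bound & bound > 0
    ivs <- ivs[keep, , drop = FALSE]
    bound <- bound[keep]
    cut <- ivs$end > bound
    ivs$end[cut] <- bound[cut]
    ivs$end_state[cut] <- NA_integer_
  }
  if (is.null(ivs) || nrow(ivs) == 0) {
    out <- data.frame(subject_id = character(0), from_index = integer(0),
                      to_index = integer(0), transition_id = integer(0),
                      t_start = numeric(0), t_stop = numeric(0),
                      status = integer(0))
    class(out) <- c("msm_transition_table", "data.frame")
    attr(out, "space") <- space; attr(out, "struct") <- struct
    return(out)
  }
  lookup <- transition_lookup(struct)
  bad <- !is.na(ivs$end_state) &
    is.na(lookup[cbind(ivs$state, ivs$end_state)])
  if (any(bad)) {
    stop("internal consistency error: realized transition not in structure (",
         paste(unique(paste0(ivs$state[bad], "->", ivs$end_state[bad])),
               collapse = ", "), ")")
  }
  dest_by_from <- split(struct$to, struct$from)
  id_by_from <- split(struct$transition_id, struct$from)
  counts <- lengths(dest_by_from)[as.character(ivs$state)]
  rep_i <- rep(seq_len(nrow(ivs)), times = counts)
  to <- unlist(dest_by_from[as.character(ivs$state)], use.names = FALSE)
  tid <- unlist(id_by_from[as.character(ivs$state)], use.names = FALSE)
  out <- data.frame(subject_id = ivs$subject_id[rep_i],
                    from_index = ivs$state[rep_i],
                    to_index = to,
                    transition_id = tid,
                    t_start = ivs$start[rep_i],
                    t_stop = ivs$end[rep_i],
                    status = as.integer(!is.na(ivs$end_state[rep_i]) &
                                          ivs$end_state[rep_i] == to))
  out <- out[order(out$subject_id, out$t_start, out$transition_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "space") <- space
  attr(out, "struct") <- struct
  class(out) <- c("msm_transition_table", "data.frame")
  out
}
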