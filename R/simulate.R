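#' Piecewise-constant transition intensity model
#'
#' Holds per-transition rates (per day) on consecutive time pieces. Rates
#' exist only for transitions in the allowed structure, so the forbidden
#' inactive-to-deceased-donor moves are structurally impossible.
#'
#' @param struct Transition structure from [build_transition_structure()].
#' @param rates Numeric vector of length `nrow(struct)` (one piece) or a
#'   pieces x transitions matrix.
#' @param breakpoints Increasing piece start days, first element 0.
#' @return A list of class `msm_intensity_model`.
#' @export
intensity_model <- function(struct, rates, breakpoints = 0) {
  if (is.null(dim(rates))) rates <- matrix(rates, nrow = 1)
  if (ncol(rates) != nrow(struct)) {
    stop("`rates` must have one column per allowed transition (",
         nrow(struct), ")")
  }
  if (length(breakpoints) != nrow(rates) || breakpoints[1] != 0 ||
      is.unsorted(breakpoints, strictly = TRUE)) {
    stop("`breakpoints` must be increasing, start at 0, one per rate row")
  }
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("rates must be finite and non-negative")
  }
  structure(list(struct = struct, space = attr(struct, "space"),
                 rates = rates, breakpoints = breakpoints),
            class = "msm_intensity_model")
}

#' @export
print.msm_intensity_model <- function(x, ...) {
  cat("Piecewise-constant intensity model:", nrow(x$rates), "piece(s),",
      sum(x$rates[1, ] > 0), "positive rates in piece 1\n")
  invisible(x)
}

# generator matrix (states x states) for one piece
piece_generator <- function(model, piece) {
  ns <- nrow(model$space)
  Q <- matrix(0, ns, ns)
  Q[cbind(model$struct$from, model$struct$to)] <- model$rates[piece, ]
  diag(Q) <- -rowSums(Q)
  Q
}

#' Build a per-transition rate vector from named rule rates
#'
#' Convenience constructor for scenario intensity vectors. CPRA moves are
#' restricted to adjacent categories; all other transient-transient rates
#' are zero. Deceased-donor rates apply to active states only (the inactive
#' transitions do not exist in the structure).
#'
#' @param space State space.
#' @param struct Transition structure.
#' @param activation Inactive -> active rate (same category).
#' @param inactivation Active -> inactive rate (same category).
#' @param cpra_up,cpra_down Adjacent-category move rates (status preserved).
#' @param death_active,death_inactive Death/deterioration rates.
#' @param deceased_donor Deceased-donor transplant rate(s) from active
#'   states: scalar or one value per CPRA category.
#' @param living_donor Living-donor transplant rate (all states).
#' @param removal Other-removal rate (all states).
#' @return Numeric vector of rates aligned with `struct$transition_id`.
#' @export
transition_rates <- function(space, struct,
                             activation = 0, inactivation = 0,
                             cpra_up = 0, cpra_down = 0,
                             death_active = 0, death_inactive = 0,
                             deceased_donor = 0, living_donor = 0,
                             removal = 0) {
  ncat <- max(space$cpra_index, na.rm = TRUE)
  if (length(deceased_donor) == 1) deceased_donor <- rep(deceased_donor, ncat)
  fcat <- space$cpra_index[struct$from]
  fact <- space$status[struct$from]
  tcat <- space$cpra_index[struct$to]
  tact <- space$status[struct$to]
  tlab <- space$label[struct$to]
  r <- numeric(nrow(struct))
  same_cat <- !is.na(tcat) & tcat == fcat
  r[same_cat & fact == "inactive" & tact == "active"] <- activation
  r[same_cat & fact == "active" & tact == "inactive"] <- inactivation
  adj_up <- !is.na(tcat) & tcat == fcat + 1 & tact == fact
  adj_dn <- !is.na(tcat) & tcat == fcat - 1 & tact == fact
  r[adj_up] <- cpra_up
  r[adj_dn] <- cpra_down
  is_death <- tlab == "death_or_deteriorated"
  r[is_death & fact == "active"] <- death_active
  r[is_death & fact == "inactive"] <- death_inactive
  ddtx <- tlab == "deceased_donor_transplant"
  r[ddtx] <- deceased_donor[fcat[ddtx]]
  r[tlab == "living_donor_transplant"] <- living_donor
  r[tlab == "removed_other"] <- removal
  r
}

#' Scenario configuration for the cohort simulator
#'
#' @param n_subjects Cohort size.
#' @param seed Integer seed for the single RNG stream.
#' @param initial_state_distribution Probability vector over the transient
#'   states (sums to 1).
#' @param intensities A [intensity_model()].
#' @param censoring_rate Exponential right-censoring rate per day, or NULL
#'   for none.
#' @param admin_horizon_day Administrative horizon (days since listing).
#' @param listing_start,listing_end Listing-date window (dates); listing
#'   dates are drawn uniformly over the window.
#' @param day_resolution `"continuous"` keeps exact event times;
#'   `"day"` rounds update/outcome days up to whole days, emulating registry
#'   granularity.
#' @return A list of class `msm_scenario`.
#' @export
scenario_config <- function(n_subjects, seed = 1L,
                            initial_state_distribution,
                            intensities,
                            censoring_rate = NULL,
                            admin_horizon_day = 1095,
                            listing_start = as.Date("2015-01-01"),
                            listing_end = as.Date("2015-12-31"),
                            day_resolution = c("continuous", "day")) {
  day_resolution <- match.arg(day_resolution)
  stopifnot(n_subjects >= 1, inherits(intensities, "msm_intensity_model"))
  p <- initial_state_distribution
  nt <- n_transient(intensities$space)
  if (length(p) != nt || abs(sum(p) - 1) > 1e-8 || any(p < 0)) {
    stop("`initial_state_distribution` must be a probability vector over the ",
         nt, " transient states")
  }
  if (is.null(admin_horizon_day)) {
    last <- intensities$rates[nrow(intensities$rates), ]
    exit <- vapply(seq_len(nt), function(i)
      sum(last[intensities$struct$from == i]), 0)
    if (any(exit == 0)) {
      stop("an administrative horizon is required: some states have ",
           "all-zero exit rates and would never terminate")
    }
  }
  structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 initial_state_distribution = p, intensities = intensities,
                 censoring_rate = censoring_rate,
                 admin_horizon_day = admin_horizon_day,
                 listing_start = as.Date(listing_start),
                 listing_end = as.Date(listing_end),
                 day_resolution = day_resolution),
            class = "msm_scenario")
}

#' Default waitlist-like scenario
#'
#' Initial states concentrated on the two lowest sensitization categories
#' (about 98% of registrants, mostly active), modest inactivation and
#' reactivation, elevated death intensity from inactive states, and
#' deceased-donor rates varying with CPRA category. The numeric rates are
#' illustrative fixtures for building and testing, not registry estimates.
#'
#' @param n_subjects Cohort size.
#' @param seed Integer seed.
#' @param ... Overrides passed to [scenario_config()].
#' @return A `msm_scenario`.
#' @export
scenario_registry_like <- function(n_subjects = 2000, seed = 1L, ...) {
  space <- build_state_space()
  struct <- build_transition_structure(space)
  cat_p <- c(0.660, 0.321, 0.0059, 0.0036, 0.0045, 0.0051)
  cat_p <- cat_p / sum(cat_p)
  init <- as.vector(rbind(cat_p * 0.85, cat_p * 0.15))
  rates <- transition_rates(
    space, struct,
    activation = 2.5e-3, inactivation = 8e-4,
    cpra_up = 1.2e-4, cpra_down = 8e-5,
    death_active = 2.5e-4, death_inactive = 6e-4,
    deceased_donor = c(3.5e-4, 3.5e-4, 3.0e-4, 3.0e-4, 2.5e-4, 2.0e-4),
    living_donor = 1.2e-4, removal = 1.0e-4)
  args <- list(n_subjects = n_subjects, seed = seed,
               initial_state_distribution = init,
               intensities = intensity_model(struct, rates),
               censoring_rate = NULL, admin_horizon_day = 1095)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(scenario_config, args)
}

# draw one holding time from a piecewise-constant total exit rate by
# inversion: accumulate hazard across pieces until it reaches an Exp(1) draw
piecewise_exit_time <- function(t0, breakpoints, total_rates, horizon) {
  e <- stats::rexp(1)
  np <- length(breakpoints)
  t <- t0
  acc <- 0
  repeat {
    piece <- findInterval(t, breakpoints)
    lam <- total_rates[piece]
    piece_end <- if (piece < np) breakpoints[piece + 1] else Inf
    if (lam <= 0) {
      if (!is.finite(piece_end) || piece_end >= horizon) return(Inf)
      t <- piece_end
      next
    }
    need <- (e - acc) / lam
    if (t + need <= piece_end) return(t + need)
    acc <- acc + lam * (piece_end - t)
    t <- piece_end
    if (t >= horizon) return(Inf)
  }
}

record_from_path <- function(subject_id, space, start_state, jump_days,
                             jump_states, terminal, terminal_day, censor_day,
                             listing_date, covariates = NULL) {
  categories <- attr(space, "categories")
  rep_cpra <- categories$lower  # representative percent per category
  init_cpra <- rep_cpra[space$cpra_index[start_state]]
  prev_cat <- space$cpra_index[start_state]
  prev_status <- space$status[start_state]
  up_day <- numeric(0); up_cpra <- numeric(0); up_status <- character(0)
  for (k in seq_along(jump_days)) {
    st <- jump_states[k]
    cat_k <- space$cpra_index[st]; stat_k <- space$status[st]
    up_day <- c(up_day, jump_days[k])
    up_cpra <- c(up_cpra, if (cat_k != prev_cat) rep_cpra[cat_k] else NA_real_)
    up_status <- c(up_status, if (stat_k != prev_status) stat_k else NA_character_)
    prev_cat <- cat_k; prev_status <- stat_k
  }
  base <- data.frame(
    subject_id = subject_id,
    listing_date = listing_date,
    age_at_listing = if (is.null(covariates$age_at_listing)) 50
                     else covariates$age_at_listing,
    first_time = TRUE, multi_organ = FALSE,
    age_group = if (is.null(covariates$age_group)) "40-64"
                else covariates$age_group,
    gender = if (is.null(covariates$gender)) "Male" else covariates$gender,
    abo = if (is.null(covariates$abo)) "O" else covariates$abo,
    race = if (is.null(covariates$race)) "White" else covariates$race,
    esrd_diagnosis = if (is.null(covariates$esrd_diagnosis)) "Other"
                     else covariates$esrd_diagnosis,
    initial_cpra = init_cpra,
    initial_status = space$status[start_state],
    updates = encode_updates(up_day, up_cpra, up_status),
    terminal_day = terminal_day,
    terminal_state = if (!is.na(terminal)) space$label[terminal]
                     else NA_character_,
    censor_day = censor_day,
    stringsAsFactors = FALSE)
  base
}

#' Simulate one registrant trajectory
#'
#' Samples a trajectory of the piecewise-constant Markov process: the
#' initial state, then alternating holding-time draws (inversion across
#' pieces of the total exit intensity) and destination draws (probability
#' proportional to the destination rates at the transition instant), stopped
#' at absorption, at an independent exponential censoring draw, or at the
#' administrative horizon.
#'
#' @param config A [scenario_config()]; its seed is NOT set here (the
#'   cohort-level stream is managed by [simulate_cohort()]).
#' @param subject_id Identifier for the emitted record.
#' @param listing_date Listing date for the emitted record.
#' @param covariates Optional list of covariate values.
#' @return A one-row registrant-record data frame.
#' @export
simulate_subject <- function(config, subject_id = "S1",
                             listing_date = config$listing_start,
                             covariates = NULL) {
  model <- config$intensities
  space <- model$space
  horizon <- if (is.null(config$admin_horizon_day)) Inf
             else config$admin_horizon_day
  state <- sample.int(length(config$initial_state_distribution), 1L,
                      prob = config$initial_state_distribution)
  state0 <- state
  cens <- if (!is.null(config$censoring_rate) && config$censoring_rate > 0) {
    stats::rexp(1, config$censoring_rate)
  } else Inf
  stop_day <- min(cens, horizon)
  t <- 0
  jump_days <- numeric(0); jump_states <- integer(0)
  terminal <- NA_integer_; terminal_day <- NA_real_
  from_rows <- split(seq_len(nrow(model$struct)), model$struct$from)
  repeat {
    rows <- from_rows[[as.character(state)]]
    total <- rowSums(model$rates[, rows, drop = FALSE])
    tnext <- piecewise_exit_time(t, model$breakpoints, total, stop_day)
    if (tnext >= stop_day) break
    piece <- findInterval(tnext, model$breakpoints)
    rt <- model$rates[piece, rows]
    dest <- model$struct$to[rows][sample.int(length(rows), 1L, prob = rt)]
    t <- tnext
    if (space$kind[dest] == "absorbing") {
      terminal <- dest; terminal_day <- t
      break
    }
    jump_days <- c(jump_days, t)
    jump_states <- c(jump_states, dest)
    state <- dest
  }
  if (config$day_resolution == "day") {
    jump_days <- ceiling(jump_days)
    if (!is.na(terminal_day)) terminal_day <- ceiling(terminal_day)
    stop_day <- ceiling(stop_day)
  }
  record_from_path(subject_id, space, start_state = state0,
                   jump_days = jump_days, jump_states = jump_states,
                   terminal = terminal, terminal_day = terminal_day,
                   censor_day = if (is.na(terminal)) min(stop_day, horizon)
                                else NA_real_,
                   listing_date = listing_date, covariates = covariates)
}

#' Simulate a seeded waitlist cohort
#'
#' Draws `n_subjects` independent trajectories from one seeded RNG stream in
#' documented order (per subject: listing date, covariates, initial state,
#' censoring draw, then alternating holding-time and destination draws).
#' Identical configuration and seed give identical cohorts.
#'
#' @param config A [scenario_config()].
#' @return A registrant-record data frame with one row per subject.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "msm_scenario"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  span <- as.numeric(config$listing_end - config$listing_start)
  races <- c("White", "Black", "Hispanic", "Asian", "Other")
  abos <- c("O", "A", "B", "AB")
  esrds <- c("Diabetes", "Glomerulonephritis", "Graft Failure",
             "Hypertension", "Other")
  recs <- vector("list", config$n_subjects)
  for (m in seq_len(config$n_subjects)) {
    ld <- config$listing_start + floor(stats::runif(1, 0, span + 1))
    age <- floor(stats::runif(1, 19, 80))
    cov <- list(
      age_at_listing = age,
      age_group = if (age < 40) "18-39" else if (age < 65) "40-64" else ">=65",
      gender = sample(c("Male", "Female"), 1, prob = c(0.61, 0.39)),
      abo = sample(abos, 1, prob = c(0.48, 0.34, 0.14, 0.04)),
      race = sample(races, 1, prob = c(0.44, 0.29, 0.18, 0.065, 0.025)),
      esrd_diagnosis = sample(esrds, 1,
                              prob = c(0.36, 0.11, 0.02, 0.23, 0.28)))
    recs[[m]] <- simulate_subject(config,
                                  subject_id = sprintf("S%05d", m),
                                  listing_date = ld, covariates = cov)
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Analytic transition probabilities of the simulator
#'
#' Exact P(s, t) of the piecewise-constant Markov process: the product over
#' pieces overlapping (s, t] of the matrix exponential of (piece duration x
#' piece generator). Serves as the independent oracle for the
#' Aalen-Johansen estimator.
#'
#' @param model A [intensity_model()].
#' @param s,t Interval endpoints in days, `s <= t`.
#' @return A states x states probability matrix.
#' @export
true_transition_probability <- function(model, s, t) {
  stopifnot(s <= t)
  ns <- nrow(model$space)
  P <- diag(ns)
  if (t == s) return(P)
  bp <- model$breakpoints
  np <- length(bp)
  for (piece in seq_len(np)) {
    a <- max(s, bp[piece])
    b <- if (piece < np) min(t, bp[piece + 1]) else t
    if (b <= a) next
    Q <- piece_generator(model, piece)
    P <- P %*% as.matrix(Matrix::expm(Q * (b - a)))
  }
  dimnames(P) <- NULL
  P
}
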