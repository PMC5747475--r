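# Shared fixtures: validation scenarios and small hand-built datasets.
# All scenario rates were fixed by design (see the methods vignette) and are
# study conditions, not tuning knobs.

the_space <- build_state_space()
the_struct <- build_transition_structure(the_space)

# low-rate homogeneous generator for estimator recovery: total exit
# probability by day 365 is ~1.2%, so the Monte-Carlo error budget of the
# sup-norm comparison at n = 5000 split over 12 origins stays well inside
# the tolerance (power reasoning in the methods vignette)
recovery_intensity <- function() {
  rates <- transition_rates(
    the_space, the_struct,
    activation = 1.1e-5, inactivation = 1.1e-5,
    cpra_up = 4e-6, cpra_down = 4e-6,
    death_active = 4e-6, death_inactive = 8e-6,
    deceased_donor = 5e-6, living_donor = 2e-6, removal = 2e-6)
  intensity_model(the_struct, rates)
}

# moderate-rate homogeneous generator for interval-coverage checks:
# roughly 8-25 expected events per (origin, outcome) cell at n = 1000
coverage_intensity <- function(deceased_donor = 8e-4) {
  rates <- transition_rates(
    the_space, the_struct,
    activation = 1.5e-3, inactivation = 1.5e-3,
    cpra_up = 3e-4, cpra_down = 3e-4,
    death_active = 6e-4, death_inactive = 1.2e-3,
    deceased_donor = deceased_donor, living_donor = 4e-4, removal = 4e-4)
  intensity_model(the_struct, rates)
}

uniform_scenario <- function(n, seed, intensities, horizon = 400, ...) {
  scenario_config(n, seed = seed,
                  initial_state_distribution = rep(1 / 12, 12),
                  intensities = intensities,
                  admin_horizon_day = horizon, ...)
}

# four subjects, events at days 10 and 20 only:
#   day 10: one of three subjects in state 1 moves to state 2
#   day 20: one of two remaining in state 1 is transplanted (deceased donor);
#           one of two in state 2 dies
hand_built_table <- function() {
  lk <- transition_lookup(the_struct)
  row <- function(id, from, to, t0, t1, st) {
    data.frame(subject_id = id, from_index = from, to_index = to,
               transition_id = lk[from, to], t_start = t0, t_stop = t1,
               status = st)
  }
  tab <- rbind(
    row("A", 1L, 2L, 0, 10, 1L),     # 1 -> 2 at day 10
    row("A", 2L, 15L, 10, 30, 0L),   # then censored in state 2
    row("B", 1L, 13L, 0, 20, 1L),    # 1 -> deceased-donor tx at day 20
    row("C", 1L, 2L, 0, 30, 0L),     # stays in state 1, censored
    row("D", 2L, 15L, 0, 20, 1L))    # 2 -> death at day 20
  attr(tab, "space") <- the_space
  attr(tab, "struct") <- the_struct
  class(tab) <- c("msm_transition_table", "data.frame")
  tab
}

# two-state reduction: one transient state (1), one absorbing (15 = death);
# observed times and death indicators give the classical KM setting
two_state_table <- function(time, death) {
  lk <- transition_lookup(the_struct)
  tab <- data.frame(subject_id = sprintf("s%03d", seq_along(time)),
                    from_index = 1L, to_index = 15L,
                    transition_id = lk[1L, 15L],
                    t_start = 0, t_stop = time, status = as.integer(death))
  attr(tab, "space") <- the_space
  attr(tab, "struct") <- the_struct
  class(tab) <- c("msm_transition_table", "data.frame")
  tab
}

published_demographics <- function() {
  utils::read.delim(system.file("extdata",
                                "waitlist_demographics_published.tsv",
                                package = "waitlistMSM"),
                    stringsAsFactors = FALSE)
}

make_record <- function(subject_id = "r1", listing_date = "2015-01-01",
                        age = 50, first_time = TRUE, multi_organ = FALSE,
                        initial_cpra = 0, initial_status = "active",
                        updates = "", terminal_day = NA_real_,
                        terminal_state = NA_character_,
                        censor_day = NA_real_) {
  data.frame(subject_id = subject_id,
             listing_date = as.Date(listing_date),
             age_at_listing = age, first_time = first_time,
             multi_organ = multi_organ, age_group = "40-64",
             gender = "Male", abo = "O", race = "White",
             esrd_diagnosis = "Other", initial_cpra = initial_cpra,
             initial_status = initial_status, updates = updates,
             terminal_day = terminal_day, terminal_state = terminal_state,
             censor_day = censor_day, stringsAsFactors = FALSE)
}
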