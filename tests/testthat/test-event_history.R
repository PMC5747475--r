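test_that("cohort filters retain adults, first-time, kidney-only in window", {
  recs <- rbind(
    make_record("ok", "2015-03-01", age = 45, censor_day = 365),
    make_record("age18", "2015-03-01", age = 18, censor_day = 365),
    make_record("multi", "2015-03-01", multi_organ = TRUE, censor_day = 365),
    make_record("repeat", "2015-03-01", first_time = FALSE, censor_day = 365),
    make_record("early", "2014-01-01", censor_day = 365))
  out <- suppressMessages(
    filter_cohort(recs, "2015-01-01", "2015-12-31"))
  expect_equal(out$subject_id, "ok")
  excl <- attr(out, "exclusions")
  expect_equal(unname(excl["age_18_or_younger"]), 1)
  expect_equal(unname(excl["multi_organ"]), 1)
  expect_equal(unname(excl["repeat_registration"]), 1)
  expect_equal(unname(excl["outside_window"]), 1)
})

test_that("trajectories follow the construction rules", {
  # no updates, censored at one year: a single censored interval
  tr <- trajectory_from_record(make_record(censor_day = 365), the_space)
  expect_equal(tr, data.frame(state = 1L, start = 0, end = 365,
                              end_state = NA_integer_))

  # CPRA 85 active -> inactive at day 30 -> death at day 90
  tr <- trajectory_from_record(
    make_record(initial_cpra = 85, updates = "30::inactive",
                terminal_day = 90, terminal_state = "death_or_deteriorated"),
    the_space)
  expect_equal(tr$state, c(5L, 6L))          # CPRA 80-89 active, then inactive
  expect_equal(tr$start, c(0, 30))
  expect_equal(tr$end, c(30, 90))
  expect_equal(tr$end_state, c(6L, 15L))

  # CPRA update 5 -> 40 at day 50: same category, no interval boundary
  tr <- trajectory_from_record(
    make_record(initial_cpra = 5, updates = "50:40:", censor_day = 100),
    the_space)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$end, 100)

  # same-day CPRA and status change merge into one combined transition
  tr <- trajectory_from_record(
    make_record(initial_cpra = 0, updates = "20:96:;20::inactive",
                censor_day = 50), the_space)
  expect_equal(tr$state, c(1L, 10L))  # 95-98% inactive
  expect_equal(tr$end_state[1], 10L)

  # terminal on day 0 is shifted by half a day
  expect_warning(
    tr <- trajectory_from_record(
      make_record(terminal_day = 0, terminal_state = "living_donor_transplant"),
      the_space),
    "half a day")
  expect_equal(tr$end, 0.5)
  expect_equal(tr$end_state, 14L)

  # update after the terminal day is malformed
  expect_error(
    trajectory_from_record(
      make_record(updates = "40::inactive", terminal_day = 30,
                  terminal_state = "removed_other"), the_space),
    "after terminal")
})

test_that("policy censoring truncates and lifting retains late events", {
  rec <- make_record(listing_date = "2014-01-01", terminal_day = 500,
                     terminal_state = "death_or_deteriorated")
  tr <- trajectory_from_record(rec, the_space)
  # policy boundary at day 500 - 100 = 400 for this listing date
  sch <- censoring_scheme(policy_date = as.Date("2014-01-01") + 400,
                          censor_at_policy = TRUE)
  cut <- apply_censoring(tr, rec, sch)
  expect_equal(cut$end, 400)
  expect_true(is.na(cut$end_state))
  # idempotent
  expect_equal(apply_censoring(cut, rec, sch), cut)
  # lifted: policy date ignored, administrative horizon applies
  lifted <- censoring_scheme(censor_at_policy = FALSE,
                             admin_horizon_day = 1095)
  expect_equal(apply_censoring(tr, rec, lifted), tr)
  # trajectory entirely before the boundary is unchanged
  early <- trajectory_from_record(make_record(censor_day = 100), the_space)
  expect_equal(apply_censoring(early, rec, sch), early)
  # policy before listing: the subject contributes nothing
  pre <- censoring_scheme(policy_date = as.Date("2013-06-01"),
                          censor_at_policy = TRUE)
  expect_equal(nrow(apply_censoring(tr, rec, pre)), 0L)
})

test_that("transition-table expansion emits one row per allowed transition", {
  # active CPRA-0 subject dying at day 100: 15 rows, one event
  recs <- make_record(terminal_day = 100,
                      terminal_state = "death_or_deteriorated")
  tab <- prepare_transition_table(recs, the_space, the_struct)
  expect_equal(nrow(tab), 15L)
  expect_true(all(tab$t_start == 0 & tab$t_stop == 100))
  expect_equal(sum(tab$status), 1L)
  expect_equal(tab$to_index[tab$status == 1], 15L)

  # inactive interval: 14 rows, none to deceased-donor transplant
  recs <- make_record(initial_status = "inactive", censor_day = 50)
  tab <- prepare_transition_table(recs, the_space, the_struct)
  expect_equal(nrow(tab), 14L)
  expect_false(13L %in% tab$to_index)
  expect_true(all(tab$status == 0L))  # censored-only subject

  # every row's (from, to) pair is in the structure and t_start < t_stop
  recs <- rbind(
    make_record("a", updates = "10:85:;60::inactive", censor_day = 400),
    make_record("b", initial_status = "inactive", terminal_day = 200,
                terminal_state = "deceased_donor_transplant",
                updates = "100::active"))
  tab <- prepare_transition_table(recs, the_space, the_struct)
  lk <- transition_lookup(the_struct)
  expect_false(anyNA(lk[cbind(tab$from_index, tab$to_index)]))
  expect_true(all(tab$t_start < tab$t_stop))
  # within each (subject, interval) block at most one realized transition
  blocks <- split(tab$status, paste(tab$subject_id, tab$t_start))
  expect_true(all(vapply(blocks, sum, 0) <= 1))
})

test_that("simulated cohorts round-trip through the event-history layer", {
  scen <- scenario_registry_like(n_subjects = 300, seed = 42)
  cohort <- simulate_cohort(scen)
  tab <- prepare_transition_table(cohort, the_space, the_struct)
  # realized event counts in the table equal the simulator's moves
  n_updates <- vapply(strsplit(cohort$updates, ";"), function(u)
    sum(nzchar(u)), 0L)
  n_terminal <- sum(!is.na(cohort$terminal_day))
  expect_equal(sum(tab$status), sum(n_updates) + n_terminal)
  # per-subject time at risk equals occupancy: total follow-up conserved
  iv <- tab[!duplicated(paste(tab$subject_id, tab$from_index, tab$t_start)), ]
  followup <- ifelse(is.na(cohort$terminal_day), cohort$censor_day,
                     cohort$terminal_day)
  risk <- tapply(iv$t_stop - iv$t_start, iv$subject_id, sum)
  expect_equal(as.numeric(risk[cohort$subject_id]), as.numeric(followup),
               tolerance = 1e-12)
})

test_that("registrant records round-trip through their file format", {
  scen <- scenario_registry_like(n_subjects = 40, seed = 9)
  cohort <- simulate_cohort(scen)
  withr::with_tempdir({
    write_registrants(cohort, "regs.tsv")
    back <- read_registrants("regs.tsv")
    expect_equal(back$subject_id, cohort$subject_id)
    expect_equal(back$updates, cohort$updates)
    expect_equal(back$initial_cpra, cohort$initial_cpra)
    expect_equal(back$terminal_day, cohort$terminal_day)
    tab1 <- prepare_transition_table(cohort, the_space, the_struct)
    tab2 <- prepare_transition_table(back, the_space, the_struct)
    expect_equal(tab1$t_stop, tab2$t_stop, tolerance = 1e-10)
  })
})
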