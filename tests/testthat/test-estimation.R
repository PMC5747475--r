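test_that("risk sets and event counts follow the counting-process rules", {
  # 3 subjects in state 1 over [0, 100), one 1->2 event at day 50
  lk <- transition_lookup(the_struct)
  tab <- rbind(
    data.frame(subject_id = "a", from_index = 1L, to_index = 2L,
               transition_id = lk[1, 2], t_start = 0, t_stop = 50,
               status = 1L),
    data.frame(subject_id = c("b", "c"), from_index = 1L, to_index = 2L,
               transition_id = lk[1, 2], t_start = 0, t_stop = 100,
               status = 0L))
  prof <- count_risk_and_events(tab, the_space, the_struct)
  expect_equal(prof$times, 50)
  expect_equal(unname(prof$Y[1, 1]), 3)
  expect_equal(unname(prof$dN[lk[1, 2], 1]), 1)

  # empty table gives an empty profile
  prof0 <- count_risk_and_events(tab[0, ], the_space, the_struct)
  expect_length(prof0$times, 0)

  # two simultaneous events from the same state share one event time
  tab2 <- rbind(
    data.frame(subject_id = c("a", "b"), from_index = 1L, to_index = 2L,
               transition_id = lk[1, 2], t_start = 0, t_stop = 30,
               status = 1L),
    data.frame(subject_id = c("c", "d"), from_index = 1L, to_index = 2L,
               transition_id = lk[1, 2], t_start = 0, t_stop = 60,
               status = 0L))
  prof2 <- count_risk_and_events(tab2, the_space, the_struct)
  expect_equal(prof2$times, 30)
  expect_equal(unname(prof2$dN[lk[1, 2], 1]), 2)
  expect_equal(unname(prof2$Y[1, 1]), 4)
})

test_that("Nelson-Aalen jumps are dN/Y with Greenwood-type variance", {
  lk <- transition_lookup(the_struct)
  # one event among 4 at risk: a single jump of 1/4
  tab <- two_state_table(time = c(10, 20, 20, 20), death = c(1, 0, 0, 0))
  haz <- nelson_aalen(count_risk_and_events(tab))
  id <- lk[1, 15]
  expect_equal(unname(haz$A[id, ncol(haz$A)]), 0.25)
  expect_equal(unname(haz$var_dA[id, 1]), 1 * (4 - 1) / 4^3)

  # no events: hazards identically zero
  tab0 <- two_state_table(time = c(5, 8), death = c(0, 0))
  haz0 <- nelson_aalen(count_risk_and_events(tab0))
  expect_true(all(haz0$A == 0))

  # shrinking risk sets 5 then 4: cumulative hazard 1/5 + 1/4
  tab2 <- two_state_table(time = c(3, 7, 9, 9, 9), death = c(1, 1, 0, 0, 0))
  haz2 <- nelson_aalen(count_risk_and_events(tab2))
  expect_equal(unname(haz2$A[id, 2]), 1 / 5 + 1 / 4)
  # Poisson-type flag for sensitivity checks
  hp <- nelson_aalen(count_risk_and_events(tab2), variance = "poisson")
  expect_equal(unname(hp$var_dA[id, 1]), 1 / 25)
  # hazards are non-decreasing, start at zero, jump only at event times
  expect_true(all(diff(haz2$A[id, ]) >= 0))
  df <- as.data.frame(haz2)
  expect_equal(df$time, c(3, 7))
})

test_that("Aalen-Johansen equals the brute-force product of (I + dA)", {
  tab <- hand_built_table()
  fit <- waitlist_msm(tab)
  traj <- predict(fit, t = 30, type = "trajectory")
  # independent brute force from the raw counts: factors at days 10 and 20
  F10 <- diag(16); F10[1, 2] <- 1 / 3; F10[1, 1] <- 1 - 1 / 3
  F20 <- diag(16)
  F20[1, 13] <- 1 / 2; F20[1, 1] <- 1 - 1 / 2
  F20[2, 15] <- 1 / 2; F20[2, 2] <- 1 - 1 / 2
  expected <- F10 %*% F20
  expect_equal(transition_matrix(traj, 30), expected, tolerance = 1e-14)
  # no events in (s, t]: identity
  expect_equal(transition_matrix(traj, 5), diag(16))
  # P(s, s) = identity and rows sum to one throughout
  expect_equal(traj$P[, , 1], diag(16))
  for (k in seq_along(traj$times)) {
    expect_equal(rowSums(traj$P[, , k]), rep(1, 16), tolerance = 1e-12)
  }
  # absorbing rows are unit vectors on themselves
  expect_equal(traj$P[13:16, , dim(traj$P)[3]], diag(16)[13:16, ])
})

test_that("two-state reduction reproduces Kaplan-Meier and Greenwood", {
  skip_if_not_installed("survival")
  time <- c(2, 3, 4, 5, 5)
  death <- c(1, 0, 1, 0, 0)
  tab <- two_state_table(time, death)
  fit <- waitlist_msm(tab)
  traj <- predict(fit, t = 5, type = "trajectory")
  k <- length(traj$times)
  # closed-form product-limit and Greenwood oracle, computed by hand:
  # deaths at t=2 (Y=5) and t=4 (Y=3)
  S <- (1 - 1 / 5) * (1 - 1 / 3)
  gw <- S^2 * (1 / (5 * 4) + 1 / (3 * 2))
  expect_equal(traj$P[1, 1, k], S, tolerance = 1e-14)
  expect_equal(traj$var[1, 1, k], gw, tolerance = 1e-14)
  # cross-check against the survival package
  sf <- survival::survfit(survival::Surv(time, death) ~ 1)
  sm <- summary(sf, times = 4)
  expect_equal(traj$P[1, 1, k], sm$surv, tolerance = 1e-12)
  expect_equal(sqrt(traj$var[1, 1, k]), sm$std.err, tolerance = 1e-12)
  # variance is non-negative on the whole grid
  expect_true(all(traj$var >= 0))
  # no events: zero variance everywhere
  traj0 <- predict(waitlist_msm(two_state_table(c(5, 8), c(0, 0))),
                   t = 8, type = "trajectory")
  expect_true(all(traj0$var == 0))
})

test_that("competing-risks reduction matches the standard CIF estimator", {
  skip_if_not_installed("cmprsk")
  set.seed(31)
  n <- 60
  ft <- rexp(n, 0.04)
  cause <- sample(c(15L, 13L, 14L), n, replace = TRUE,
                  prob = c(0.5, 0.3, 0.2))
  cens <- runif(n, 0, 40)
  obs <- pmin(ft, cens)
  status <- ifelse(ft <= cens, cause, 0L)
  lk <- transition_lookup(the_struct)
  rows <- lapply(c(13L, 14L, 15L, 16L), function(to)
    data.frame(subject_id = sprintf("s%02d", 1:n), from_index = 1L,
               to_index = to, transition_id = lk[1, to], t_start = 0,
               t_stop = obs, status = as.integer(status == to)))
  tab <- do.call(rbind, rows)
  attr(tab, "space") <- the_space; attr(tab, "struct") <- the_struct
  class(tab) <- c("msm_transition_table", "data.frame")
  fit <- waitlist_msm(tab)
  traj <- predict(fit, t = 30, type = "trajectory", variance = FALSE)
  ci <- cmprsk::cuminc(obs, status, cencode = 0)
  for (grp in names(ci)[names(ci) != "Tests"]) {
    cause_k <- as.integer(sub("^1 ", "", grp))
    est <- cmprsk::timepoints(ci[grp], times = 30)$est[1, 1]
    expect_equal(transition_matrix(traj, 30)[1, cause_k], est,
                 tolerance = 1e-10)
  }
})

test_that("Chapman-Kolmogorov holds exactly for the product-integral form", {
  tab <- hand_built_table()
  fit <- waitlist_msm(tab)
  P_0_30 <- transition_matrix(predict(fit, t = 30, type = "trajectory"), 30)
  t15 <- predict(fit, s = 15, t = 30, type = "trajectory", variance = FALSE)
  P_0_15 <- transition_matrix(predict(fit, t = 15, type = "trajectory"), 15)
  expect_equal(P_0_15 %*% transition_matrix(t15, 30), P_0_30,
               tolerance = 1e-14)
})

test_that("confidence bands truncate, collapse at zero variance, and widen", {
  tab <- two_state_table(c(2, 3, 4, 5, 5), c(1, 0, 1, 0, 0))
  fit <- waitlist_msm(tab)
  traj <- aalen_johansen(fit$hazards, 0, report_times = 5)
  b90 <- confidence_interval(traj, 0.90)
  b99 <- confidence_interval(traj, 0.99)
  expect_true(all(b90$lower >= 0 & b90$upper <= 1))
  # width is monotone in the level
  expect_true(all(b99$upper - b99$lower >= b90$upper - b90$lower - 1e-14))
  # zero variance: bands equal the point estimate
  zero <- b90$var == 0
  expect_equal(b90$lower[zero], b90$P[zero])
  expect_equal(b90$upper[zero], b90$P[zero])
  # truncation at 1: estimate 0.9 with se 0.1 at level 0.95
  expect_equal(min(0.9 + qnorm(0.975) * 0.1, 1), 1)
  hi <- confidence_interval(traj, 0.9999)
  expect_true(all(hi$upper <= 1))
  # log-transformed bands are available and respect [0, 1]
  lg <- confidence_interval(traj, 0.95, method = "log")
  expect_true(all(lg$lower >= 0 & lg$upper <= 1))
  expect_true(all(lg$lower <= lg$P + 1e-14 & lg$upper >= lg$P - 1e-14))
  expect_error(confidence_interval(traj, 1.2), "level")
})

test_that("greenwood_variance fills variances for a variance-free trajectory", {
  tab <- two_state_table(c(2, 3, 4, 5, 5), c(1, 0, 1, 0, 0))
  fit <- waitlist_msm(tab)
  bare <- aalen_johansen(fit$hazards, 0, report_times = 5, variance = FALSE)
  expect_true(all(bare$var == 0))
  filled <- greenwood_variance(fit$hazards, bare)
  full <- aalen_johansen(fit$hazards, 0, report_times = 5, variance = TRUE)
  expect_equal(filled$var, full$var, tolerance = 1e-14)
})

test_that("martingale residuals sum to zero within every transition", {
  scen <- scenario_registry_like(n_subjects = 150, seed = 5)
  fit <- waitlist_msm(simulate_cohort(scen))
  res <- residuals(fit)
  expect_equal(max(abs(colSums(res))), 0, tolerance = 1e-9)
  expect_equal(nrow(res), fit$n_subjects)
})

test_that("an origin beyond follow-up warns and returns identities", {
  tab <- two_state_table(c(2, 3), c(1, 0))
  fit <- waitlist_msm(tab)
  expect_warning(traj <- aalen_johansen(fit$hazards, s = 10), "identity")
  expect_equal(traj$P[, , dim(traj$P)[3]], diag(16))
})
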