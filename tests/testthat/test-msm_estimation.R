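canonical_struct <- transition_structure(canonical_state_space())

test_that("competing-risks expansion enumerates sojourns x allowed exits", {
  B0 <- as.Date("2005-01-01")
  iv <- data.frame(
    person_id = c(1, 1, 1, 2, 3, 3),
    state = c("work", "unemployment", "work",
              "work",
              "work", "disability_retirement"),
    start_date = B0 + c(0, 59, 105, 0, 0, 200),
    end_date = B0 + c(58, 104, 364, 364, 199, 364),
    stringsAsFactors = FALSE)
  fu <- data.frame(person_id = 1:3, entry_date = B0,
                   censor_date = B0 + 364,
                   censor_reason = "study_end", stringsAsFactors = FALSE)
  persons <- data.frame(person_id = 1:3, entry_age = c(55, 60, 57))
  rec <- to_transition_records(list(intervals = iv, followup = fu),
                               persons, canonical_struct)

  # person 2: in work the whole follow-up -> 6 records, all censored
  r2 <- rec[rec$person_id == 2, ]
  expect_equal(nrow(r2), 6L)
  expect_true(all(r2$status == 0L))
  expect_true(all(r2$from == "work"))
  expect_equal(r2$entry_age, rep(60, 6))
  expect_equal(r2$exit_age, rep(60 + 365 / 365.25, 6))

  # person 3: disability retirement sojourn -> exactly 2 records
  r3 <- rec[rec$person_id == 3 & rec$from == "disability_retirement", ]
  expect_equal(nrow(r3), 2L)
  expect_setequal(r3$to, c("retirement", "death"))
  expect_true(all(r3$status == 0L))

  # person 1: 3 sojourns x 6 exits, with the observed transitions flagged
  r1 <- rec[rec$person_id == 1, ]
  expect_equal(nrow(r1), 18L)
  expect_equal(sum(r1$status), 2L)
  expect_equal(r1$to[r1$status == 1L], c("unemployment", "work"))
  expect_equal(unique(r1$entry_age[r1$from == "unemployment"]),
               55 + 59 / 365.25)
  expect_equal(unique(r1$exit_age[r1$from == "unemployment"]),
               55 + 105 / 365.25)
  # total: 18 + 6 + (6 work + 2 disability retirement) = 32
  expect_equal(nrow(rec), 32L)
})

test_that("a disallowed observed transition is a data error", {
  B0 <- as.Date("2005-01-01")
  iv <- data.frame(person_id = c(1, 1),
                   state = c("retirement", "work"),
                   start_date = B0 + c(0, 100),
                   end_date = B0 + c(99, 364), stringsAsFactors = FALSE)
  fu <- data.frame(person_id = 1, entry_date = B0, censor_date = B0 + 364,
                   censor_reason = "study_end", stringsAsFactors = FALSE)
  expect_error(
    to_transition_records(list(intervals = iv, followup = fu),
                          data.frame(person_id = 1, entry_age = 55),
                          canonical_struct),
    "disallowed transition")
})

test_that("Cox beta matches brute-force partial-likelihood maximization", {
  entry <- c(50, 50, 50.5, 51, 51, 52, 52.5, 53, 50.2, 54)
  exit <- c(51, 52.5, 53, 54, 52, 55.5, 56, 57, 58, 60)
  status <- c(1L, 0L, 1L, 1L, 0L, 1L, 0L, 1L, 1L, 0L)
  x <- matrix(c(1, 0, 1, 0, 1, 1, 0, 0, 1, 0), ncol = 1,
              dimnames = list(NULL, "z"))
  fit <- fit_transition_cox(entry, exit, status, x)
  oracle <- stats::optimize(
    function(b) cox_loglik_oracle(b, entry, exit, status, x),
    interval = c(-5, 5), maximum = TRUE, tol = 1e-10)
  expect_equal(unname(fit$beta), oracle$maximum, tolerance = 1e-6)

  # identical covariates carry no information: beta is exactly 0
  x0 <- matrix(1, length(entry), 1, dimnames = list(NULL, "z"))
  fit0 <- fit_transition_cox(entry, exit, status, x0)
  expect_identical(unname(fit0$beta), 0)

  # zero events: beta 0 and a null baseline, with a message
  expect_message(
    fitz <- fit_transition_cox(entry, exit, rep(0L, 10), x),
    "no events")
  expect_equal(unname(fitz$beta), 0)
  expect_length(fitz$baseline$ages, 0L)
})

test_that("Breslow baseline reproduces Nelson-Aalen when beta is zero", {
  entry <- c(50, 50, 51, 51, 52)
  exit <- c(53, 54, 54, 55, 56)
  status <- c(1L, 1L, 1L, 0L, 1L)
  fit <- fit_transition_cox(entry, exit, status,
                            matrix(numeric(0), 5, 0))
  sf <- survival::survfit(survival::Surv(entry, exit, status) ~ 1)
  na_inc <- diff(c(0, sf$cumhaz[sf$n.event > 0]))
  expect_equal(fit$baseline$ages, sf$time[sf$n.event > 0])
  expect_equal(fit$baseline$dA, na_inc, tolerance = 1e-12)
})

test_that("fitted hazard ratio recovers the simulated truth", {
  sp <- state_space(c("work", "death"), absorbing = "death")
  st <- transition_structure(sp)
  cfg <- sim_config(n_persons = 40000, seed = 61, space = sp,
                    structure = st, age_breaks = c(50, 63),
                    intensities = matrix(0.08, 1, 1),
                    effects = matrix(log(2), 1, 1,
                                     dimnames = list(NULL, "class_manual")),
                    entry_age_range = c(50, 56),
                    study_end_date = "2018-12-31",
                    class_probs = c(manual = 0.5, upper_non_manual = 0.5))
  sim <- simulate_register(cfg, render_episodes = FALSE)
  rec <- to_transition_records(
    list(intervals = sim$trajectories, followup = sim$followup),
    sim$persons, st)
  fit <- fit_multistate(rec, sim$persons, st, "class_manual")
  b <- fit$fits[[1]]$beta[["class_manual"]]
  se <- fit$fits[[1]]$se[["class_manual"]]
  expect_lt(abs(b - log(2)), 3 * se)

  # adjusted cumulative hazard vs subgroup Nelson-Aalen oracle
  adj <- adjusted_cumhaz(fit$fits[[1]],
                         c(class_manual = 1))
  man <- rec$person_id %in%
    sim$persons$person_id[sim$persons$occupational_class == "manual"]
  sf <- survival::survfit(
    survival::Surv(rec$entry_age[man], rec$exit_age[man],
                   rec$status[man]) ~ 1)
  at <- c(53, 56, 59)
  A_adj <- vapply(at, function(t) sum(adj$dA[adj$ages <= t]), 0)
  A_na <- vapply(at, function(t) max(c(0, sf$cumhaz[sf$time <= t])), 0)
  expect_equal(A_adj, A_na, tolerance = 0.05)

  # reference profile leaves the baseline untouched; log-2 profile doubles it
  ref <- adjusted_cumhaz(fit$fits[[1]], c(class_manual = 0))
  expect_identical(ref$dA, fit$fits[[1]]$baseline$dA)
  expect_equal(adj$dA, ref$dA * exp(b), tolerance = 1e-12)
  expect_error(adjusted_cumhaz(fit$fits[[1]], c(wrong = 1)),
               "profile")
})

test_that("product integral with no events is the identity", {
  fit <- fake_fit(canonical_struct,
                  vector("list", canonical_struct$n_transitions))
  aj <- aalen_johansen(fit)
  expect_equal(transition_probability(aj), diag(7), ignore_attr = TRUE)
  e <- elos(aj)
  expect_equal(unname(e[["work"]]), 13)
  expect_equal(sum(e), 13)
})

test_that("oversized increments are capped so rows stay probabilities", {
  bl <- vector("list", canonical_struct$n_transitions)
  bl[[6]] <- list(ages = 55, dA = 1.5)  # work -> death jump > 1
  fit <- fake_fit(canonical_struct, bl)
  expect_message(aj <- aalen_johansen(fit), "capped")
  P <- transition_probability(aj)
  expect_true(all(P >= 0))
  expect_equal(unname(rowSums(P)), rep(1, 7), tolerance = 1e-12)
  expect_equal(P["work", "death"], 1)
})

test_that("two-state estimator approaches the exponential closed form", {
  sp <- state_space(c("work", "death"), absorbing = "death")
  st <- transition_structure(sp)
  cfg <- sim_config(n_persons = 30000, seed = 71, space = sp,
                    structure = st, age_breaks = c(50, 63),
                    intensities = matrix(0.1, 1, 1),
                    effects = matrix(0, 1, 0),
                    entry_age_range = c(50, 50),
                    study_end_date = "2018-12-31")
  sim <- simulate_register(cfg, render_episodes = FALSE)
  rec <- to_transition_records(
    list(intervals = sim$trajectories, followup = sim$followup),
    sim$persons, st)
  fit <- fit_multistate(rec, sim$persons, st)
  aj <- aalen_johansen(fit)
  for (t in c(53, 56, 60)) {
    p <- transition_probability(aj, t)["work", "work"]
    truth <- exp(-0.1 * (t - 50))
    expect_lt(abs(p - truth), 3 * sqrt(truth * (1 - truth) / 30000) + 1e-3)
  }
})

test_that("illness-death probabilities match the Kolmogorov solution", {
  rates <- c(0.15, 0.05, 0.40, 0.10)
  cfg <- illness_death_config(20000, seed = 81, rates = rates)
  sim <- simulate_register(cfg, render_episodes = FALSE)
  st <- cfg$structure
  rec <- to_transition_records(
    list(intervals = sim$trajectories, followup = sim$followup),
    sim$persons, st)
  fit <- fit_multistate(rec, sim$persons, st)
  aj <- aalen_johansen(fit)
  states <- st$space$states
  Q <- matrix(0, 3, 3, dimnames = list(states, states))
  for (k in seq_len(st$n_transitions)) {
    Q[st$transitions$from[k], st$transitions$to[k]] <- rates[k]
  }
  diag(Q) <- -rowSums(Q)
  for (t in c(54, 58)) {
    P_hat <- transition_probability(aj, t)["work", ]
    P_true <- expm_P(Q, t - 50)["work", ]
    tol <- 3 * sqrt(pmax(P_true * (1 - P_true), 1e-4) / 20000) + 2e-3
    expect_true(all(abs(P_hat - P_true) < tol))
  }
})

test_that("nonparametric estimate equals an independent simple implementation", {
  sim <- simulate_register(sim_config(n_persons = 15, seed = 91,
                                      study_end_date = "2018-12-31"),
                           render_episodes = FALSE)
  st <- sim$config$structure
  rec <- to_transition_records(
    list(intervals = sim$trajectories, followup = sim$followup),
    sim$persons, st)
  fit <- suppressMessages(fit_multistate(rec, sim$persons, st))
  aj <- suppressMessages(aalen_johansen(fit, s = 50, horizon = 63))
  P_pkg <- transition_probability(aj)
  P_naive <- naive_aj(records_to_sojourns(rec), st$space$states, 50, 63)
  expect_equal(P_pkg, P_naive, tolerance = 1e-12)
})

test_that("Chapman-Kolmogorov holds on the estimator grid", {
  sim <- simulate_register(sim_config(n_persons = 120, seed = 101),
                           render_episodes = FALSE)
  st <- sim$config$structure
  rec <- to_transition_records(
    list(intervals = sim$trajectories, followup = sim$followup),
    sim$persons, st)
  fit <- suppressMessages(fit_multistate(rec, sim$persons, st))
  aj <- suppressMessages(aalen_johansen(fit))
  u <- aj$ages[floor(length(aj$ages) / 2)]
  aj_u <- suppressMessages(aalen_johansen(fit, s = u, horizon = 63))
  lhs <- transition_probability(aj, u) %*% transition_probability(aj_u)
  expect_equal(lhs, transition_probability(aj), tolerance = 1e-12)
  # row-stochasticity along the whole grid
  sums <- apply(aj$P, 3, rowSums)
  expect_true(all(abs(sums - 1) < 1e-10))
  expect_true(all(aj$P >= -1e-12 & aj$P <= 1 + 1e-12))
})
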