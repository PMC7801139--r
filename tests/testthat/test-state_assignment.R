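ep_row <- function(pid, type, from, to) {
  data.frame(person_id = pid, episode_type = type,
             start_date = as.Date(from), end_date = as.Date(to),
             stringsAsFactors = FALSE)
}
fixture_person <- function(pid, entry_age = 55) {
  data.frame(person_id = pid, entry_age = entry_age)
}
B0 <- as.Date("2005-01-01")
E0 <- as.Date("2005-12-31")

test_that("stated override rules resolve concurrent episodes", {
  # unemployment overrules earnings
  tr <- assign_daily_states(
    rbind(ep_row(1, "earnings", "2005-01-01", "2005-12-31"),
          ep_row(1, "unemployment_benefit", "2005-03-01", "2005-04-15")),
    fixture_person(1), B0, E0)
  expect_equal(tr$intervals$state,
               c("work", "unemployment", "work"))
  expect_equal(tr$intervals$start_date,
               as.Date(c("2005-01-01", "2005-03-01", "2005-04-16")))
  expect_equal(tr$intervals$end_date,
               as.Date(c("2005-02-28", "2005-04-15", "2005-12-31")))

  # part-time sickness allowance counts as work (with or without earnings)
  tr2 <- assign_daily_states(
    rbind(ep_row(2, "earnings", "2005-01-01", "2005-06-30"),
          ep_row(2, "sickness_allowance_parttime", "2005-03-01", "2005-03-31")),
    fixture_person(2), B0, E0)
  expect_equal(tr2$intervals$state[1], "work")
  expect_equal(tr2$intervals$start_date[1], as.Date("2005-01-01"))
  expect_equal(tr2$intervals$end_date[1], as.Date("2005-06-30"))
  tr2b <- assign_daily_states(
    ep_row(2, "sickness_allowance_parttime", "2005-03-01", "2005-03-31"),
    fixture_person(2), B0, E0)
  expect_equal(tr2b$intervals$state,
               c("economic_inactivity", "work", "economic_inactivity"))

  # partial disability pension: work with earnings, time-restricted work
  # disability without
  tr3 <- assign_daily_states(
    rbind(ep_row(3, "partial_disability_pension", "2005-02-01", "2005-05-31"),
          ep_row(3, "earnings", "2005-02-01", "2005-03-31")),
    fixture_person(3), B0, E0)
  expect_equal(tr3$intervals$state[1:2],
               c("economic_inactivity", "work"))
  expect_equal(tr3$intervals$state[3], "time_restricted_work_disability")
  expect_equal(tr3$intervals$start_date[3], as.Date("2005-04-01"))
  expect_equal(tr3$intervals$end_date[3], as.Date("2005-05-31"))
})

test_that("a single covering earnings episode gives one work interval", {
  tr <- assign_daily_states(ep_row(1, "earnings", "2005-01-01", "2005-12-31"),
                            fixture_person(1), B0, E0)
  expect_equal(nrow(tr$intervals), 1L)
  expect_equal(tr$intervals$state, "work")
  expect_equal(tr$censor_reason, "study_end")
  expect_equal(tr$censor_date, E0)
})

test_that("three-person hand fixture matches the hand-resolved table", {
  episodes <- rbind(
    ep_row(1, "earnings", "2005-01-01", "2005-12-31"),
    ep_row(1, "unemployment_benefit", "2005-03-01", "2005-04-15"),
    ep_row(2, "earnings", "2005-01-01", "2005-06-30"),
    ep_row(2, "sickness_allowance_parttime", "2005-03-01", "2005-03-31"),
    ep_row(2, "partial_disability_pension", "2005-07-01", "2005-09-30"),
    ep_row(2, "earnings", "2005-10-01", "2005-12-31"),
    ep_row(2, "partial_disability_pension", "2005-10-01", "2005-10-31"),
    ep_row(3, "unemployment_benefit", "2005-05-01", "2005-07-31"),
    ep_row(3, "full_disability_pension", "2005-08-01", "2005-11-14"),
    ep_row(3, "death", "2005-11-15", "2005-11-15")
  )
  persons <- data.frame(person_id = 1:3, entry_age = c(55, 58, 60.5))
  traj <- assign_trajectories(episodes, persons, B0, E0)
  expected <- data.frame(
    person_id = c(1, 1, 1,
                  2, 2, 2,
                  3, 3, 3, 3),
    state = c("work", "unemployment", "work",
              "work", "time_restricted_work_disability", "work",
              "economic_inactivity", "unemployment",
              "disability_retirement", "death"),
    start_date = as.Date(c("2005-01-01", "2005-03-01", "2005-04-16",
                           "2005-01-01", "2005-07-01", "2005-10-01",
                           "2005-01-01", "2005-05-01",
                           "2005-08-01", "2005-11-15")),
    end_date = as.Date(c("2005-02-28", "2005-04-15", "2005-12-31",
                         "2005-06-30", "2005-09-30", "2005-12-31",
                         "2005-04-30", "2005-07-31",
                         "2005-11-14", "2005-11-15")),
    stringsAsFactors = FALSE
  )
  got <- traj$intervals
  rownames(got) <- NULL
  expect_equal(got, expected)
  expect_equal(traj$followup$censor_reason, c("study_end", "study_end",
                                              "death"))
  expect_equal(traj$followup$censor_date[3], as.Date("2005-11-15"))
})

test_that("person-time is conserved and trajectories are idempotent", {
  sim <- simulate_register(sim_config(n_persons = 150, seed = 17,
                                      overlap_rate = 0.4))
  traj <- assign_trajectories(sim$episodes, sim$persons,
                              sim$config$baseline_date,
                              sim$config$study_end_date)
  days <- as.numeric(traj$intervals$end_date - traj$intervals$start_date) + 1
  per_person <- tapply(days, traj$intervals$person_id, sum)
  fu <- traj$followup
  expected <- as.numeric(fu$censor_date - fu$entry_date) + 1
  expect_equal(as.numeric(per_person[as.character(fu$person_id)]),
               expected)

  # idempotence: re-render the assigned trajectory as clean episodes and
  # re-assign
  type_of <- c(work = "earnings",
               time_restricted_work_disability = "sickness_allowance_full",
               unemployment = "unemployment_benefit",
               disability_retirement = "full_disability_pension",
               retirement = "oldage_or_early_pension",
               death = "death")
  iv <- traj$intervals[traj$intervals$state != "economic_inactivity", ]
  ep2 <- data.frame(person_id = iv$person_id,
                    episode_type = unname(type_of[iv$state]),
                    start_date = iv$start_date, end_date = iv$end_date,
                    stringsAsFactors = FALSE)
  traj2 <- assign_trajectories(ep2, sim$persons,
                               sim$config$baseline_date,
                               sim$config$study_end_date)
  expect_equal(traj2$intervals, traj$intervals)
  expect_equal(traj2$followup, traj$followup)
})

test_that("censoring at age 63 ends follow-up the day before the birthday", {
  # entry at 62: 365.25 more days to the 63rd birthday
  tr <- assign_daily_states(ep_row(1, "earnings", "2005-01-01", "2014-10-31"),
                            fixture_person(1, entry_age = 62),
                            B0, as.Date("2014-10-31"))
  expect_equal(tr$censor_reason, "age_63")
  expect_equal(tr$censor_date, B0 + (ceiling(365.25) - 1))
  expect_equal(max(tr$intervals$end_date), tr$censor_date)
})

test_that("malformed episodes are data errors", {
  expect_error(assign_daily_states(
    ep_row(1, "holiday_pay", "2005-01-01", "2005-02-01"),
    fixture_person(1), B0, E0), "unknown episode_type")
  expect_error(assign_daily_states(
    ep_row(1, "earnings", "2005-03-01", "2005-02-01"),
    fixture_person(1), B0, E0), "end_date before start_date")
  expect_error(assign_daily_states(
    rbind(ep_row(1, "death", "2005-05-01", "2005-05-01"),
          ep_row(1, "earnings", "2005-06-01", "2005-07-01")),
    fixture_person(1), B0, E0), "after death")
})
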