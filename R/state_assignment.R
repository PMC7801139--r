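#' Episode types recognized by the daily-state assignment
#' @return Character vector of valid `episode_type` values.
#' @export
episode_types <- function() {
  c("earnings", "sickness_allowance_full", "sickness_allowance_parttime",
    "vocational_rehabilitation", "temporary_disability_pension",
    "partial_disability_pension", "full_disability_pension",
    "unemployment_benefit", "unemployment_pension",
    "oldage_or_early_pension", "death")
}

#' Default priority order for concurrent episodes
#'
#' When several states are candidates on the same day (beyond the explicit
#' override rules), the earlier state in this vector wins. Non-working
#' states rank above work so that working-years-lost are not underestimated;
#' among non-working states, ill-health (time-restricted work disability)
#' ranks above unemployment, which is a package convention (configurable).
#'
#' @return Character vector of the seven states, highest priority first.
#' @export
default_priority <- function() {
  c("death", "retirement", "disability_retirement",
    "time_restricted_work_disability", "unemployment", "work",
    "economic_inactivity")
}

#' Resolve overlapping episodes into a daily state trajectory
#'
#' Converts one person's raw register episodes (which may overlap) into a
#' gap-free sequence of daily labor-market states over the follow-up window,
#' then run-length-encodes the days into intervals. The assignment rules are:
#' \itemize{
#'   \item earnings with no concurrent ill-health or unemployment benefit
#'     -> work;
#'   \item part-time sickness allowance -> work (part-time sick-listed
#'     persons work part of the time);
#'   \item partial disability pension with concurrent earnings -> work,
#'     without earnings -> time-restricted work disability;
#'   \item full sickness allowance, vocational rehabilitation, or temporary
#'     disability pension -> time-restricted work disability;
#'   \item any unemployment benefit or unemployment pension -> unemployment,
#'     even with concurrent earnings (unemployment overrules earnings);
#'   \item full (permanent) disability pension -> disability retirement;
#'   \item old-age or early pension -> retirement;
#'   \item death -> death (single day, ends follow-up);
#'   \item a day with no episode at all -> economic inactivity.
#' }
#' Remaining simultaneity is broken by `priority`. Follow-up runs from
#' `baseline_date` to the earliest of the study end date, the day before the
#' person's age reaches 63 (entry age + days/365.25), and death.
#'
#' @param episodes data.frame of this person's episodes (`episode_type`,
#'   `start_date`, `end_date`; Date).
#' @param person one-row data.frame (or list) with `person_id` and
#'   `entry_age` (years at `baseline_date`).
#' @param baseline_date,study_end_date follow-up window (Date).
#' @param priority state priority order, see [default_priority()].
#' @param age_cap censoring age in years (default 63).
#' @return List of class `state_trajectory`: `intervals` (data.frame
#'   person_id, state, start_date, end_date), `entry_date`, `censor_date`,
#'   `censor_reason` (one of `age_63`, `study_end`, `death`).
#' @export
assign_daily_states <- function(episodes, person, baseline_date,
                                study_end_date, priority = default_priority(),
                                age_cap = 63) {
  baseline_date <- as.Date(baseline_date)
  study_end_date <- as.Date(study_end_date)
  unknown <- setdiff(unique(episodes$episode_type), episode_types())
  if (length(unknown)) {
    stop("unknown episode_type: ", paste(unknown, collapse = ", "))
  }
  if (nrow(episodes) && any(episodes$end_date < episodes$start_date)) {
    stop("episode with end_date before start_date")
  }
  stopifnot(setequal(priority, worklife_states()))

  fu_days <- as.integer(study_end_date - baseline_date)
  last63 <- as.integer(ceiling((age_cap - person$entry_age) * 365.25)) - 1L
  D <- min(fu_days, last63)
  reason <- if (last63 <= fu_days) "age_63" else "study_end"

  s_day <- as.integer(episodes$start_date - baseline_date)
  e_day <- as.integer(episodes$end_date - baseline_date)

  dth <- which(episodes$episode_type == "death")
  if (length(dth) > 1L) stop("multiple death episodes for person ",
                             person$person_id)
  if (length(dth) == 1L) {
    if (s_day[dth] != e_day[dth]) stop("death episode must be a single day")
    if (any(s_day[-dth] > s_day[dth])) {
      stop("episode starting after death for person ", person$person_id)
    }
    if (s_day[dth] <= D) {
      D <- s_day[dth]
      reason <- "death"
    }
  }
  if (D < 0L) stop("follow-up window is empty for person ", person$person_id)

  nd <- D + 1L
  cover <- function(types) {
    v <- logical(nd)
    for (i in which(episodes$episode_type %in% types)) {
      a <- max(0L, s_day[i]); b <- min(D, e_day[i])
      if (a <= b) v[(a + 1L):(b + 1L)] <- TRUE
    }
    v
  }
  earn <- cover("earnings")
  sa_full <- cover("sickness_allowance_full")
  sa_part <- cover("sickness_allowance_parttime")
  vocreh <- cover("vocational_rehabilitation")
  tempdp <- cover("temporary_disability_pension")
  partdp <- cover("partial_disability_pension")
  fulldp <- cover("full_disability_pension")
  unemp <- cover(c("unemployment_benefit", "unemployment_pension"))
  oldage <- cover("oldage_or_early_pension")
  dthv <- logical(nd)
  if (reason == "death") dthv[nd] <- TRUE

  illh <- sa_full | vocreh | tempdp | partdp | fulldp
  candidates <- list(
    work = (earn & !illh & !unemp) | sa_part | (partdp & earn),
    time_restricted_work_disability = sa_full | vocreh | tempdp |
      (partdp & !earn),
    unemployment = unemp,
    disability_retirement = fulldp,
    retirement = oldage,
    death = dthv
  )
  state_i <- rep(NA_integer_, nd)
  for (s in priority) {
    if (s == "economic_inactivity") next
    hit <- is.na(state_i) & candidates[[s]]
    state_i[hit] <- match(s, worklife_states())
  }
  state_i[is.na(state_i)] <- match("economic_inactivity", worklife_states())

  r <- rle(state_i)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  intervals <- data.frame(
    person_id = rep(person$person_id, length(r$values)),
    state = worklife_states()[r$values],
    start_date = baseline_date + (starts - 1L),
    end_date = baseline_date + (ends - 1L),
    stringsAsFactors = FALSE
  )
  structure(list(intervals = intervals,
                 entry_date = baseline_date,
                 censor_date = baseline_date + D,
                 censor_reason = reason),
            class = "state_trajectory")
}

#' Assign daily states for a whole cohort
#'
#' Applies [assign_daily_states()] to every person and collects the results
#' into the trajectory/follow-up pair used by the estimation stage.
#'
#' @param episodes episode data.frame for all persons (`person_id` column).
#' @param persons persons data.frame (`person_id`, `entry_age`).
#' @inheritParams assign_daily_states
#' @return List of class `trajectory_set`: `intervals` (stacked intervals)
#'   and `followup` (person_id, entry_date, censor_date, censor_reason).
#' @export
assign_trajectories <- function(episodes, persons, baseline_date,
                                study_end_date,
                                priority = default_priority(),
                                age_cap = 63) {
  ep_split <- split(seq_len(nrow(episodes)), episodes$person_id)
  ivs <- vector("list", nrow(persons))
  fu <- vector("list", nrow(persons))
  for (i in seq_len(nrow(persons))) {
    pid <- persons$person_id[i]
    rows <- ep_split[[as.character(pid)]]
    ep <- if (is.null(rows)) episodes[0, , drop = FALSE] else
      episodes[rows, , drop = FALSE]
    tr <- assign_daily_states(ep, persons[i, ], baseline_date,
                              study_end_date, priority, age_cap)
    ivs[[i]] <- tr$intervals
    fu[[i]] <- data.frame(person_id = pid, entry_date = tr$entry_date,
                          censor_date = tr$censor_date,
                          censor_reason = tr$censor_reason,
                          stringsAsFactors = FALSE)
  }
  structure(list(intervals = do.call(rbind, ivs),
                 followup = do.call(rbind, fu)),
            class = "trajectory_set")
}

#' Write a trajectory set to CSV
#' @param traj a `trajectory_set`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(traj, path) {
  utils::write.csv(traj$intervals, path, row.names = FALSE)
  invisible(path)
}
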