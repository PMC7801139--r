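#' Expected length of stay in each state
#'
#' Integrates the occupation probabilities of the Aalen-Johansen estimator
#' over the age window: ELOS_j = integral from s to horizon of
#' P_{start,j}(s, u) du. For the cadlag step estimator this is computed
#' exactly as the sum over grid intervals of the left-endpoint probability
#' times the interval width.
#'
#' @param aj an `aj_prob` from [aalen_johansen()].
#' @param start_state starting state (default `"work"`).
#' @return Named numeric vector of expected years per state; the components
#'   sum to `horizon - s` (13 years for the default 50-63 window).
#' @export
elos <- function(aj, start_state = "work") {
  si <- match(start_state, aj$states)
  if (is.na(si)) stop("unknown start_state")
  widths <- diff(c(aj$ages, aj$horizon))
  occ <- aj$P[si, , , drop = TRUE]       # states x grid
  if (is.null(dim(occ))) occ <- matrix(occ, nrow = length(aj$states))
  out <- drop(occ %*% widths)
  names(out) <- aj$states
  out
}

#' Working life expectancy and working years lost
#'
#' WLE is the expected number of years in the work state between the start
#' age and the horizon, starting in work; WYL is the complementary time,
#' decomposed by the non-work state in which it is spent. With the default
#' 50-63 window, WLE + the six WYL components = 13 years.
#'
#' @param elos_years named ELOS vector from [elos()] (start state work).
#' @param s,horizon the age window the ELOS was computed on.
#' @return Object of class `lifecourse_summary`: `WLE`, `WYL_by_state`
#'   (named: time_restricted_work_disability, disability_retirement, death,
#'   unemployment, economic_inactivity, retirement), `total_WYL`, `horizon_years`.
#' @export
wle_wyl <- function(elos_years, s = 50, horizon = 63) {
  horizon_years <- horizon - s
  if (abs(sum(elos_years) - horizon_years) > 1e-6) {
    stop("ELOS components do not sum to the horizon length")
  }
  canonical <- c("time_restricted_work_disability", "disability_retirement",
                 "death", "unemployment", "economic_inactivity", "retirement")
  wyl_states <- c(intersect(canonical, names(elos_years)),
                  setdiff(names(elos_years), c("work", canonical)))
  structure(list(WLE = unname(elos_years["work"]),
                 WYL_by_state = elos_years[wyl_states],
                 total_WYL = horizon_years - unname(elos_years["work"]),
                 horizon_years = horizon_years),
            class = "lifecourse_summary")
}

#' @export
print.lifecourse_summary <- function(x, ...) {
  cat(sprintf("WLE: %.2f years (of %g potential)\n", x$WLE,
              x$horizon_years))
  cat("WYL by state (years):\n")
  print(round(x$WYL_by_state, 2))
  cat(sprintf("total WYL: %.2f\n", x$total_WYL))
  invisible(x)
}

#' One-call lifecourse summary for a covariate profile
#'
#' Adjusts the fitted hazards to the profile, runs the Aalen-Johansen
#' product integral from `s`, integrates ELOS, and returns the WLE/WYL
#' decomposition.
#'
#' @param fit an `msm_fit`.
#' @param profile named covariate profile (NULL = reference).
#' @param s,horizon age window.
#' @param start_state starting state.
#' @return A `lifecourse_summary`.
#' @export
lifecourse_summary <- function(fit, profile = NULL, s = 50, horizon = 63,
                               start_state = "work") {
  aj <- aalen_johansen(fit, profile = profile, s = s, horizon = horizon)
  wle_wyl(elos(aj, start_state = start_state), s = s, horizon = horizon)
}

#' Flatten a lifecourse summary into a named vector
#' @param x a `lifecourse_summary`.
#' @return named numeric: WLE, WYL_<state> x6, total_WYL.
#' @export
summary_vector <- function(x) {
  c(WLE = x$WLE,
    stats::setNames(as.numeric(x$WYL_by_state),
                    paste0("WYL_", names(x$WYL_by_state))),
    total_WYL = x$total_WYL)
}

#' Build a covariate profile vector
#'
#' Convenience constructor: zero for every covariate except the indicators
#' for the requested occupational class and/or exposure category.
#'
#' @param covariates design-column names of the fitted model.
#' @param class occupational-class level or NULL (reference).
#' @param exposure exposure-category level or NULL (reference).
#' @return named numeric profile.
#' @export
make_profile <- function(covariates, class = NULL, exposure = NULL) {
  p <- stats::setNames(rep(0, length(covariates)), covariates)
  if (!is.null(class) && paste0("class_", class) %in% covariates) {
    p[paste0("class_", class)] <- 1
  }
  if (!is.null(exposure) && paste0("expo_", exposure) %in% covariates) {
    p[paste0("expo_", exposure)] <- 1
  }
  p
}

#' Percentile bootstrap confidence intervals for WLE and WYL
#'
#' Resamples persons with replacement (original cohort size), re-runs the
#' full estimation (all transition-specific Cox fits, the Aalen-Johansen
#' product integral, and the ELOS integration) on every resample, and
#' reports the 2.5th and 97.5th percentiles of each summary quantity per
#' covariate profile. One master seed spawns an independent sub-seed per
#' replicate, so results are reproducible and replicate order irrelevant.
#'
#' @param records transition records of the full cohort.
#' @param persons persons data.frame.
#' @param structure a `transition_structure`.
#' @param profiles named list of covariate profiles.
#' @param covariates design-column names for the fits.
#' @param B number of bootstrap replicates (default 100).
#' @param seed master seed.
#' @param s,horizon age window.
#' @param start_state starting state for the ELOS.
#' @return data.frame: profile, quantity, lower, upper (plus the replicate
#'   matrix in attribute `"replicates"`).
#' @export
bootstrap_ci <- function(records, persons, structure, profiles,
                         covariates = character(), B = 100L, seed = 1L,
                         s = 50, horizon = 63, start_state = "work") {
  stopifnot(B >= 1L)
  n <- nrow(persons)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, B)
  rec_by_person <- split(seq_len(nrow(records)), records$person_id)
  rec_key <- names(rec_by_person)
  states <- structure$space$states
  canonical <- c("time_restricted_work_disability", "disability_retirement",
                 "death", "unemployment", "economic_inactivity", "retirement")
  wyl_states <- c(intersect(canonical, states),
                  setdiff(states, c(start_state, canonical)))
  qty_names <- c("WLE", paste0("WYL_", wyl_states), "total_WYL")
  reps <- array(NA_real_,
                dim = c(B, length(profiles), length(qty_names)),
                dimnames = list(NULL, names(profiles), qty_names))
  for (b in seq_len(B)) {
    set.seed(sub_seeds[b])
    draw <- sample.int(n, n, replace = TRUE)
    pid <- persons$person_id[draw]
    rows <- rec_by_person[match(as.character(pid), rec_key)]
    lens <- lengths(rows)
    rec_b <- records[unlist(rows, use.names = FALSE), , drop = FALSE]
    new_id <- rep.int(seq_len(n), lens)
    rec_b$person_id <- new_id
    pers_b <- persons[draw, , drop = FALSE]
    pers_b$person_id <- seq_len(n)
    fit_b <- suppressWarnings(suppressMessages(
      fit_multistate(rec_b, pers_b, structure, covariates)
    ))
    for (pr in seq_along(profiles)) {
      sm <- suppressMessages(
        lifecourse_summary(fit_b, profiles[[pr]], s = s, horizon = horizon,
                           start_state = start_state)
      )
      reps[b, pr, ] <- summary_vector(sm)
    }
  }
  out <- do.call(rbind, lapply(seq_along(profiles), function(pr) {
    lo <- apply(reps[, pr, , drop = FALSE], 3L, stats::quantile,
                probs = 0.025, names = FALSE)
    hi <- apply(reps[, pr, , drop = FALSE], 3L, stats::quantile,
                probs = 0.975, names = FALSE)
    data.frame(profile = names(profiles)[pr], quantity = qty_names,
               lower = lo, upper = hi, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "replicates") <- reps
  out
}

#' Difference in WLE and WYL between two profiles
#'
#' Componentwise contrast (a minus b) of two lifecourse summaries computed
#' on the same age window, e.g. exposed minus non-exposed workers.
#'
#' @param summary_a,summary_b `lifecourse_summary` objects.
#' @return named numeric: WLE_diff, per-state WYL differences, total_WYL_diff.
#' @export
wyl_difference <- function(summary_a, summary_b) {
  if (summary_a$horizon_years != summary_b$horizon_years) {
    stop("summaries computed on different horizons")
  }
  c(WLE_diff = summary_a$WLE - summary_b$WLE,
    stats::setNames(as.numeric(summary_a$WYL_by_state -
                                 summary_b$WYL_by_state),
                    paste0("WYL_diff_", names(summary_a$WYL_by_state))),
    total_WYL_diff = summary_a$total_WYL - summary_b$total_WYL)
}
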