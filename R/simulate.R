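#' Simulation configuration for synthetic register data
#'
#' Bundles everything the synthetic-register generator needs: the state space
#' and transition structure, piecewise-constant baseline transition
#' intensities over age bands, proportional (log hazard ratio) covariate
#' effects per transition, the occupational-class mix, a job-exposure-matrix
#' table, and the follow-up window. Defaults emulate a register cohort of
#' workers aged 50-63 at a common baseline (2005-01-01) followed to
#' 2014-10-31, censored at age 63.
#'
#' @param n_persons number of persons to generate.
#' @param seed integer seed; the generator uses one stream keyed by this seed.
#' @param baseline_date,study_end_date follow-up window (Date or string).
#' @param entry_age_range entry ages are drawn uniformly over this range.
#' @param age_breaks band boundaries (years) for the piecewise-constant
#'   baseline intensities; must span the age window.
#' @param space,structure the state space and its transition enumeration.
#' @param intensities K x B matrix of baseline intensities (events per
#'   person-year), rows in transition-id order, columns = age bands.
#' @param effects K x P matrix of log hazard ratios; column names identify
#'   covariates (`class_<level>` or `expo_<category>`).
#' @param class_probs named probabilities over the four occupational classes.
#' @param jem job-exposure-matrix data.frame (see [default_jem()]).
#' @param occupation_pools named list: occupation codes sampled per class.
#' @param overlap_rate probability that a non-work benefit episode gets a
#'   spurious overlapping earnings spell (to exercise the priority rules).
#' @param p_woman probability a person is a woman.
#' @param exposure_threshold JEM dichotomization threshold (default 0.40).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_persons = 1000L,
                       seed = 1L,
                       baseline_date = "2005-01-01",
                       study_end_date = "2014-10-31",
                       entry_age_range = c(50, 63),
                       age_breaks = c(50, 55, 60, 63),
                       space = canonical_state_space(),
                       structure = transition_structure(space),
                       intensities = default_intensities(structure),
                       effects = default_effects(structure),
                       class_probs = c(manual = 0.31, lower_non_manual = 0.33,
                                       upper_non_manual = 0.21,
                                       self_employed = 0.15),
                       jem = default_jem(),
                       occupation_pools = default_occupation_pools(),
                       overlap_rate = 0.15,
                       p_woman = 0.5,
                       exposure_threshold = 0.40) {
  K <- structure$n_transitions
  if (!is.matrix(intensities) || nrow(intensities) != K ||
      ncol(intensities) != length(age_breaks) - 1L) {
    stop("`intensities` must be a ", K, " x ", length(age_breaks) - 1L,
         " matrix (transitions x age bands)")
  }
  if (any(intensities < 0)) stop("intensities must be >= 0")
  if (!is.matrix(effects) || nrow(effects) != K) {
    stop("`effects` must have one row per transition")
  }
  if (abs(sum(class_probs) - 1) > 1e-8) stop("class_probs must sum to 1")
  cfg <- list(
    n_persons = as.integer(n_persons), seed = as.integer(seed),
    baseline_date = as.Date(baseline_date),
    study_end_date = as.Date(study_end_date),
    entry_age_range = entry_age_range, age_breaks = age_breaks,
    space = space, structure = structure,
    intensities = intensities, effects = effects,
    class_probs = class_probs, jem = jem,
    occupation_pools = occupation_pools,
    overlap_rate = overlap_rate, p_woman = p_woman,
    exposure_threshold = exposure_threshold
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Default baseline transition intensities
#'
#' Piecewise-constant baseline intensities (events per person-year) over the
#' age bands 50-55, 55-60 and 60-63 for the canonical 27 transitions. The
#' values are synthetic test fixtures with plausible magnitudes for an older
#' workforce (rising ill-health exits with age, old-age retirement
#' concentrated in the last band, high return-to-work from short sick leave);
#' they are not estimates from any real population.
#'
#' @param structure a `transition_structure` (canonical by default).
#' @return K x 3 matrix, rows in transition-id order.
#' @export
default_intensities <- function(structure = transition_structure(canonical_state_space())) {
  tr <- structure$transitions
  rate <- function(from, to) {
    # returns c(band 50-55, 55-60, 60-63)
    key <- paste(from, to, sep = ">")
    switch(key,
      "work>time_restricted_work_disability" = c(0.060, 0.080, 0.100),
      "work>unemployment"                    = c(0.055, 0.065, 0.075),
      "work>economic_inactivity"             = c(0.020, 0.020, 0.025),
      "work>disability_retirement"           = c(0.008, 0.018, 0.030),
      "work>retirement"                      = c(0.000, 0.004, 0.350),
      "work>death"                           = c(0.003, 0.005, 0.008),
      "time_restricted_work_disability>work" = c(0.900, 0.750, 0.550),
      "time_restricted_work_disability>unemployment"        = c(0.060, 0.060, 0.050),
      "time_restricted_work_disability>economic_inactivity" = c(0.050, 0.050, 0.050),
      "time_restricted_work_disability>disability_retirement" = c(0.220, 0.280, 0.340),
      "time_restricted_work_disability>retirement"          = c(0.000, 0.000, 0.180),
      "time_restricted_work_disability>death"               = c(0.010, 0.012, 0.015),
      "unemployment>work"                    = c(0.350, 0.220, 0.080),
      "unemployment>time_restricted_work_disability" = c(0.050, 0.055, 0.060),
      "unemployment>economic_inactivity"     = c(0.050, 0.045, 0.040),
      "unemployment>disability_retirement"   = c(0.015, 0.030, 0.050),
      "unemployment>retirement"              = c(0.000, 0.005, 0.380),
      "unemployment>death"                   = c(0.005, 0.007, 0.010),
      "economic_inactivity>work"             = c(0.250, 0.150, 0.050),
      "economic_inactivity>time_restricted_work_disability" = c(0.030, 0.035, 0.040),
      "economic_inactivity>unemployment"     = c(0.060, 0.050, 0.040),
      "economic_inactivity>disability_retirement" = c(0.015, 0.025, 0.040),
      "economic_inactivity>retirement"       = c(0.000, 0.005, 0.300),
      "economic_inactivity>death"            = c(0.005, 0.008, 0.012),
      "disability_retirement>retirement"     = c(0.000, 0.000, 0.500),
      "disability_retirement>death"          = c(0.020, 0.028, 0.038),
      "retirement>death"                     = c(0.018, 0.025, 0.035),
      stop("no default intensity for transition ", key)
    )
  }
  out <- t(mapply(rate, tr$from, tr$to))
  dimnames(out) <- list(paste(tr$from, tr$to, sep = ">"),
                        c("50-55", "55-60", "60-63"))
  out
}

#' Default covariate effects (log hazard ratios) per transition
#'
#' Synthetic fixture effects for occupational class (reference: upper
#' non-manual) and physical-workload exposure category (reference: none).
#' Directions follow the expected epidemiology: manual work and high physical
#' exposure raise ill-health-related exit intensities (to time-restricted
#' work disability, disability retirement, death) and unemployment, and
#' slightly lower return-to-work intensities; the self-employed have lower
#' unemployment and ill-health exit intensities. Magnitudes are invented.
#'
#' @param structure a `transition_structure`.
#' @return K x 5 matrix with columns `class_manual`,
#'   `class_lower_non_manual`, `class_self_employed`, `expo_one_to_three`,
#'   `expo_four_to_five`.
#' @export
default_effects <- function(structure = transition_structure(canonical_state_space())) {
  tr <- structure$transitions
  cols <- c("class_manual", "class_lower_non_manual", "class_self_employed",
            "expo_one_to_three", "expo_four_to_five")
  eff <- matrix(0, nrow(tr), length(cols),
                dimnames = list(paste(tr$from, tr$to, sep = ">"), cols))
  ill <- tr$to %in% c("time_restricted_work_disability",
                      "disability_retirement", "death")
  eff[ill, ] <- rep(c(0.40, 0.15, -0.20, 0.25, 0.50), each = sum(ill))
  unemp <- tr$to == "unemployment"
  eff[unemp, ] <- rep(c(0.50, 0.20, -0.60, 0.10, 0.20), each = sum(unemp))
  rtw <- tr$to == "work"
  eff[rtw, ] <- rep(c(-0.20, -0.05, 0.10, -0.10, -0.30), each = sum(rtw))
  eff
}

#' Default synthetic job-exposure matrix
#'
#' A small gender-specific JEM: for each occupation code and gender, the
#' probability of exposure to each of five physical workload factors (heavy
#' physical work, kneeling or squatting, manual handling of heavy loads,
#' hands above shoulder level, awkward trunk posture). Codes are chosen so
#' the default class-specific occupation pools span all three exposure
#' categories. Synthetic values, not a real JEM.
#'
#' @return data.frame with columns `occupation_code`, `gender`, and the five
#'   factor columns, values in [0, 1].
#' @export
default_jem <- function() {
  fac <- c("heavy_physical_work", "kneeling_squatting",
           "manual_handling_heavy_loads", "hands_above_shoulder",
           "awkward_trunk_posture")
  rows <- list(
    # code, men values, women values
    list("711", c(0.85, 0.60, 0.55, 0.45, 0.70), c(0.80, 0.55, 0.30, 0.42, 0.72)),
    list("712", c(0.75, 0.65, 0.50, 0.55, 0.60), c(0.70, 0.52, 0.25, 0.45, 0.62)),
    list("811", c(0.55, 0.30, 0.45, 0.20, 0.50), c(0.60, 0.28, 0.20, 0.18, 0.55)),
    list("913", c(0.50, 0.45, 0.25, 0.15, 0.55), c(0.62, 0.48, 0.15, 0.12, 0.58)),
    list("411", c(0.05, 0.03, 0.02, 0.04, 0.10), c(0.08, 0.10, 0.03, 0.04, 0.15)),
    list("422", c(0.10, 0.05, 0.03, 0.05, 0.12), c(0.15, 0.20, 0.06, 0.05, 0.22)),
    list("513", c(0.35, 0.42, 0.15, 0.10, 0.45), c(0.45, 0.41, 0.12, 0.08, 0.48)),
    list("211", c(0.02, 0.01, 0.01, 0.03, 0.03), c(0.02, 0.04, 0.01, 0.05, 0.08)),
    list("231", c(0.03, 0.02, 0.01, 0.10, 0.05), c(0.03, 0.06, 0.01, 0.12, 0.10)),
    list("611", c(0.70, 0.60, 0.55, 0.25, 0.65), c(0.60, 0.48, 0.45, 0.20, 0.60)),
    list("522", c(0.30, 0.20, 0.35, 0.12, 0.42), c(0.35, 0.25, 0.30, 0.12, 0.45))
  )
  out <- do.call(rbind, lapply(rows, function(r) {
    d <- rbind(r[[2]], r[[3]])
    data.frame(occupation_code = r[[1]], gender = c("man", "woman"),
               as.data.frame(d), stringsAsFactors = FALSE)
  }))
  names(out)[3:7] <- fac
  rownames(out) <- NULL
  out
}

#' Default occupation-code pools per occupational class
#' @return named list of character vectors of occupation codes.
#' @export
default_occupation_pools <- function() {
  list(manual = c("711", "712", "811", "913"),
       lower_non_manual = c("411", "422", "513"),
       upper_non_manual = c("211", "231"),
       self_employed = c("611", "522", "711"))
}

#' Build a covariate design matrix from a persons table
#'
#' Maps covariate names to person columns: `class_<level>` becomes an
#' indicator for `occupational_class == level`, `expo_<category>` an
#' indicator for `exposure_category == category`.
#'
#' @param persons persons data.frame with `occupational_class` and (if any
#'   `expo_*` names are requested) `exposure_category`.
#' @param covariate_names character vector of design-column names.
#' @return numeric matrix, one row per person, one column per name.
#' @export
covariate_design <- function(persons, covariate_names) {
  n <- nrow(persons)
  if (length(covariate_names) == 0L) {
    return(matrix(0, n, 0))
  }
  cols <- lapply(covariate_names, function(nm) {
    if (startsWith(nm, "class_")) {
      as.numeric(persons$occupational_class == sub("^class_", "", nm))
    } else if (startsWith(nm, "expo_")) {
      as.numeric(persons$exposure_category == sub("^expo_", "", nm))
    } else {
      stop("unknown covariate name: ", nm)
    }
  })
  out <- do.call(cbind, cols)
  colnames(out) <- covariate_names
  out
}

# Vectorized continuous-time Markov chain over piecewise-constant intensities.
# entry_age, censor_age: per-person; expfac: n x K multiplicative hazard
# factors. Returns data.frame(person, age, from, to) of transition events.
simulate_paths <- function(entry_age, censor_age, structure, intensities,
                           expfac, age_breaks, start_state = "work") {
  states <- structure$space$states
  tr <- structure$transitions
  K <- nrow(tr)
  from_i <- match(tr$from, states)
  to_i <- match(tr$to, states)
  n <- length(entry_age)
  cur_age <- entry_age
  cur_state <- rep(match(start_state, states), n)
  done <- cur_age >= censor_age
  death_i <- match("death", states)
  acc <- vector("list", 0L)
  guard <- 0L
  while (any(!done)) {
    guard <- guard + 1L
    if (guard > 10000L) stop("simulation failed to terminate")
    act <- which(!done)
    na <- length(act)
    band <- findInterval(pmin(cur_age[act], age_breaks[length(age_breaks)] - 1e-12),
                         age_breaks)
    rate <- matrix(0, na, K)
    for (k in seq_len(K)) {
      sel <- cur_state[act] == from_i[k]
      if (any(sel)) {
        rate[sel, k] <- intensities[k, band[sel]] * expfac[act[sel], k]
      }
    }
    tot <- rowSums(rate)
    w <- stats::rexp(na)
    w <- ifelse(tot > 0, w / tot, Inf)
    t_bound <- age_breaks[pmin(band + 1L, length(age_breaks))] - cur_age[act]
    t_cens <- censor_age[act] - cur_age[act]
    lim <- pmin(t_bound, t_cens)
    is_event <- w < lim
    # advance non-events to the band boundary or censoring age
    adv <- act[!is_event]
    if (length(adv)) {
      hit_cens <- t_cens[!is_event] <= t_bound[!is_event]
      cur_age[adv] <- cur_age[adv] + lim[!is_event]
      done[adv[hit_cens]] <- TRUE
      done[adv] <- done[adv] | cur_age[adv] >= censor_age[adv]
    }
    evt <- act[is_event]
    if (length(evt)) {
      ne <- length(evt)
      new_age <- cur_age[evt] + w[is_event]
      u <- stats::runif(ne) * tot[is_event]
      dest_k <- rep(NA_integer_, ne)
      cum <- rep(0, ne)
      rate_e <- rate[is_event, , drop = FALSE]
      for (k in seq_len(K)) {
        cum <- cum + rate_e[, k]
        hit <- is.na(dest_k) & u <= cum & rate_e[, k] > 0
        dest_k[hit] <- k
      }
      dest_k[is.na(dest_k)] <- max.col(rate_e, ties.method = "last")[is.na(dest_k)]
      acc[[length(acc) + 1L]] <- data.frame(
        person = evt, age = new_age,
        from = cur_state[evt], to = to_i[dest_k]
      )
      cur_state[evt] <- to_i[dest_k]
      cur_age[evt] <- new_age
      done[evt] <- done[evt] | to_i[dest_k] == death_i |
        all_absorbed(to_i[dest_k], structure)
    }
  }
  if (length(acc)) {
    ev <- do.call(rbind, acc)
    ev <- ev[order(ev$person, ev$age), , drop = FALSE]
    rownames(ev) <- NULL
    ev
  } else {
    data.frame(person = integer(), age = numeric(),
               from = integer(), to = integer())
  }
}

# TRUE for destinations with no outgoing transitions in the structure
all_absorbed <- function(state_idx, structure) {
  states <- structure$space$states
  has_exit <- states %in% structure$transitions$from
  !has_exit[state_idx]
}

#' Generate a synthetic register cohort
#'
#' Draws persons (gender, occupational class, occupation code, entry age
#' uniform over the configured range), derives their physical-workload
#' exposure category from the JEM, simulates latent daily state trajectories
#' as a continuous-time Markov chain with piecewise-constant baseline
#' intensities modified proportionally by the covariate effects, truncates at
#' the earlier of age 63 and the study end date, and renders the latent
#' states as overlapping episode records (earnings spells for work, benefit
#' spells otherwise; economic inactivity leaves a gap). A configurable share
#' of benefit episodes is overlapped by spurious earnings spells so that
#' downstream priority rules are exercised.
#'
#' @param config a [sim_config()].
#' @param render_episodes if `FALSE`, skip episode rendering (useful for
#'   non-canonical state spaces in simulation studies).
#' @return List of class `register_sim`: `persons`, `episodes`, `jem`,
#'   `trajectories` (latent intervals: person_id, state, start_date,
#'   end_date), `followup` (person_id, entry_date, censor_date,
#'   censor_reason), `config`.
#' @examples
#' sim <- simulate_register(sim_config(n_persons = 50, seed = 42))
#' head(sim$episodes)
#' @export
simulate_register <- function(config, render_episodes = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_persons
  states <- config$space$states
  if (render_episodes && !all(states %in% worklife_states())) {
    stop("episode rendering requires canonical state labels; ",
         "use render_episodes = FALSE")
  }
  classes <- names(config$class_probs)
  persons <- data.frame(
    person_id = seq_len(n),
    gender = ifelse(stats::runif(n) < config$p_woman, "woman", "man"),
    occupational_class = sample(classes, n, replace = TRUE,
                                prob = config$class_probs),
    stringsAsFactors = FALSE
  )
  persons$occupation_code <- vapply(persons$occupational_class, function(cl) {
    pool <- config$occupation_pools[[cl]]
    pool[sample.int(length(pool), 1L)]
  }, character(1))
  persons$entry_age <- stats::runif(n, config$entry_age_range[1],
                                    config$entry_age_range[2])
  persons <- add_exposure(persons, config$jem,
                          threshold = config$exposure_threshold)

  Z <- covariate_design(persons, colnames(config$effects))
  expfac <- exp(Z %*% t(config$effects))  # n x K

  max_age <- config$age_breaks[length(config$age_breaks)]
  fu_days <- as.integer(config$study_end_date - config$baseline_date)
  censor_age <- pmin(max_age, persons$entry_age + (fu_days + 1) / 365.25)
  events <- simulate_paths(persons$entry_age, censor_age, config$structure,
                           config$intensities, expfac, config$age_breaks)
  traj <- events_to_trajectories(events, persons, config)
  episodes <- NULL
  if (render_episodes) {
    episodes <- render_episode_records(traj$intervals, config)
  }
  structure(list(persons = persons, episodes = episodes, jem = config$jem,
                 trajectories = traj$intervals, followup = traj$followup,
                 config = config),
            class = "register_sim")
}

# Discretize event ages to days and assemble latent day-resolution intervals.
events_to_trajectories <- function(events, persons, config) {
  states <- config$space$states
  n <- nrow(persons)
  fu_days <- as.integer(config$study_end_date - config$baseline_date)
  last63 <- ceiling((config$age_breaks[length(config$age_breaks)] -
                       persons$entry_age) * 365.25) - 1
  D <- pmin(fu_days, last63)
  reason <- ifelse(last63 <= fu_days, "age_63", "study_end")

  ev <- events
  if (nrow(ev)) {
    ev$day <- pmax(1L,
                   as.integer(ceiling((ev$age - persons$entry_age[ev$person]) * 365.25)))
    ev <- ev[ev$day <= D[ev$person], , drop = FALSE]
    # enforce strictly increasing change days within person (rare collisions)
    if (nrow(ev) > 1L) {
      same <- ev$person[-1L] == ev$person[-nrow(ev)]
      bad <- c(FALSE, same & diff(ev$day) <= 0L)
      if (any(bad)) {
        for (p in unique(ev$person[bad])) {
          i <- which(ev$person == p)
          d <- ev$day[i]
          for (j in seq_along(d)[-1L]) d[j] <- max(d[j], d[j - 1L] + 1L)
          ev$day[i] <- d
        }
        ev <- ev[ev$day <= D[ev$person], , drop = FALSE]
      }
    }
  }
  death_i <- match("death", states)
  died <- ev$person[ev$to == death_i]
  D[died] <- ev$day[ev$to == death_i]
  reason[died] <- "death"

  # build intervals: per person, states c(start, ev$to...), change days
  n_ev <- tabulate(ev$person, nbins = n)
  pid <- rep.int(seq_len(n), n_ev + 1L)
  first <- !duplicated(pid)
  st <- integer(length(pid))
  st[first] <- match("work", states)
  st[!first] <- ev$to
  start_day <- integer(length(pid))
  start_day[!first] <- ev$day
  end_day <- integer(length(pid))
  last <- !duplicated(pid, fromLast = TRUE)
  end_day[!last] <- ev$day - 1L
  end_day[last] <- D[pid[last]]
  keep <- start_day <= end_day  # guard (cannot trigger by construction)
  intervals <- data.frame(
    person_id = pid[keep],
    state = states[st[keep]],
    start_date = config$baseline_date + start_day[keep],
    end_date = config$baseline_date + end_day[keep],
    stringsAsFactors = FALSE
  )
  followup <- data.frame(
    person_id = seq_len(n),
    entry_date = rep(config$baseline_date, n),
    censor_date = config$baseline_date + D,
    censor_reason = reason,
    stringsAsFactors = FALSE
  )
  list(intervals = intervals, followup = followup)
}

# Render latent state intervals as raw episode records; inject overlapping
# earnings spells over a share of benefit episodes.
render_episode_records <- function(intervals, config) {
  type_of <- c(
    work = "earnings",
    unemployment = "unemployment_benefit",
    disability_retirement = "full_disability_pension",
    retirement = "oldage_or_early_pension",
    death = "death"
  )
  trwd_types <- c("sickness_allowance_full", "vocational_rehabilitation",
                  "temporary_disability_pension")
  iv <- intervals[intervals$state != "economic_inactivity", , drop = FALSE]
  etype <- character(nrow(iv))
  is_trwd <- iv$state == "time_restricted_work_disability"
  etype[!is_trwd] <- type_of[iv$state[!is_trwd]]
  etype[is_trwd] <- sample(trwd_types, sum(is_trwd), replace = TRUE)
  ep <- data.frame(person_id = iv$person_id, episode_type = etype,
                   start_date = iv$start_date, end_date = iv$end_date,
                   stringsAsFactors = FALSE)
  ep$end_date[ep$episode_type == "death"] <- ep$start_date[ep$episode_type == "death"]

  benefit <- !(ep$episode_type %in% c("earnings", "death"))
  hit <- benefit & stats::runif(nrow(ep)) < config$overlap_rate
  if (any(hit)) {
    len <- as.integer(ep$end_date[hit] - ep$start_date[hit]) + 1L
    off <- as.integer(floor(stats::runif(sum(hit)) * pmax(1L, len %/% 2L)))
    sub_start <- ep$start_date[hit] + off
    sub_len <- pmax(1L, as.integer(ceiling(stats::runif(sum(hit)) *
                                             pmax(1L, len - off))))
    sub_end <- pmin(ep$end_date[hit], sub_start + sub_len - 1L)
    ep <- rbind(ep, data.frame(person_id = ep$person_id[hit],
                               episode_type = "earnings",
                               start_date = sub_start, end_date = sub_end,
                               stringsAsFactors = FALSE))
  }
  ep <- ep[order(ep$person_id, ep$start_date, ep$episode_type), , drop = FALSE]
  rownames(ep) <- NULL
  ep
}

#' Write / read a synthetic register to CSV files
#'
#' Writes `persons.csv` (person_id, gender, occupational_class,
#' occupation_code, entry_age), `episodes.csv` (person_id, episode_type,
#' start_date, end_date; ISO-8601 dates, closed intervals) and `jem.csv`.
#'
#' @param sim a `register_sim`.
#' @param dir output directory (created if needed).
#' @return `write_register` returns `dir` invisibly; the readers return
#'   data.frames with dates parsed.
#' @export
write_register <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- sim$persons[, c("person_id", "gender", "occupational_class",
                       "occupation_code", "entry_age")]
  utils::write.csv(p, file.path(dir, "persons.csv"), row.names = FALSE)
  utils::write.csv(sim$episodes, file.path(dir, "episodes.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$jem, file.path(dir, "jem.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_register
#' @param path a CSV file path.
#' @export
read_episodes <- function(path) {
  ep <- utils::read.csv(path, stringsAsFactors = FALSE)
  ep$start_date <- as.Date(ep$start_date)
  ep$end_date <- as.Date(ep$end_date)
  ep
}

#' @rdname write_register
#' @export
read_persons <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(occupation_code = "character"))
}

#' @rdname write_register
#' @export
read_jem <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(occupation_code = "character"))
}
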