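#' Build a pipeline run configuration
#'
#' Assembles (with defaults) the configuration consumed by
#' [run_pipeline()]: either a `simulate` block (synthetic cohort) or input
#' CSV paths, the follow-up window, gender strata, the covariate mode, the
#' sensitivity filter excluding the self-employed, the bootstrap size, and
#' the output directory.
#'
#' @param output_dir where result files are written.
#' @param simulate NULL, or list(n_persons, seed, overlap_rate) to generate
#'   a synthetic register.
#' @param persons_csv,episodes_csv,jem_csv input paths (ignored when
#'   `simulate` is given).
#' @param baseline_date,study_end_date follow-up window.
#' @param genders strata to analyse (default both).
#' @param covariate_mode one of `"class"`, `"exposure"`, `"joint"`.
#' @param exclude_self_employed sensitivity filter.
#' @param start_age,horizon_age ELOS window (default 50 to 63).
#' @param B bootstrap replicates (0 disables the bootstrap).
#' @param bootstrap_seed master seed for the bootstrap.
#' @param exposure_threshold JEM dichotomization threshold.
#' @return list of class `run_config`.
#' @export
run_config <- function(output_dir = "worklife-output",
                       simulate = list(n_persons = 1000, seed = 1,
                                       overlap_rate = 0.15),
                       persons_csv = NULL, episodes_csv = NULL,
                       jem_csv = NULL,
                       baseline_date = "2005-01-01",
                       study_end_date = "2014-10-31",
                       genders = c("man", "woman"),
                       covariate_mode = c("class", "exposure", "joint"),
                       exclude_self_employed = FALSE,
                       start_age = 50, horizon_age = 63,
                       B = 0L, bootstrap_seed = 1L,
                       exposure_threshold = 0.40) {
  covariate_mode <- match.arg(covariate_mode)
  stopifnot(start_age < horizon_age, B >= 0)
  structure(list(output_dir = output_dir, simulate = simulate,
                 persons_csv = persons_csv, episodes_csv = episodes_csv,
                 jem_csv = jem_csv,
                 baseline_date = as.Date(baseline_date),
                 study_end_date = as.Date(study_end_date),
                 genders = genders, covariate_mode = covariate_mode,
                 exclude_self_employed = isTRUE(exclude_self_employed),
                 start_age = start_age, horizon_age = horizon_age,
                 B = as.integer(B), bootstrap_seed = as.integer(bootstrap_seed),
                 exposure_threshold = exposure_threshold),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; keys as in [run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

mode_covariates <- function(mode) {
  switch(mode,
    class = c("class_manual", "class_lower_non_manual",
              "class_self_employed"),
    exposure = c("expo_one_to_three", "expo_four_to_five"),
    joint = c("class_manual", "class_lower_non_manual",
              "class_self_employed", "expo_one_to_three",
              "expo_four_to_five"),
    stop("unknown covariate mode: ", mode)
  )
}

mode_profiles <- function(mode, include_self_employed = TRUE) {
  covs <- mode_covariates(mode)
  classes <- c("upper_non_manual", "lower_non_manual", "manual",
               if (include_self_employed) "self_employed")
  expos <- c("none", "one_to_three", "four_to_five")
  if (mode == "class") {
    profs <- lapply(classes, function(cl) make_profile(covs, class = cl))
    names(profs) <- classes
  } else if (mode == "exposure") {
    profs <- lapply(expos, function(e) make_profile(covs, exposure = e))
    names(profs) <- expos
  } else {
    grid <- expand.grid(class = classes, exposure = expos,
                        stringsAsFactors = FALSE)
    profs <- lapply(seq_len(nrow(grid)), function(i) {
      make_profile(covs, class = grid$class[i], exposure = grid$exposure[i])
    })
    names(profs) <- paste(grid$class, grid$exposure, sep = ".")
  }
  profs
}

#' Run the full estimation pipeline
#'
#' Orchestrates simulate (or read) -> JEM exposure -> daily-state assignment
#' -> transition records -> per-transition Cox fits -> Aalen-Johansen ->
#' ELOS / WLE / WYL -> percentile bootstrap, separately per gender, and
#' writes trajectories, fitted coefficients, summary tables and a run
#' manifest to the output directory. Deterministic for fixed seeds.
#'
#' @param config a `run_config`.
#' @param quiet suppress per-stage log messages.
#' @return (invisibly) list with `summaries` (data.frame), `fits` (per
#'   gender), `trajectories`, `persons`, `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  log <- function(...) if (!quiet) message("[worklife] ", ...)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$simulate)) {
    sc <- sim_config(n_persons = config$simulate$n_persons,
                     seed = config$simulate$seed,
                     baseline_date = config$baseline_date,
                     study_end_date = config$study_end_date,
                     overlap_rate = config$simulate$overlap_rate %||% 0.15,
                     exposure_threshold = config$exposure_threshold)
    sim <- simulate_register(sc)
    persons_raw <- sim$persons[, c("person_id", "gender",
                                   "occupational_class", "occupation_code",
                                   "entry_age")]
    episodes <- sim$episodes
    jem <- sim$jem
    log("simulated ", nrow(persons_raw), " persons, ", nrow(episodes),
        " episodes (seed ", config$simulate$seed, ")")
  } else {
    persons_raw <- read_persons(config$persons_csv)
    episodes <- read_episodes(config$episodes_csv)
    jem <- read_jem(config$jem_csv)
    log("read ", nrow(persons_raw), " persons, ", nrow(episodes),
        " episodes")
  }

  persons <- suppressMessages(
    add_exposure(persons_raw, jem, threshold = config$exposure_threshold)
  )
  n_excluded <- nrow(attr(persons, "excluded"))
  log("exposure linkage: ", nrow(persons), " persons kept, ", n_excluded,
      " excluded (missing JEM key)")

  episodes <- episodes[episodes$person_id %in% persons$person_id, ,
                       drop = FALSE]
  traj <- assign_trajectories(episodes, persons, config$baseline_date,
                              config$study_end_date,
                              age_cap = config$horizon_age)
  log("assigned ", nrow(traj$intervals), " state intervals")
  write_trajectories(traj, file.path(config$output_dir, "trajectories.csv"))

  space <- canonical_state_space()
  struct <- transition_structure(space)
  covs <- mode_covariates(config$covariate_mode)
  profiles <- mode_profiles(config$covariate_mode,
                            include_self_employed = !config$exclude_self_employed)

  all_summaries <- list()
  fits <- list()
  counts <- list()
  for (g in config$genders) {
    pers_g <- persons[persons$gender == g, , drop = FALSE]
    if (config$exclude_self_employed) {
      pers_g <- pers_g[pers_g$occupational_class != "self_employed", ,
                       drop = FALSE]
    }
    if (nrow(pers_g) == 0L) {
      log("gender ", g, ": no persons, skipped")
      next
    }
    keep <- traj$intervals$person_id %in% pers_g$person_id
    traj_g <- list(intervals = traj$intervals[keep, , drop = FALSE],
                   followup = traj$followup[
                     traj$followup$person_id %in% pers_g$person_id, ,
                     drop = FALSE])
    records <- to_transition_records(traj_g, pers_g, struct,
                                     max_age = config$horizon_age)
    log("gender ", g, ": ", nrow(pers_g), " persons, ", nrow(records),
        " transition records, ", sum(records$status), " events")
    fit <- suppressMessages(fit_multistate(records, pers_g, struct, covs))
    fits[[g]] <- fit

    coefs <- do.call(rbind, lapply(fit$fits, function(f) {
      if (!length(f$beta)) return(NULL)
      data.frame(transition_id = f$transition_id,
                 from = struct$transitions$from[f$transition_id],
                 to = struct$transitions$to[f$transition_id],
                 term = names(f$beta), beta = as.numeric(f$beta),
                 se = as.numeric(f$se), n_events = f$n_events,
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(coefs,
                     file.path(config$output_dir,
                               paste0("coefficients_", g, ".csv")),
                     row.names = FALSE)

    est <- lapply(profiles, function(pr) {
      summary_vector(suppressMessages(
        lifecourse_summary(fit, pr, s = config$start_age,
                           horizon = config$horizon_age)))
    })
    sm <- do.call(rbind, lapply(names(est), function(nm) {
      data.frame(gender = g, profile = nm, quantity = names(est[[nm]]),
                 estimate = as.numeric(est[[nm]]),
                 stringsAsFactors = FALSE)
    }))
    if (config$B >= 1L) {
      ci <- bootstrap_ci(records, pers_g, struct, profiles, covs,
                         B = config$B, seed = config$bootstrap_seed,
                         s = config$start_age, horizon = config$horizon_age)
      sm <- merge(sm, ci, by = c("profile", "quantity"), sort = FALSE)
      log("gender ", g, ": bootstrap done (B = ", config$B, ")")
    }
    all_summaries[[g]] <- sm
    counts[[g]] <- list(persons = nrow(pers_g), records = nrow(records),
                        events = sum(records$status))
  }
  summaries <- do.call(rbind, all_summaries)
  rownames(summaries) <- NULL
  utils::write.csv(summaries, file.path(config$output_dir, "summaries.csv"),
                   row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("worklife")),
    covariate_mode = config$covariate_mode,
    exclude_self_employed = config$exclude_self_employed,
    window = c(config$start_age, config$horizon_age),
    baseline_date = as.character(config$baseline_date),
    study_end_date = as.character(config$study_end_date),
    seeds = list(simulate = config$simulate$seed %||% NA,
                 bootstrap = config$bootstrap_seed),
    B = config$B,
    n_persons_input = nrow(persons_raw),
    n_excluded_missing_jem = n_excluded,
    n_episodes = nrow(episodes),
    strata = counts
  )
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log("wrote results to ", config$output_dir)
  invisible(list(summaries = summaries, fits = fits, trajectories = traj,
                 persons = persons, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
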