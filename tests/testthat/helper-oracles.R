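# Independent oracle implementations used to cross-check the package.
# Deliberately written in a plain loop-based style, sharing no code with R/.

# Brute-force enumeration of allowed ordered state pairs under the rules:
# no self-transitions, no exits from absorbing states, restricted states may
# only move to their listed destinations.
brute_force_transitions <- function(states, absorbing = character(),
                                    restricted = list()) {
  out <- list()
  for (a in states) {
    if (a %in% absorbing) next
    for (b in states) {
      if (a == b) next
      if (a %in% names(restricted) && !(b %in% restricted[[a]])) next
      out[[length(out) + 1L]] <- c(a, b)
    }
  }
  out
}

# Hand-coded Cox log partial likelihood with Breslow ties and left
# truncation; x is a numeric matrix, beta a vector.
cox_loglik_oracle <- function(beta, entry, exit, status, x) {
  lp <- as.numeric(x %*% beta)
  ll <- 0
  for (i in which(status == 1L)) {
    at_risk <- entry < exit[i] & exit >= exit[i]
    ll <- ll + lp[i] - log(sum(exp(lp[at_risk])))
  }
  ll
}

# Plain nonparametric Aalen-Johansen estimator from sojourn-level data
# (one row per sojourn: entry, exit, from, to; to = NA when censored).
naive_aj <- function(sojourns, states, s, horizon) {
  ev <- sojourns[!is.na(sojourns$to) & sojourns$exit > s &
                   sojourns$exit <= horizon, ]
  times <- sort(unique(ev$exit))
  ns <- length(states)
  P <- diag(ns)
  dimnames(P) <- list(states, states)
  for (u in times) {
    dA <- matrix(0, ns, ns, dimnames = list(states, states))
    for (j in states) {
      Yj <- sum(sojourns$from == j & sojourns$entry < u & sojourns$exit >= u)
      if (Yj == 0) next
      for (k in states) {
        if (k == j) next
        Njk <- sum(ev$from == j & ev$to == k & ev$exit == u)
        dA[j, k] <- Njk / Yj
      }
      dA[j, j] <- -sum(dA[j, ])
    }
    P <- P %*% (diag(ns) + dA)
  }
  P
}

# Deterministic state-occupation truth for time-homogeneous (per age band)
# Markov intensities: propagates p(u) through matrix exponentials on a fine
# grid and integrates occupation probabilities by the trapezoid rule.
true_elos_pwc <- function(structure, intensities, age_breaks, s, horizon,
                          hr = NULL, start_state = "work", h = 0.0025) {
  states <- structure$space$states
  ns <- length(states)
  tr <- structure$transitions
  K <- nrow(tr)
  if (is.null(hr)) hr <- rep(1, K)
  p <- rep(0, ns)
  p[match(start_state, states)] <- 1
  occ_int <- rep(0, ns)
  u <- s
  while (u < horizon - 1e-12) {
    band <- findInterval(min(u, age_breaks[length(age_breaks)] - 1e-9),
                         age_breaks)
    Q <- matrix(0, ns, ns)
    for (k in seq_len(K)) {
      Q[match(tr$from[k], states), match(tr$to[k], states)] <-
        intensities[k, band] * hr[k]
    }
    diag(Q) <- -rowSums(Q)
    step <- min(h, horizon - u, age_breaks[band + 1L] - u)
    M <- as.matrix(Matrix::expm(Q * step))
    p_new <- as.numeric(p %*% M)
    occ_int <- occ_int + step * (p + p_new) / 2
    p <- p_new
    u <- u + step
  }
  names(occ_int) <- states
  list(elos = occ_int, p_final = stats::setNames(p, states))
}

# Transition probability matrix at time t for constant intensities.
expm_P <- function(Q, t) as.matrix(Matrix::expm(Q * t))

# Convenience: a 3-state illness-death state space (subset of the canonical
# machinery) used across the simulation studies.
illness_death_space <- function() {
  state_space(states = c("work", "time_restricted_work_disability", "death"),
              absorbing = "death")
}

illness_death_config <- function(n, seed, rates = c(0.15, 0.05, 0.40, 0.10),
                                 effects = NULL, entry_range = c(50, 50),
                                 study_end = "2018-12-31",
                                 class_probs = c(manual = 0.5,
                                                 upper_non_manual = 0.5)) {
  sp <- illness_death_space()
  st <- transition_structure(sp)
  intens <- matrix(rates, nrow = st$n_transitions, ncol = 1)
  if (is.null(effects)) {
    effects <- matrix(0, st$n_transitions, 0)
  }
  sim_config(n_persons = n, seed = seed, space = sp, structure = st,
             age_breaks = c(50, 63), intensities = intens, effects = effects,
             entry_age_range = entry_range, study_end_date = study_end,
             class_probs = class_probs)
}

# Build an msm_fit by hand from explicit baseline increments, bypassing
# estimation; used for structural properties of the product integral.
fake_fit <- function(structure, baselines) {
  fits <- lapply(seq_len(structure$n_transitions), function(k) {
    b <- baselines[[k]]
    if (is.null(b)) b <- list(ages = numeric(0), dA = numeric(0))
    structure(list(transition_id = k, beta = numeric(0), se = numeric(0),
                   baseline = b, n_events = length(b$ages),
                   n_records = NA_integer_),
              class = "transition_cox")
  })
  structure(list(fits = fits, covariates = character(),
                 structure = structure), class = "msm_fit")
}

# Sojourn-level view of transition records (one row per sojourn) for the
# naive AJ oracle.
records_to_sojourns <- function(records) {
  key <- paste(records$person_id, records$from, records$entry_age)
  out <- do.call(rbind, lapply(split(records, key), function(d) {
    hit <- d$status == 1L
    data.frame(entry = d$entry_age[1], exit = d$exit_age[1],
               from = d$from[1],
               to = if (any(hit)) d$to[hit] else NA_character_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
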