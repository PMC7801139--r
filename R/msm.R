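#' Expand state trajectories into competing-risks transition records
#'
#' Each sojourn of a person in a non-absorbing state becomes one record per
#' allowed outgoing transition (long-format counting-process data): entry age
#' at the sojourn start, exit age at the state change or censoring, and
#' status 1 only for the transition that actually occurred. Ages are
#' fractional years (days / 365.25) on the age time axis, giving delayed
#' entry at the person's entry age; exit ages are capped at `max_age`.
#'
#' @param traj a `trajectory_set` (or any list with `intervals` and
#'   `followup` as produced by [assign_trajectories()] or the simulator).
#' @param persons persons data.frame with `person_id` and `entry_age`.
#' @param structure a `transition_structure`.
#' @param max_age administrative censoring age (default 63).
#' @return data.frame: person_id, transition_id, from, to, entry_age,
#'   exit_age, status.
#' @export
to_transition_records <- function(traj, persons, structure, max_age = 63) {
  iv <- traj$intervals
  iv <- iv[order(iv$person_id, iv$start_date), , drop = FALSE]
  entry_age <- persons$entry_age[match(iv$person_id, persons$person_id)]
  entry_date <- traj$followup$entry_date[match(iv$person_id,
                                               traj$followup$person_id)]
  start_day <- as.integer(iv$start_date - entry_date)
  end_day <- as.integer(iv$end_date - entry_date)
  a_in <- entry_age + start_day / 365.25
  a_out <- pmin(max_age, entry_age + (end_day + 1L) / 365.25)

  n <- nrow(iv)
  nxt_same <- c(iv$person_id[-1L] == iv$person_id[-n], FALSE)
  nxt_state <- c(iv$state[-1L], NA_character_)
  nxt_state[!nxt_same] <- NA_character_

  states <- structure$space$states
  lookup <- structure$lookup
  has_exit <- states %in% structure$transitions$from
  keep <- has_exit[match(iv$state, states)]
  if (anyNA(match(iv$state, states))) stop("interval state not in state space")

  # disallowed observed transitions are a data error
  obs <- !is.na(nxt_state)
  if (any(obs)) {
    ids <- lookup[cbind(match(iv$state[obs], states),
                        match(nxt_state[obs], states))]
    if (any(ids == 0L)) {
      bad <- which(obs)[ids == 0L][1L]
      stop("disallowed transition ", iv$state[bad], " -> ", nxt_state[bad],
           " for person ", iv$person_id[bad])
    }
  }

  idx <- which(keep & a_in < a_out)
  from_i <- match(iv$state[idx], states)
  n_out <- tabulate(structure$transitions$from |> match(states),
                    nbins = length(states))[from_i]
  rec_row <- rep.int(idx, n_out)
  # transition ids for each sojourn's allowed exits, in id order
  tr_by_from <- split(structure$transitions$id,
                      match(structure$transitions$from, states))
  tid <- unlist(tr_by_from[as.character(from_i)], use.names = FALSE)
  rec <- data.frame(
    person_id = iv$person_id[rec_row],
    transition_id = tid,
    from = structure$transitions$from[tid],
    to = structure$transitions$to[tid],
    entry_age = a_in[rec_row],
    exit_age = a_out[rec_row],
    stringsAsFactors = FALSE
  )
  ev_id <- rep.int(ifelse(is.na(nxt_state[idx]), 0L,
                          lookup[cbind(from_i,
                                       match(nxt_state[idx], states))]),
                   n_out)
  rec$status <- as.integer(rec$transition_id == ev_id)
  rownames(rec) <- NULL
  rec
}

# Breslow baseline cumulative-hazard increments at beta-hat.
# entry/exit/status/lp are per-record vectors; returns list(ages, dA).
breslow_baseline <- function(entry, exit, status, lp) {
  te <- sort(unique(exit[status == 1L]))
  if (!length(te)) return(list(ages = numeric(0), dA = numeric(0)))
  w <- exp(lp)
  d <- vapply(split(rep(1L, sum(status == 1L)),
                    factor(exit[status == 1L], levels = te)), sum, 0)
  eps <- 1e-9
  n <- length(w)
  # reverse cumulative sums: sum of w over {exit >= t} and {entry >= t};
  # the risk set {entry < t <= exit} is their difference
  oe <- order(exit)
  rev_exit <- rev(cumsum(rev(w[oe])))       # rev_exit[i] = sum w, exit rank >= i
  n_less_exit <- findInterval(te - eps, exit[oe])
  W_exit_ge <- ifelse(n_less_exit >= n, 0, rev_exit[pmin(n, n_less_exit + 1L)])
  oa <- order(entry)
  rev_entry <- rev(cumsum(rev(w[oa])))
  n_less_entry <- findInterval(te - eps, entry[oa])
  W_entry_ge <- ifelse(n_less_entry >= n, 0,
                       rev_entry[pmin(n, n_less_entry + 1L)])
  S0 <- W_exit_ge - W_entry_ge
  # extreme linear predictors can make the subtraction cancel; recompute
  # those event times exactly over the risk set
  bad <- which(!is.finite(S0) | S0 <= 0 |
                 S0 < 1e-8 * pmax(W_exit_ge, W_entry_ge))
  for (i in bad) {
    S0[i] <- sum(w[entry < te[i] & exit >= te[i]])
  }
  list(ages = te, dA = as.numeric(d) / S0)
}

#' Fit a Cox model for one transition
#'
#' Maximizes the Cox partial likelihood (Breslow ties) for one transition's
#' competing-risks records with delayed entry on the age axis, then computes
#' the Breslow baseline cumulative-hazard increments at the estimate.
#' Covariate columns with no variation are dropped from estimation and their
#' coefficients fixed at 0; with zero events the fit is beta = 0 with a
#' zero baseline (reported via a message).
#'
#' @param entry,exit,status per-record entry age, exit age, event indicator.
#' @param X numeric covariate matrix (may have zero columns).
#' @param transition_id identifier stored in the result.
#' @return Object of class `transition_cox`: `beta`, `se`, `baseline`
#'   (list `ages`, `dA`), `n_events`, `n_records`, `transition_id`.
#' @export
fit_transition_cox <- function(entry, exit, status, X, transition_id = NA) {
  if (any(entry >= exit)) stop("entry_age must be < exit_age")
  p <- ncol(X)
  beta <- stats::setNames(rep(0, p), colnames(X))
  se <- stats::setNames(rep(NA_real_, p), colnames(X))
  n_events <- sum(status)
  if (n_events == 0L) {
    message("transition ", transition_id, ": no events; beta = 0, A0 = 0")
    return(structure(list(transition_id = transition_id, beta = beta,
                          se = se,
                          baseline = list(ages = numeric(0), dA = numeric(0)),
                          n_events = 0L, n_records = length(entry)),
                     class = "transition_cox"))
  }
  est <- which(apply(X, 2L, function(x) stats::var(x) > 0))
  if (p > 0L && length(est)) {
    Xe <- X[, est, drop = FALSE]
    fit <- survival::coxph(survival::Surv(entry, exit, status) ~ Xe,
                           ties = "breslow",
                           control = survival::coxph.control(iter.max = 50))
    cf <- stats::coef(fit)
    cf[is.na(cf)] <- 0
    beta[est] <- cf
    v <- diag(stats::vcov(fit))
    if (length(v) == length(est)) se[est] <- sqrt(pmax(0, v))
  }
  lp <- if (p > 0L) drop(X %*% beta) else rep(0, length(entry))
  structure(list(transition_id = transition_id, beta = beta, se = se,
                 baseline = breslow_baseline(entry, exit, status, lp),
                 n_events = n_events, n_records = length(entry)),
            class = "transition_cox")
}

#' Fit the full multistate Cox model
#'
#' Fits one transition-specific Cox model per allowed transition, all with
#' the same covariate set (the Markov assumption: only the current state,
#' age, and the covariates affect transition intensities).
#'
#' @param records transition records from [to_transition_records()].
#' @param persons persons data.frame (for the covariate design; must contain
#'   the columns [covariate_design()] needs).
#' @param structure a `transition_structure`.
#' @param covariates design-column names (`class_*`, `expo_*`), possibly
#'   empty for a fully nonparametric fit.
#' @return Object of class `msm_fit`: `fits` (list over transition ids),
#'   `covariates`, `structure`.
#' @export
fit_multistate <- function(records, persons, structure,
                           covariates = character()) {
  Z <- covariate_design(persons, covariates)
  ridx <- match(records$person_id, persons$person_id)
  if (anyNA(ridx)) stop("records reference persons missing from `persons`")
  X <- Z[ridx, , drop = FALSE]
  fits <- vector("list", structure$n_transitions)
  for (k in seq_len(structure$n_transitions)) {
    sel <- records$transition_id == k
    fits[[k]] <- fit_transition_cox(records$entry_age[sel],
                                    records$exit_age[sel],
                                    records$status[sel],
                                    X[sel, , drop = FALSE],
                                    transition_id = k)
  }
  structure(list(fits = fits, covariates = covariates,
                 structure = structure),
            class = "msm_fit")
}

#' @export
print.msm_fit <- function(x, ...) {
  cat("Multistate Cox fit:", x$structure$n_transitions, "transitions,",
      length(x$covariates), "covariate(s)\n")
  ev <- vapply(x$fits, function(f) f$n_events, 0L)
  cat("events per transition:", paste(ev, collapse = " "), "\n")
  invisible(x)
}

#' Covariate-adjusted cumulative hazard for one transition
#'
#' Scales the Breslow baseline increments by the profile's hazard ratio:
#' A(t | z) = A0(t) exp(beta'z).
#'
#' @param fit a `transition_cox`.
#' @param profile named numeric covariate vector (same names as `fit$beta`);
#'   the reference profile is all zeros.
#' @return list(ages, dA) of adjusted increments.
#' @export
adjusted_cumhaz <- function(fit, profile = NULL) {
  if (is.null(profile)) profile <- stats::setNames(rep(0, length(fit$beta)),
                                                   names(fit$beta))
  if (length(profile) != length(fit$beta) ||
      (length(profile) && !setequal(names(profile), names(fit$beta)))) {
    stop("profile does not match the fitted covariates")
  }
  hr <- if (length(fit$beta)) exp(sum(fit$beta * profile[names(fit$beta)]))
        else 1
  list(ages = fit$baseline$ages, dA = fit$baseline$dA * hr)
}

#' Aalen-Johansen transition probability matrices
#'
#' Product-integral over the pooled event-age grid of all transitions:
#' P(s, t) = prod over event ages u in (s, t] of (I + dA(u)), where the
#' off-diagonal (j,k) entry of dA(u) is the adjusted cumulative-hazard
#' increment of transition j->k at u and each diagonal entry is minus the
#' row sum of the off-diagonals. If a row's off-diagonal increments sum
#' above 1 (possible under extreme covariate profiles), they are scaled down
#' so the diagonal of I + dA stays at 0, with a message.
#'
#' @param fit an `msm_fit`.
#' @param profile named covariate profile (reference = all zeros / NULL).
#' @param s starting age (default 50).
#' @param horizon end age (default 63).
#' @return Object of class `aj_prob`: `ages` (grid, first element `s`),
#'   `P` (array states x states x length(ages), `P[, , i]` = P(s, ages[i])),
#'   `states`, `s`, `horizon`, `profile`.
#' @export
aalen_johansen <- function(fit, profile = NULL, s = 50, horizon = 63) {
  stopifnot(inherits(fit, "msm_fit"), s < horizon)
  states <- fit$structure$space$states
  ns <- length(states)
  tr <- fit$structure$transitions
  K <- nrow(tr)
  adj <- lapply(fit$fits, adjusted_cumhaz, profile = profile)
  ages_all <- unlist(lapply(adj, `[[`, "ages"), use.names = FALSE)
  grid <- sort(unique(ages_all[ages_all > s & ages_all <= horizon]))
  m <- length(grid)
  inc <- matrix(0, m, K)
  for (k in seq_len(K)) {
    a <- adj[[k]]
    in_win <- a$ages > s & a$ages <= horizon
    inc[match(a$ages[in_win], grid), k] <- a$dA[in_win]
  }
  from_i <- match(tr$from, states)
  to_i <- match(tr$to, states)
  P <- array(0, dim = c(ns, ns, m + 1L),
             dimnames = list(states, states, NULL))
  cur <- diag(ns)
  P[, , 1L] <- cur
  capped <- FALSE
  Amat <- matrix(0, ns, ns)
  ij <- cbind(from_i, to_i)
  for (i in seq_len(m)) {
    Amat[] <- 0
    Amat[ij] <- inc[i, ]
    rs <- rowSums(Amat)
    over <- rs > 1
    if (any(over)) {
      capped <- TRUE
      Amat[over, ] <- Amat[over, , drop = FALSE] / rs[over]
      rs[over] <- 1
    }
    diag(Amat) <- diag(Amat) - rs
    cur <- cur %*% (diag(ns) + Amat)
    P[, , i + 1L] <- cur
  }
  if (capped) {
    message("hazard increments capped to keep 1 + dA_jj >= 0 on some ages")
  }
  structure(list(ages = c(s, grid), P = P, states = states, s = s,
                 horizon = horizon, profile = profile),
            class = "aj_prob")
}

#' Extract P(s, t) from an `aj_prob`
#' @param aj an `aj_prob`.
#' @param t age (defaults to the horizon).
#' @return states x states transition probability matrix.
#' @export
transition_probability <- function(aj, t = aj$horizon) {
  if (t < aj$s || t > aj$horizon) stop("t outside [s, horizon]")
  i <- findInterval(t + 1e-12, aj$ages)
  aj$P[, , i]
}
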