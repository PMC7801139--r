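#' Canonical labor-market state labels
#'
#' The seven daily labor-market states used throughout the package, in the
#' canonical order that fixes transition numbering: work, time-restricted work
#' disability, unemployment, economic inactivity, disability retirement,
#' retirement, and death.
#'
#' @return Character vector of length 7.
#' @export
worklife_states <- function() {
  c("work", "time_restricted_work_disability", "unemployment",
    "economic_inactivity", "disability_retirement", "retirement", "death")
}

#' Construct a multistate state space
#'
#' A state space is the ordered set of state labels together with a 0/1
#' matrix of allowed instantaneous transitions. By default every ordered pair
#' of distinct states is allowed, minus exits from absorbing states, minus any
#' exits not listed in `restricted` for states appearing there.
#'
#' @param states character vector of state labels (unique, length >= 2).
#' @param absorbing character vector of absorbing states (no exits).
#' @param restricted named list: for each named state, the only destinations
#'   it may move to. States not named (and not absorbing) may move anywhere.
#' @return An object of class `state_space`: list with `states`, `absorbing`,
#'   and `allowed` (0/1 matrix with dimnames).
#' @examples
#' sp <- canonical_state_space()
#' sum(sp$allowed)  # 27
#' @export
state_space <- function(states, absorbing = character(),
                        restricted = list()) {
  if (anyDuplicated(states)) stop("duplicate state labels")
  if (length(states) < 2L) stop("need at least two states")
  bad <- setdiff(c(absorbing, names(restricted), unlist(restricted)), states)
  if (length(bad)) {
    stop("unknown state label(s): ", paste(unique(bad), collapse = ", "))
  }
  n <- length(states)
  allowed <- matrix(1L, n, n, dimnames = list(from = states, to = states))
  diag(allowed) <- 0L
  allowed[states %in% absorbing, ] <- 0L
  for (s in names(restricted)) {
    allowed[s, ] <- 0L
    allowed[s, restricted[[s]]] <- 1L
  }
  structure(list(states = states, absorbing = absorbing, allowed = allowed),
            class = "state_space")
}

#' The canonical seven-state labor-market state space
#'
#' Death is absorbing; retirement may only move to death; disability
#' retirement may only move to retirement or death; each of the four active
#' states (work, time-restricted work disability, unemployment, economic
#' inactivity) may move to any of the other six states. This yields 27
#' allowed transitions.
#'
#' @return A `state_space` object.
#' @export
canonical_state_space <- function() {
  state_space(
    states = worklife_states(),
    absorbing = "death",
    restricted = list(
      retirement = "death",
      disability_retirement = c("retirement", "death")
    )
  )
}

#' Enumerate the allowed transitions of a state space
#'
#' Transitions are numbered row-major: by from-state in the order of
#' `space$states`, then by to-state in the same order. The numbering is a
#' bijection 1..K and is stable across runs.
#'
#' @param space a `state_space`.
#' @return An object of class `transition_structure`: list with `transitions`
#'   (data.frame `id`, `from`, `to`), `n_transitions`, `space`, and `lookup`
#'   (matrix mapping from,to -> id, 0 where disallowed).
#' @examples
#' ts <- transition_structure(canonical_state_space())
#' ts$n_transitions  # 27
#' @export
transition_structure <- function(space) {
  if (!inherits(space, "state_space")) stop("`space` must be a state_space")
  idx <- which(t(space$allowed) == 1L)  # t() => row-major order
  n <- length(space$states)
  from_i <- (idx - 1L) %/% n + 1L
  to_i <- (idx - 1L) %% n + 1L
  transitions <- data.frame(
    id = seq_along(idx),
    from = space$states[from_i],
    to = space$states[to_i],
    stringsAsFactors = FALSE
  )
  lookup <- matrix(0L, n, n,
                   dimnames = list(from = space$states, to = space$states))
  lookup[cbind(from_i, to_i)] <- transitions$id
  structure(list(transitions = transitions, n_transitions = nrow(transitions),
                 space = space, lookup = lookup),
            class = "transition_structure")
}

#' @export
print.transition_structure <- function(x, ...) {
  cat("Transition structure:", length(x$space$states), "states,",
      x$n_transitions, "transitions\n")
  print(x$transitions, row.names = FALSE)
  invisible(x)
}

#' Export / import a transition matrix as JSON
#'
#' Writes the allowed-transition 0/1 matrix (with state labels) so the
#' structure can be audited or reused outside R; `read_transition_matrix`
#' reconstructs the `state_space`.
#'
#' @param space a `state_space`.
#' @param path file path for the JSON matrix.
#' @return `write_transition_matrix` returns `path` invisibly;
#'   `read_transition_matrix` returns a `state_space`.
#' @export
write_transition_matrix <- function(space, path) {
  jsonlite::write_json(
    list(states = space$states, absorbing = space$absorbing,
         allowed = unname(apply(space$allowed, 1L, identity, simplify = FALSE))),
    path, auto_unbox = FALSE, digits = NA
  )
  invisible(path)
}

#' @rdname write_transition_matrix
#' @export
read_transition_matrix <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- do.call(rbind, lapply(seq_along(x$states), function(i) {
    as.integer(x$allowed[i, ])
  }))
  dimnames(allowed) <- list(from = x$states, to = x$states)
  sp <- structure(list(states = x$states,
                       absorbing = as.character(x$absorbing),
                       allowed = allowed),
                  class = "state_space")
  sp
}
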