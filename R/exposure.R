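#' Physical workload factor names
#' @return Character vector of the five JEM factor columns.
#' @export
workload_factors <- function() {
  c("heavy_physical_work", "kneeling_squatting",
    "manual_handling_heavy_loads", "hands_above_shoulder",
    "awkward_trunk_posture")
}

#' Dichotomize a JEM exposure probability
#'
#' A job-exposure-matrix value (probability of exposure, 0-1) is classified
#' as exposed when it is at or above the threshold, non-exposed below it.
#' The default threshold is 0.40.
#'
#' @param jem_value numeric vector of probabilities in [0, 1].
#' @param threshold dichotomization cut point.
#' @return logical vector: `TRUE` = exposed.
#' @examples
#' dichotomize(c(0.39, 0.40, 0.41))  # FALSE TRUE TRUE
#' @export
dichotomize <- function(jem_value, threshold = 0.40) {
  if (any(is.na(jem_value)) || any(jem_value < 0) || any(jem_value > 1)) {
    stop("JEM values must be probabilities in [0, 1]")
  }
  jem_value >= threshold
}

#' Exposure profile for one occupation code and gender
#'
#' Looks up the five workload-factor probabilities, dichotomizes each, counts
#' the exposed factors, and maps the count to the exposure category:
#' 0 -> `none`, 1-3 -> `one_to_three`, 4-5 -> `four_to_five`.
#'
#' @param jem JEM data.frame (columns `occupation_code`, `gender`, and the
#'   five factor columns).
#' @param occupation_code,gender lookup key.
#' @param threshold dichotomization cut point.
#' @return list with `flags` (named logical, 5), `n_exposed`, `category`.
#' @export
exposure_profile <- function(jem, occupation_code, gender, threshold = 0.40) {
  row <- jem[jem$occupation_code == occupation_code & jem$gender == gender, ,
             drop = FALSE]
  if (nrow(row) == 0L) {
    stop("no JEM row for occupation_code=", occupation_code,
         " gender=", gender)
  }
  if (nrow(row) > 1L) stop("duplicate JEM key")
  vals <- as.numeric(row[1, workload_factors()])
  flags <- dichotomize(vals, threshold)
  names(flags) <- workload_factors()
  n <- sum(flags)
  list(flags = flags, n_exposed = n, category = exposure_category(n))
}

#' @rdname exposure_profile
#' @param n_exposed integer count of exposed factors (0-5).
#' @export
exposure_category <- function(n_exposed) {
  stopifnot(all(n_exposed %in% 0:5))
  c("none", rep("one_to_three", 3), rep("four_to_five", 2))[n_exposed + 1L]
}

#' Append JEM exposure covariates to a persons table
#'
#' Joins each person's occupation code and gender against the JEM,
#' dichotomizes the five factors at `threshold`, and appends per-factor
#' exposed flags, the exposed-factor count, and the exposure category.
#' Persons whose (occupation_code, gender) key is missing from the JEM are
#' excluded, with a message reporting the count; the excluded rows are kept
#' in the `"excluded"` attribute of the result.
#'
#' @param persons data.frame with `occupation_code` and `gender`.
#' @param jem JEM data.frame.
#' @param threshold dichotomization cut point (default 0.40).
#' @return `persons` with columns `exposed_<factor>` (5), `n_exposed`,
#'   `exposure_category`; attribute `"excluded"` holds dropped rows.
#' @export
add_exposure <- function(persons, jem, threshold = 0.40) {
  key <- paste(persons$occupation_code, persons$gender)
  jkey <- paste(jem$occupation_code, jem$gender)
  if (anyDuplicated(jkey)) stop("duplicate JEM keys")
  idx <- match(key, jkey)
  missing <- is.na(idx)
  if (any(missing)) {
    message(sum(missing), " person(s) excluded: occupation code missing ",
            "from the JEM")
  }
  excluded <- persons[missing, , drop = FALSE]
  persons <- persons[!missing, , drop = FALSE]
  idx <- idx[!missing]
  vals <- as.matrix(jem[idx, workload_factors(), drop = FALSE])
  flags <- matrix(dichotomize(as.numeric(vals), threshold), nrow = nrow(vals))
  colnames(flags) <- paste0("exposed_", workload_factors())
  persons <- cbind(persons, as.data.frame(flags))
  persons$n_exposed <- as.integer(rowSums(flags))
  persons$exposure_category <- exposure_category(persons$n_exposed)
  rownames(persons) <- NULL
  attr(persons, "excluded") <- excluded
  persons
}
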