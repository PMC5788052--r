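#' Feature spaces for continuous-report experiments
#'
#' A feature space describes the circular response dimension of an experiment:
#' its name and its period in native degrees (360 for a colour wheel or motion
#' direction, 180 for orientation). Internally all angles are represented in
#' radians on `[-pi, pi)` with one full period mapped onto the circle, so
#' orientation data are "doubled" into the internal space; summaries are
#' converted back to native degrees for reporting.
#'
#' @param name Label for the feature dimension (e.g. `"color"`).
#' @param period_degrees Positive period of the response space in degrees.
#' @return An object of class `feature_space`.
#' @examples
#' sp <- feature_space("orientation", 180)
#' to_internal(90, sp)     # wraps to -pi
#' @export
feature_space <- function(name, period_degrees) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(period_degrees) || length(period_degrees) != 1L ||
      !is.finite(period_degrees) || period_degrees <= 0) {
    abort("`period_degrees` must be a single positive number.")
  }
  structure(list(name = name, period_degrees = period_degrees),
            class = "feature_space")
}

#' @export
print.feature_space <- function(x, ...) {
  cat(sprintf("<feature_space> %s (period %g deg)\n", x$name, x$period_degrees))
  invisible(x)
}

#' Convert native degrees to internal radians
#'
#' Scales values so that one feature period spans `2*pi`, then wraps to
#' `[-pi, pi)`.
#'
#' @param value Numeric vector in native degrees.
#' @param space A [feature_space()].
#' @return Angles in internal radians.
#' @export
to_internal <- function(value, space) {
  stopifnot(inherits(space, "feature_space"))
  wrap_angle(value * 2 * pi / space$period_degrees)
}

#' Convert internal radians back to native degrees
#'
#' Inverse of [to_internal()] up to wrapping; results lie in
#' `[-period/2, period/2)`.
#'
#' @inheritParams to_internal
#' @param value Numeric vector in internal radians.
#' @return Values in native degrees.
#' @export
from_internal <- function(value, space) {
  stopifnot(inherits(space, "feature_space"))
  wrap_angle(value) * space$period_degrees / (2 * pi)
}

#' Read a feature-space configuration
#'
#' Experiments in a collated trial table may report different feature
#' dimensions. A space configuration maps each experiment label to a feature
#' space. It can be given as a YAML file (`experiment: period`, or
#' `experiment: {name: ..., period_degrees: ...}`), a named numeric vector of
#' periods, or a data frame with columns `experiment` and `period_degrees`.
#'
#' @param config Path to a YAML file, a named numeric vector, or a data frame.
#' @return A named list of [feature_space()] objects keyed by experiment.
#' @export
read_space_config <- function(config) {
  if (is.character(config) && length(config) == 1L && file.exists(config)) {
    config <- yaml::read_yaml(config)
  }
  if (is.data.frame(config)) {
    stopifnot(all(c("experiment", "period_degrees") %in% names(config)))
    config <- setNames(as.list(config$period_degrees), config$experiment)
  }
  if (is.numeric(config) && !is.null(names(config))) config <- as.list(config)
  if (!is.list(config) || is.null(names(config)) || any(names(config) == "")) {
    abort("space config must map experiment labels to feature spaces.")
  }
  purrr::imap(config, function(v, nm) {
    if (inherits(v, "feature_space")) return(v)
    if (is.list(v)) return(feature_space(v$name %||% nm, v$period_degrees))
    feature_space(nm, as.numeric(v))
  })
}
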