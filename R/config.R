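#' Pipeline configuration
#'
#' Returns the full set of tunable analysis parameters with their defaults,
#' optionally overridden. All feature-extraction and comparison functions
#' accept such a list via their \code{config} argument.
#'
#' @param ... named overrides of the defaults listed below.
#' @return a named list of class \code{armswing_config}:
#' \describe{
#'   \item{trim_head_s, trim_tail_s}{seconds removed from the start/end of
#'     each trial before analysis (default 1 and 1), discarding the
#'     gait-initiation and stopping transients so features describe
#'     steady-state swing.}
#'   \item{sensor_separation_m}{distance between the two wrist sensors
#'     (default 0.1 m).}
#'   \item{trial_aggregation}{\code{"median"} (default) or \code{"mean"}:
#'     how per-trial features are collapsed to one value per subject/arm.}
#'   \item{offset_removal_target}{\code{"magnitude"} (default) or
#'     \code{"per_axis"}: whether the mean offset is removed from the
#'     angular-acceleration magnitude signal or from each axis before the
#'     magnitude is taken.}
#'   \item{cycle_bounds_s}{lag window (s) searched for the full-cycle
#'     autocorrelation peak (default \code{c(0.6, 2)}).}
#'   \item{a_window_fraction}{fractions of the cycle-peak lag searched for the
#'     half-cycle peak (default \code{c(0.25, 0.75)}).}
#'   \item{band_edges_hz}{energy band edges (default \code{c(0, 2.5, 5, 10)}).}
#'   \item{spectral_window}{\code{"rect"} (default) or \code{"hann"}.}
#'   \item{component_measure}{\code{"amplitude"} (default) or \code{"power"}:
#'     whether band energies sum spectral amplitudes or their squares.}
#'   \item{wavelet_levels}{detail levels of the db4 decomposition (default 5).}
#'   \item{variance_target}{\code{"coefficients"} (default) or
#'     \code{"reconstructed"}: what the per-level variance is computed over.}
#'   \item{alpha}{significance level for normality gating and group tests
#'     (default 0.05).}
#'   \item{exact_test_max_n}{largest combined sample size for which the
#'     Mann-Whitney U test is computed exactly (default 25).}
#'   \item{control_side_convention}{\code{"right_dominant"} (default),
#'     \code{"left_dominant"} or \code{"random"}: how the arms of controls and
#'     clinically symmetric patients are assigned to the LAS/MAS columns.}
#'   \item{multiple_testing}{\code{"none"} (default) or \code{"holm"}.}
#' }
#' @examples
#' cfg <- armswingConfig(trim_head_s = 0.5, spectral_window = "hann")
#' cfg$band_edges_hz
#' @export
armswingConfig <- function(...) {
  cfg <- list(
    trim_head_s = 1,
    trim_tail_s = 1,
    sensor_separation_m = 0.1,
    trial_aggregation = "median",
    offset_removal_target = "magnitude",
    cycle_bounds_s = c(0.6, 2.0),
    a_window_fraction = c(0.25, 0.75),
    band_edges_hz = c(0, 2.5, 5, 10),
    spectral_window = "rect",
    component_measure = "amplitude",
    wavelet_levels = 5L,
    variance_target = "coefficients",
    alpha = 0.05,
    exact_test_max_n = 25L,
    control_side_convention = "right_dominant",
    multiple_testing = "none"
  )
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(!nzchar(names(over))))
      stop("configuration overrides must be named")
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    cfg <- modifyList(cfg, over)
  }
  stopifnot(
    cfg$trial_aggregation %in% c("median", "mean"),
    cfg$offset_removal_target %in% c("magnitude", "per_axis"),
    cfg$spectral_window %in% c("rect", "hann"),
    cfg$component_measure %in% c("amplitude", "power"),
    cfg$variance_target %in% c("coefficients", "reconstructed"),
    cfg$control_side_convention %in%
      c("right_dominant", "left_dominant", "random"),
    cfg$multiple_testing %in% c("none", "holm"),
    length(cfg$band_edges_hz) >= 2, !is.unsorted(cfg$band_edges_hz),
    cfg$alpha > 0, cfg$alpha < 1
  )
  structure(cfg, class = "armswing_config")
}

#' Read a configuration file
#'
#' Reads a YAML file of configuration keys (see [armswingConfig()]) and merges
#' it over the defaults.
#'
#' @param path path to a YAML file.
#' @return an \code{armswing_config} list.
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) return(armswingConfig())
  do.call(armswingConfig, vals)
}
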