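#' Extract per-arm features for one subject
#'
#' Runs all four feature-extraction techniques on every trial of a subject's
#' session and aggregates per-trial values to one value per arm (median over
#' trials by default):
#' \enumerate{
#'   \item RMS of the angular-acceleration magnitude (dual-sensor difference,
#'     magnitude, offset removal, RMS - in that order), and the ASA index
#'     from the two arms' RMS within each trial present for both arms;
#'   \item half-cycle (posterior-anterior phase) and full-cycle regularity
#'     from the unbiased autocorrelation of the wrist Y axis;
#'   \item low/mid/high/total spectral band energies of the wrist sensor;
#'   \item per-axis fractal dimension via the db4 wavelet variance slope.
#' }
#' Trials on which a technique fails (no autocorrelation peak in the search
#' window, degenerate wavelet decomposition) are excluded from that variable's
#' aggregate with a warning; the remaining trials still contribute.
#'
#' @param session a [SubjectSession-class].
#' @param config an [armswingConfig()] list.
#' @return named numeric vector with per-arm entries
#'   (\code{left_rms, right_rms, left_phase_regularity, ...,
#'   left_dx, ..., right_dz}) plus \code{asa}.
#' @export
extractFeatures <- function(session, config = armswingConfig()) {
  stopifnot(is(session, "SubjectSession"))
  recs <- lapply(recordings(session), trimSteadyState,
                 head_s = config$trim_head_s, tail_s = config$trim_tail_s)
  arms <- vapply(recs, arm, character(1))
  trials <- vapply(recs, trialIndex, integer(1))
  agg <- function(x) {
    x <- x[is.finite(x)]
    if (!length(x)) return(NA_real_)
    if (config$trial_aggregation == "median") median(x) else mean(x)
  }

  per_trial <- lapply(recs, function(rec) {
    out <- c(rms = NA_real_, phase_regularity = NA_real_,
             cycle_regularity = NA_real_,
             low_energy = NA_real_, mid_energy = NA_real_,
             high_energy = NA_real_, total_energy = NA_real_,
             dx = NA_real_, dy = NA_real_, dz = NA_real_)
    # Technique A: angular acceleration -> magnitude -> offset removal -> RMS
    alpha <- angularAcceleration(rec)
    if (config$offset_removal_target == "per_axis")
      alpha[] <- removeOffset(alpha)
    out["rms"] <- rmsAmplitude(removeOffset(accelMagnitude(alpha)))
    # Technique B: Y-axis autocorrelation regularity
    y <- removeOffset(rec@channels[, "ay_low"])
    pk <- tryCatch({
      r <- unbiasedAutocorrelation(y)
      regularityPeaks(r, sampleRate(rec),
                      cycle_bounds_s = config$cycle_bounds_s,
                      a_window_fraction = config$a_window_fraction)
    }, error = function(e) list(found = FALSE))
    if (isTRUE(pk$found)) {
      out["phase_regularity"] <- pk$peak_a_amplitude
      out["cycle_regularity"] <- pk$peak_b_amplitude
    } else {
      warning(sprintf("subject %s, %s arm, trial %d: no regularity peaks in search window; trial excluded from regularity variables",
                      subjectId(rec), arm(rec), trialIndex(rec)))
    }
    # Technique C: band energies
    be <- trialBandEnergies(rec, band_edges_hz = config$band_edges_hz,
                            window = config$spectral_window,
                            measure = config$component_measure)
    out["low_energy"] <- be[["low"]]
    out["mid_energy"] <- be[["mid"]]
    out["high_energy"] <- be[["high"]]
    out["total_energy"] <- be[["total"]]
    # Technique D: per-axis fractal dimension
    fd <- tryCatch(
      trialFractalDimensions(rec, levels = config$wavelet_levels,
                             variance_target = config$variance_target),
      error = function(e) {
        warning(sprintf("subject %s, %s arm, trial %d: %s; trial excluded from fractal variables",
                        subjectId(rec), arm(rec), trialIndex(rec),
                        conditionMessage(e)))
        NULL
      })
    if (!is.null(fd)) {
      out["dx"] <- fd$x$dimension
      out["dy"] <- fd$y$dimension
      out["dz"] <- fd$z$dimension
    }
    out
  })
  per_trial <- do.call(rbind, per_trial)

  feats <- c()
  for (a in c("left", "right")) {
    sel <- arms == a
    vals <- if (any(sel)) apply(per_trial[sel, , drop = FALSE], 2L, agg)
            else rep(NA_real_, ncol(per_trial))
    names(vals) <- paste0(a, "_", colnames(per_trial))
    feats <- c(feats, vals)
  }

  # ASA per trial over trials present for both arms
  paired <- intersect(trials[arms == "left"], trials[arms == "right"])
  asa_trials <- vapply(paired, function(tr) {
    armSwingAsymmetry(per_trial[which(arms == "left" & trials == tr)[1], "rms"],
                      per_trial[which(arms == "right" & trials == tr)[1], "rms"])
  }, numeric(1))
  feats["asa"] <- agg(asa_trials)
  feats
}

#' Relabel per-arm features to LAS/MAS columns
#'
#' Patients' arms are renamed by the clinically most affected side: the
#' affected arm's features become the MAS (most affected side) columns, the
#' other arm's the LAS columns. Controls - and patients scored as
#' symmetric - carry no such label, so a feature-independent convention
#' assigns their arms: by default the dominant (right) arm maps to the LAS
#' analogue; \code{"random"} draws the mapping from the current RNG stream.
#'
#' @param features named vector from [extractFeatures()].
#' @param affected_side \code{"left"}, \code{"right"}, \code{"symmetric"} or
#'   \code{"none"}.
#' @param convention mapping rule for unlabeled subjects (see
#'   [armswingConfig()]'s \code{control_side_convention}).
#' @return named numeric vector over [armSwingVariables()].
#' @export
relabelLasMas <- function(features, affected_side,
                          convention = "right_dominant") {
  stopifnot(affected_side %in% c("left", "right", "symmetric", "none"))
  mas_arm <- switch(affected_side,
    left = "left", right = "right",
    switch(convention,
           right_dominant = "left",   # dominant right arm -> LAS analogue
           left_dominant = "right",
           random = sample(c("left", "right"), 1L),
           stop("unknown control side convention: ", convention)))
  las_arm <- setdiff(c("left", "right"), mas_arm)
  vars <- armSwingVariables()
  base <- sub("_(las|mas)$", "", vars)
  side <- ifelse(grepl("_mas$", vars), mas_arm,
                 ifelse(grepl("_las$", vars), las_arm, NA))
  out <- vapply(seq_along(vars), function(i) {
    if (vars[i] == "asa") return(unname(features[["asa"]]))
    unname(features[[paste0(side[i], "_", base[i])]])
  }, numeric(1))
  names(out) <- vars
  out
}

#' Build a cohort table from subject sessions
#'
#' Extracts features for every session, relabels arms to LAS/MAS and
#' assembles the [CohortTable-class] used by [compareCohort()].
#'
#' @param sessions list of [SubjectSession-class] objects.
#' @param config an [armswingConfig()] list.
#' @return a [CohortTable-class] (features x subjects).
#' @export
buildCohort <- function(sessions, config = armswingConfig()) {
  stopifnot(length(sessions) > 0L)
  cols <- lapply(sessions, function(s)
    relabelLasMas(extractFeatures(s, config), affectedSide(s),
                  convention = config$control_side_convention))
  m <- do.call(cbind, cols)
  colnames(m) <- vapply(sessions, subjectId, character(1))
  subjects <- data.frame(
    subject_id = colnames(m),
    group = vapply(sessions, groupLabel, character(1)),
    affected_side = vapply(sessions, affectedSide, character(1)))
  newCohortTable(m, subjects)
}
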