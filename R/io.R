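#' Canonical arm swing variables
#'
#' The per-subject variables produced by the four feature-extraction
#' techniques after LAS/MAS relabeling, in their canonical reporting order.
#'
#' @param display if \code{TRUE}, return the human-readable column names used
#'   in written feature tables and reports; otherwise the internal
#'   snake_case identifiers.
#' @return character vector of 21 variable names.
#' @examples
#' armSwingVariables()
#' armSwingVariables(display = TRUE)
#' @export
armSwingVariables <- function(display = FALSE) {
  internal <- c(
    "rms_las", "rms_mas", "asa",
    "phase_regularity_las", "phase_regularity_mas",
    "cycle_regularity_las", "cycle_regularity_mas",
    "low_energy_las", "mid_energy_las", "high_energy_las", "total_energy_las",
    "low_energy_mas", "mid_energy_mas", "high_energy_mas", "total_energy_mas",
    "dx_las", "dx_mas", "dy_las", "dy_mas", "dz_las", "dz_mas"
  )
  if (!display) return(internal)
  c("RMS LAS", "RMS MAS", "ASA of RMS",
    "Posterior-anterior phase regularity LAS",
    "Posterior-anterior phase regularity MAS",
    "Arm swing cycle regularity LAS", "Arm swing cycle regularity MAS",
    "Low Energy LAS", "Mid Energy LAS", "High Energy LAS", "Total Energy LAS",
    "Low Energy MAS", "Mid Energy MAS", "High Energy MAS", "Total Energy MAS",
    "Dx LAS", "Dx MAS", "Dy LAS", "Dy MAS", "Dz LAS", "Dz MAS")
}

#' Read a wristband recording CSV
#'
#' Reads one (subject, arm, trial) recording in the flat-file dialect written
#' by [writeRecording()]: a header block of \code{# key: value} lines
#' (subject_id, arm, trial, sample_rate_hz, sensor_separation_m) followed by a
#' CSV table whose columns are the six channels
#' \code{ax_low, ay_low, az_low, ax_high, ay_high, az_high} in g.
#'
#' @param path path to the CSV file.
#' @return a validated [WristRecording-class].
#' @seealso [writeRecording()]
#' @export
readRecording <- function(path) {
  if (!file.exists(path)) stop("recording file not found: ", path)
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  header_end <- match(FALSE, is_meta, nomatch = length(lines) + 1L) - 1L
  meta <- list()
  for (ln in lines[seq_len(header_end)]) {
    kv <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(kv) == 3L) meta[[trimws(kv[2])]] <- trimws(kv[3])
  }
  need <- c("subject_id", "arm", "trial", "sample_rate_hz")
  missing_keys <- setdiff(need, names(meta))
  if (length(missing_keys))
    stop("recording header lacks key(s): ", paste(missing_keys, collapse = ", "))
  body <- lines[(header_end + 1L):length(lines)]
  tab <- tryCatch(
    read.csv(text = paste(body, collapse = "\n"), colClasses = "character"),
    error = function(e) stop("cannot parse recording table: ",
                             conditionMessage(e)))
  missing_ch <- setdiff(CHANNEL_NAMES, colnames(tab))
  if (length(missing_ch))
    stop("recording is missing channel(s): ",
         paste(missing_ch, collapse = ", "))
  ch <- matrix(NA_real_, nrow(tab), 6L, dimnames = list(NULL, CHANNEL_NAMES))
  for (cn in CHANNEL_NAMES) {
    v <- suppressWarnings(as.numeric(tab[[cn]]))
    bad <- which(is.na(v) & !is.na(tab[[cn]]))
    if (length(bad))
      stop(sprintf("non-numeric value in channel '%s' at data row %d: \"%s\"",
                   cn, bad[1], tab[[cn]][bad[1]]))
    if (anyNA(v))
      stop(sprintf("missing value in channel '%s' at data row %d",
                   cn, which(is.na(v))[1]))
    ch[, cn] <- v
  }
  WristRecording(
    subjectId = meta$subject_id, arm = meta$arm,
    trial = as.integer(meta$trial), channels = ch,
    sampleRate = as.numeric(meta$sample_rate_hz),
    sensorSeparation = as.numeric(meta$sensor_separation_m %||% 0.1))
}

#' Write a wristband recording CSV
#'
#' Writes the dialect read by [readRecording()]. Samples are serialized at
#' full double precision so a write/read round trip is bit-exact.
#'
#' @param rec a [WristRecording-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeRecording <- function(rec, path) {
  stopifnot(is(rec, "WristRecording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s",
                     c("subject_id", "arm", "trial", "sample_rate_hz",
                       "sensor_separation_m"),
                     c(rec@subjectId, rec@arm, rec@trial,
                       format(rec@sampleRate, digits = 17),
                       format(rec@sensorSeparation, digits = 17))), con)
  writeLines(paste(CHANNEL_NAMES, collapse = ","), con)
  body <- apply(rec@channels, 1L, function(r)
    paste(formatC(r, digits = 17, format = "g"), collapse = ","))
  writeLines(body, con)
  invisible(path)
}

#' Write a cohort feature table
#'
#' One row per subject; feature columns carry the human-readable variable
#' names (see \code{armSwingVariables(display = TRUE)}) preceded by
#' \code{subject_id}, \code{group} and \code{affected_side}.
#'
#' @param cohort a [CohortTable-class].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @seealso [readFeatureTable()]
#' @export
writeFeatureTable <- function(cohort, path) {
  stopifnot(is(cohort, "CohortTable"))
  if (ncol(cohort) == 0L) stop("cohort is empty; nothing to write")
  m <- t(assay(cohort, "features"))
  colnames(m) <- armSwingVariables(display = TRUE)
  cd <- colData(cohort)
  df <- data.frame(subject_id = cd$subject_id, group = cd$group,
                   affected_side = cd$affected_side, check.names = FALSE)
  df <- cbind(df, as.data.frame(m, check.names = FALSE))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort feature table
#'
#' Reads a CSV written by [writeFeatureTable()] back into a
#' [CohortTable-class].
#'
#' @param path path to the feature table CSV.
#' @return a [CohortTable-class].
#' @export
readFeatureTable <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  df <- read.csv(path, check.names = FALSE)
  disp <- armSwingVariables(display = TRUE)
  missing_cols <- setdiff(c("subject_id", "group", "affected_side", disp),
                          colnames(df))
  if (length(missing_cols))
    stop("feature table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  m <- t(as.matrix(df[, disp, drop = FALSE]))
  rownames(m) <- armSwingVariables()
  colnames(m) <- df$subject_id
  newCohortTable(m, data.frame(subject_id = df$subject_id, group = df$group,
                               affected_side = df$affected_side))
}

# internal: assemble a CohortTable from a features matrix + subject data.frame
newCohortTable <- function(features, subjects) {
  se <- SummarizedExperiment(
    assays = list(features = features),
    colData = S4Vectors::DataFrame(subjects, row.names = subjects$subject_id))
  new("CohortTable", se)
}

#' Read or write a session manifest
#'
#' The manifest lists every recording file of a study directory with its
#' subject, group, affected side, arm and trial, making session assembly
#' explicit rather than encoded in file names.
#'
#' @param path manifest CSV path.
#' @return for \code{readManifest}, a data.frame with columns
#'   \code{subject_id}, \code{group}, \code{affected_side}, \code{arm},
#'   \code{trial}, \code{file}.
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- read.csv(path, colClasses = c(trial = "integer"))
  need <- c("subject_id", "group", "affected_side", "arm", "trial", "file")
  missing_cols <- setdiff(need, colnames(df))
  if (length(missing_cols))
    stop("manifest lacks column(s): ", paste(missing_cols, collapse = ", "))
  df
}

#' @rdname readManifest
#' @param manifest data.frame in the manifest schema.
#' @export
writeManifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Assemble SubjectSessions from a manifest
#'
#' Reads every recording listed in a manifest and groups them into one
#' [SubjectSession-class] per subject. Listed files that are absent on disk
#' are skipped with a warning, so features fall back to the remaining trials.
#'
#' @param manifest data.frame as returned by [readManifest()].
#' @param dir directory that relative \code{file} entries are resolved
#'   against.
#' @return named list of [SubjectSession-class] objects.
#' @export
sessionsFromManifest <- function(manifest, dir = ".") {
  split_rows <- split(seq_len(nrow(manifest)), manifest$subject_id)
  lapply(split_rows, function(idx) {
    rows <- manifest[idx, , drop = FALSE]
    recs <- list()
    for (i in seq_len(nrow(rows))) {
      f <- rows$file[i]
      if (!file.exists(f)) f <- file.path(dir, rows$file[i])
      if (!file.exists(f)) {
        warning(sprintf("recording file missing, trial skipped: %s (subject %s, %s arm, trial %d)",
                        rows$file[i], rows$subject_id[i], rows$arm[i],
                        rows$trial[i]))
        next
      }
      recs[[length(recs) + 1L]] <- readRecording(f)
    }
    SubjectSession(rows$subject_id[1], rows$group[1], recs,
                   affectedSide = rows$affected_side[1])
  })
}
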