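#' Shapiro-Wilk normality p-value
#'
#' Thin wrapper over \code{stats::shapiro.test} with the sample-size guard
#' appropriate for small clinical cohorts.
#'
#' @param x numeric sample with 3 to 50 observations.
#' @return the Shapiro-Wilk p-value.
#' @export
shapiroNormality <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L || n > 50L)
    stop("Shapiro-Wilk gate requires 3 <= n <= 50 (got ", n, ")")
  if (var(x) == 0)
    stop("constant sample: normality test is degenerate")
  shapiro.test(x)$p.value
}

# Welch-variance two-sample Z test (normal theory), two-sided
welchZTest <- function(a, b) {
  z <- (mean(b) - mean(a)) /
    sqrt(var(a) / length(a) + var(b) / length(b))
  list(statistic = z, p_value = 2 * pnorm(-abs(z)))
}

# classical Cohen's d with pooled SD, oriented patient minus control
cohensD <- function(control, patient) {
  n1 <- length(control); n2 <- length(patient)
  sp <- sqrt(((n1 - 1) * var(control) + (n2 - 1) * var(patient)) /
               (n1 + n2 - 2))
  if (sp == 0) return(NA_real_)
  (mean(patient) - mean(control)) / sp
}

#' Compare one arm swing variable between groups
#'
#' Gate on normality, then test: if both samples pass the Shapiro-Wilk test
#' at \code{alpha}, a two-sample Z test (normal theory, Welch variance) is
#' used; otherwise the Mann-Whitney U test (exact when the combined sample
#' size is at most \code{exact_max_n} and the data are tie-free; normal
#' approximation with tie correction otherwise). Medians, IQRs and Cohen's d
#' (pooled SD, oriented patient minus control) are always reported;
#' all tests are two-sided.
#'
#' @param control,patient numeric samples (NAs dropped; at least 3 finite
#'   values each, otherwise a degenerate row is returned).
#' @param alpha significance level for both the normality gate and the
#'   significance flag.
#' @param exact_max_n largest combined n for the exact U distribution.
#' @param variable optional variable name carried into the row.
#' @return one-row data.frame: \code{variable}, \code{control_median},
#'   \code{control_iqr}, \code{patient_median}, \code{patient_iqr},
#'   \code{normal} (both samples passed the gate), \code{test}
#'   (\code{"mann_whitney_u"} or \code{"z"}), \code{statistic},
#'   \code{p_value}, \code{significant}, \code{effect_size_d}.
#' @export
compareVariable <- function(control, patient, alpha = 0.05,
                            exact_max_n = 25L, variable = NA_character_) {
  control <- control[is.finite(control)]
  patient <- patient[is.finite(patient)]
  row <- data.frame(
    variable = variable,
    control_median = if (length(control)) median(control) else NA_real_,
    control_iqr = if (length(control)) IQR(control) else NA_real_,
    patient_median = if (length(patient)) median(patient) else NA_real_,
    patient_iqr = if (length(patient)) IQR(patient) else NA_real_,
    normal = NA, test = NA_character_, statistic = NA_real_,
    p_value = NA_real_, significant = NA, effect_size_d = NA_real_,
    stringsAsFactors = FALSE)
  if (length(control) < 3L || length(patient) < 3L)
    return(row)
  normal <- tryCatch(
    shapiroNormality(control) > alpha && shapiroNormality(patient) > alpha,
    error = function(e) FALSE)
  row$normal <- normal
  if (normal) {
    zt <- welchZTest(control, patient)
    row$test <- "z"
    row$statistic <- zt$statistic
    row$p_value <- zt$p_value
  } else {
    exact <- (length(control) + length(patient)) <= exact_max_n
    wt <- suppressWarnings(
      wilcox.test(patient, control, exact = exact, correct = !exact))
    row$test <- "mann_whitney_u"
    row$statistic <- unname(wt$statistic)
    row$p_value <- wt$p.value
  }
  row$significant <- is.finite(row$p_value) && row$p_value <= alpha
  row$effect_size_d <- cohensD(control, patient)
  row
}

#' Group comparison over all arm swing variables
#'
#' Produces the full comparison report: one row per canonical variable (see
#' [armSwingVariables()]), each tested with [compareVariable()]. No
#' multiple-testing correction is applied by default; \code{"holm"} adjusts
#' the p-values (and the significance flags) across the variable family.
#'
#' @param cohort a [CohortTable-class] with both groups represented (at least
#'   3 subjects each).
#' @param config an [armswingConfig()] list (\code{alpha},
#'   \code{exact_test_max_n}, \code{multiple_testing}).
#' @return data.frame of 21 rows in canonical variable order with the columns
#'   of [compareVariable()] plus \code{variable_label}.
#' @export
compareCohort <- function(cohort, config = armswingConfig()) {
  stopifnot(is(cohort, "CohortTable"))
  grp <- colData(cohort)$group
  if (sum(grp == "control") < 3L || sum(grp == "patient") < 3L)
    stop("each group needs at least 3 subjects")
  m <- assay(cohort, "features")
  rows <- lapply(armSwingVariables(), function(v)
    compareVariable(m[v, grp == "control"], m[v, grp == "patient"],
                    alpha = config$alpha,
                    exact_max_n = config$exact_test_max_n, variable = v))
  out <- do.call(rbind, rows)
  out$variable_label <- armSwingVariables(display = TRUE)
  if (config$multiple_testing == "holm") {
    out$p_value <- p.adjust(out$p_value, method = "holm")
    out$significant <- is.finite(out$p_value) & out$p_value <= config$alpha
  }
  out
}
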