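test_that("Shapiro-Wilk gate behaves on clear cases", {
  set.seed(2)
  expect_gt(shapiroNormality(rnorm(20)), 0.05)
  p_exp <- replicate(50, shapiroNormality(rexp(20)))
  expect_gt(mean(p_exp < 0.05), 0.5)   # power against strong skew
  expect_error(shapiroNormality(rnorm(2)), "3 <= n")
  expect_error(shapiroNormality(rep(1, 10)), "constant")
})

test_that("Mann-Whitney branch equals exhaustive permutation enumeration", {
  set.seed(4)
  for (i in 1:8) {
    n1 <- sample(3:5, 1); n2 <- sample(3:5, 1)
    a <- rnorm(n1); b <- rnorm(n2, mean = runif(1, -1, 1))
    row <- compareVariable(a, b, alpha = 1)  # alpha = 1 forces the U branch
    expect_identical(row$test, "mann_whitney_u")
    expect_equal(row$p_value, bruteMannWhitneyP(b, a), tolerance = 1e-9)
  }
})

test_that("identical samples give p near 1 and zero effect size", {
  x <- c(1.2, 3.4, 0.7, 2.2, 1.9, 2.8)
  row <- compareVariable(x, x)
  expect_gt(row$p_value, 0.9)
  expect_equal(row$effect_size_d, 0)
  expect_false(row$significant)
})

test_that("Cohen's d is oriented patient minus control and uses the pooled
           SD", {
  ctrl <- c(1, 2, 3, 4, 5)
  pat <- ctrl + 2
  row <- compareVariable(ctrl, pat, alpha = 1)
  sp <- sqrt((4 * var(ctrl) + 4 * var(pat)) / 8)
  expect_equal(row$effect_size_d, 2 / sp)
  expect_gt(row$effect_size_d, 0)
  expect_lt(compareVariable(pat, ctrl, alpha = 1)$effect_size_d, 0)
})

test_that("the normality gate selects the Z test for clean Gaussians", {
  set.seed(11)
  a <- rnorm(15); b <- rnorm(15, mean = 3)
  row <- compareVariable(a, b)
  expect_true(row$normal)
  expect_identical(row$test, "z")
  z <- (mean(b) - mean(a)) / sqrt(var(a) / 15 + var(b) / 15)
  expect_equal(row$statistic, z)
  expect_equal(row$p_value, 2 * pnorm(-abs(z)))
})

test_that("medians and IQRs match order-statistic computation", {
  set.seed(12)
  a <- rnorm(11); b <- rnorm(10)
  row <- compareVariable(a, b)
  expect_equal(row$control_median, sort(a)[6])
  expect_equal(row$patient_median, mean(sort(b)[5:6]))
  expect_equal(row$control_iqr, IQR(a))
  expect_gte(row$patient_iqr, 0)
})

test_that("degenerate samples produce a flagged row, not an error", {
  row <- compareVariable(c(1, 2), rnorm(10))
  expect_true(is.na(row$p_value))
  expect_true(is.na(row$significant))
})

test_that("LAS/MAS relabeling maps the affected arm to MAS", {
  feats <- suppressWarnings(
    extractFeatures(tinySessions(seed = 41, n_per_group = 1,
                                 trials = 1)[["P01"]]))
  left_aff <- relabelLasMas(feats, "left")
  expect_equal(left_aff[["rms_mas"]], unname(feats[["left_rms"]]))
  expect_equal(left_aff[["rms_las"]], unname(feats[["right_rms"]]))
  expect_equal(left_aff[["dx_mas"]], unname(feats[["left_dx"]]))

  right_aff <- relabelLasMas(feats, "right")
  expect_equal(right_aff[["rms_mas"]], unname(feats[["right_rms"]]))

  # swapping arm labels together with the affected side leaves output fixed
  swapped <- feats
  names(swapped) <- sub("^left_", "tmp_", names(swapped))
  names(swapped) <- sub("^right_", "left_", names(swapped))
  names(swapped) <- sub("^tmp_", "right_", names(swapped))
  expect_equal(relabelLasMas(swapped, "right"), left_aff)

  # controls follow the dominant-hand convention deterministically
  ctrl <- relabelLasMas(feats, "none", convention = "right_dominant")
  expect_equal(ctrl[["rms_las"]], unname(feats[["right_rms"]]))
  ctrl_l <- relabelLasMas(feats, "none", convention = "left_dominant")
  expect_equal(ctrl_l[["rms_las"]], unname(feats[["left_rms"]]))
  expect_error(relabelLasMas(feats, "none", convention = "coin"), "unknown")
})

test_that("cohort comparison yields one row per arm swing variable, in
           order", {
  cohort <- suppressWarnings(buildCohort(tinySessions(seed = 43, trials = 1)))
  rep <- compareCohort(cohort)
  expect_equal(nrow(rep), 21L)
  expect_identical(rep$variable, armSwingVariables())
  expect_identical(rep$variable_label, armSwingVariables(display = TRUE))
  expect_true(all(rep$p_value >= 0 & rep$p_value <= 1, na.rm = TRUE))
  expect_true(all(rep$control_iqr >= 0, na.rm = TRUE))
  expect_error(compareCohort(cohort[, 1:4]), "at least 3")
})

test_that("Holm adjustment only ever reduces the significant set", {
  cohort <- suppressWarnings(buildCohort(tinySessions(seed = 44, trials = 1)))
  plain <- compareCohort(cohort)
  holm <- compareCohort(cohort, armswingConfig(multiple_testing = "holm"))
  expect_true(all(holm$p_value >= plain$p_value, na.rm = TRUE))
  expect_true(all(which(holm$significant) %in% which(plain$significant)))
})
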