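test_that("parameter validation catches impossible settings", {
  expect_error(cohort_params(n_pairs = -1), "non-negative")
  expect_error(cohort_params(severity_shape = 0), "positive")
  expect_error(cohort_params(rater_fn = c(pediatrician = 1.2, nurse = 0.1,
                                          caregiver = 0.1)), "probabilities")
  expect_error(cohort_params(dropout_prob = -0.1), "probabilities")
  expect_error(cohort_params(censor_day = 0), "positive")
  expect_error(cohort_params(cell_baseline = c(-1, -2)), "cell_baseline")
})

test_that("generation is deterministic given the seed and leaves the RNG alone", {
  p <- cohort_params(n_pairs = 15, seed = 123)
  set.seed(555); before <- runif(1)
  c1 <- generate_cohort(p)
  c2 <- generate_cohort(p)
  expect_identical(c1[], c2[])

  set.seed(555); expect_identical(runif(1), before)

  d1 <- file.path(tempdir(), "g1.csv"); d2 <- file.path(tempdir(), "g2.csv")
  o1 <- file.path(tempdir(), "o1.csv"); o2 <- file.path(tempdir(), "o2.csv")
  write_cohort(c1, d1, o1); write_cohort(c2, d2, o2)
  expect_identical(readLines(d1), readLines(d2))
  expect_identical(readLines(o1), readLines(o2))

  c3 <- generate_cohort(cohort_params(n_pairs = 15, seed = 124))
  expect_false(identical(c1[], c3[]))
})

test_that("an empty cohort and a zero-noise cohort behave as constructed", {
  expect_length(generate_cohort(cohort_params(n_pairs = 0)), 0)

  p <- cohort_params(n_pairs = 25, seed = 9,
                     rater_fn = c(pediatrician = 0, nurse = 0, caregiver = 0),
                     rater_fp = c(pediatrician = 0, nurse = 0, caregiver = 0))
  cohort <- generate_cohort(p)
  for (rec in cohort) {
    for (role in names(rec$grids)) {
      expect_identical(unclass(rec$grids[[role]]), unclass(rec$true_grid))
    }
  }
  # identical grids imply perfect inter-rater agreement on scores
  scores <- score_cohort(cohort)
  ped <- scores$score[scores$rater_role == "pediatrician" & scores$version == "v2"]
  cg <- scores$score[scores$rater_role == "caregiver" & scores$version == "v2"]
  expect_identical(ped, cg)
  if (stats::sd(ped) > 0) {
    expect_equal(icc_two_way(cbind(ped, cg))$estimate, 1)
  }
})

test_that("treatment-need prevalence converges to the analytic severity tail", {
  p0 <- cohort_params()
  analytic <- stats::pgamma(p0$treatment_threshold, shape = p0$severity_shape,
                            scale = p0$severity_scale, lower.tail = FALSE)
  expect_equal(analytic, 11 / 113, tolerance = 1e-12)

  hits <- 0; total <- 0
  for (s in 1:150) {
    cohort <- generate_cohort(cohort_params(seed = s))
    hits <- hits + sum(vapply(cohort, `[[`, logical(1), "needs_treatment"))
    total <- total + length(cohort)
  }
  se <- sqrt(analytic * (1 - analytic) / total)
  expect_lt(abs(hits / total - analytic), 4 * se)
})

test_that("cure groups bin days on closed intervals with censoring in the top group", {
  rec <- function(days, censored = FALSE, dropout = FALSE) {
    list(cure_period_days = days, censored = censored, dropout = dropout)
  }
  expect_equal(as.character(assign_cure_group(rec(0L))), "0-7")
  expect_equal(as.character(assign_cure_group(rec(7L))), "0-7")
  expect_equal(as.character(assign_cure_group(rec(8L))), "8-14")
  expect_equal(as.character(assign_cure_group(rec(14L))), "8-14")
  expect_equal(as.character(assign_cure_group(rec(15L))), "15-28")
  expect_equal(as.character(assign_cure_group(rec(28L))), "15-28")
  expect_equal(as.character(assign_cure_group(rec(NA_integer_, censored = TRUE))),
               "over_28")
  expect_true(is.ordered(assign_cure_group(rec(3L))))
  expect_error(assign_cure_group(rec(5L, dropout = TRUE)), "dropout")
})

test_that("rater noise degrades agreement between observed and true grids monotonically", {
  noisy <- function(fn, fp, seed) {
    p <- cohort_params(n_pairs = 40, seed = seed,
                       rater_fn = c(pediatrician = fn, nurse = fn, caregiver = fn),
                       rater_fp = c(pediatrician = fp, nurse = fp, caregiver = fp))
    cohort <- generate_cohort(p)
    mean(vapply(cohort, function(r) {
      mean(unclass(r$grids$caregiver) == unclass(r$true_grid))
    }, numeric(1)))
  }
  agree_low <- mean(sapply(1:5, function(s) noisy(0.05, 0.01, s)))
  agree_high <- mean(sapply(1:5, function(s) noisy(0.4, 0.2, s)))
  expect_gt(agree_low, agree_high)
  expect_gt(agree_low, 0.9)
})

test_that("default barrier readings are severity-independent nulls", {
  cohort <- generate_cohort(cohort_params(seed = 2))
  sev <- vapply(cohort, `[[`, numeric(1), "severity")
  tewl <- vapply(cohort, `[[`, numeric(1), "tewl")
  expect_lt(abs(spearman_rho(sev, tewl)), 0.4)
})
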