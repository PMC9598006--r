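#' Parameters of the synthetic infant cohort generator
#'
#' The simulator emulates the statistical structure assumed by the
#' instrument's validation design: a single latent severity per infant
#' drives (i) symptom presence in each grid cell, (ii) the pediatrician's
#' need-for-treatment judgment, and (iii) the cure period, while three rater
#' roles observe the true grid through role-specific misclassification
#' noise and skin-barrier readings are drawn independently of severity.
#'
#' Defaults are calibrated to a study-like cohort: 113 infant-caregiver
#' pairs, roughly 10% treatment-need prevalence (the analytic tail
#' probability of the Gamma severity distribution beyond
#' `treatment_threshold`), right-skewed integer cure periods censored 28
#' days after the checkup, about 19% dropout during follow-up and about 14%
#' dermatologic-agent use.
#'
#' @param n_pairs Number of infant-caregiver pairs.
#' @param severity_shape,severity_scale Shape/scale of the Gamma latent
#'   severity distribution.
#' @param cell_baseline Per-(symptom, area) logit intercepts for cell
#'   presence; a 4 x 9 matrix, or a length-4 vector recycled across areas,
#'   or a scalar.
#' @param severity_slope Logit slope linking severity to cell presence.
#' @param rater_fn,rater_fp Named numeric vectors of per-role false-negative
#'   and false-positive cell observation probabilities for roles
#'   `pediatrician`, `nurse`, `caregiver`.
#' @param treatment_threshold Severity above which the pediatrician judges
#'   the infant to need medical treatment. The default is the Gamma quantile
#'   giving ~9.7% prevalence.
#' @param cure_intercept,cure_slope,cure_sd Log-scale intercept, severity
#'   slope and Gaussian noise SD of the log-normal cure-period model
#'   `cure = round(exp(intercept + slope * severity + noise))` days.
#' @param censor_day Follow-up horizon in days; cure periods beyond it are
#'   censored ("did not disappear within 4 weeks").
#' @param agent_use_prob Probability an infant used dermatologic agents
#'   after birth (such infants are excluded from cure-period analyses).
#' @param dropout_prob Probability the pair drops out during follow-up.
#' @param barrier_params List with entries `tewl`, `sch`, `sebum`, each
#'   `c(mean, sd, severity_slope)`; the default slope 0 makes readings
#'   independent of severity (the null concurrent-validity structure).
#' @param repeat_assessment If `TRUE`, a second pediatrician assessment
#'   occasion (photograph re-rating) is emitted for the first
#'   `repeat_n` infants, together with a second pediatrician's
#'   treatment-need judgment for the agreement-rate analysis.
#' @param repeat_n Size of the two-occasion subsample.
#' @param judgment_noise_prob Probability the second pediatrician's
#'   treatment-need judgment flips relative to the threshold rule
#'   (0 reproduces perfect between-pediatrician agreement).
#' @param seed Integer seed; cohorts are byte-identical given identical
#'   parameters and seed.
#' @return A `cohort_params` list (validated).
#' @export
cohort_params <- function(n_pairs = 113,
                          severity_shape = 2,
                          severity_scale = 1,
                          cell_baseline = c(erythema = -2.6, papules = -2.3,
                                            dryness = -3.0,
                                            exudate_yellow_scaling = -3.6),
                          severity_slope = 0.4,
                          rater_fn = c(pediatrician = 0.10, nurse = 0.30,
                                       caregiver = 0.35),
                          rater_fp = c(pediatrician = 0.02, nurse = 0.05,
                                       caregiver = 0.08),
                          treatment_threshold = stats::qgamma(
                            1 - 11 / 113, shape = severity_shape,
                            scale = severity_scale),
                          cure_intercept = 1.9,
                          cure_slope = 0.5,
                          cure_sd = 0.6,
                          censor_day = 28,
                          agent_use_prob = 13 / 92,
                          dropout_prob = 21 / 113,
                          barrier_params = list(
                            tewl = c(mean = 12, sd = 4, severity_slope = 0),
                            sch = c(mean = 40, sd = 12, severity_slope = 0),
                            sebum = c(mean = 8, sd = 6, severity_slope = 0)),
                          repeat_assessment = TRUE,
                          repeat_n = 20,
                          judgment_noise_prob = 0,
                          seed = 1L) {
  if (n_pairs < 0 || n_pairs != round(n_pairs)) {
    stop("`n_pairs` must be a non-negative integer", call. = FALSE)
  }
  if (severity_shape <= 0 || severity_scale <= 0) {
    stop("severity shape/scale must be positive", call. = FALSE)
  }
  cell_baseline <- expand_baseline(cell_baseline)
  roles <- c("pediatrician", "nurse", "caregiver")
  rater_fn <- rater_fn[roles]; rater_fp <- rater_fp[roles]
  probs <- c(rater_fn, rater_fp, agent_use_prob, dropout_prob,
             judgment_noise_prob)
  if (anyNA(probs) || any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1] and cover all three roles",
         call. = FALSE)
  }
  if (cure_sd < 0) stop("`cure_sd` must be >= 0", call. = FALSE)
  if (censor_day <= 0) stop("`censor_day` must be positive", call. = FALSE)
  for (b in barrier_params) {
    if (b[["sd"]] < 0) stop("barrier sds must be >= 0", call. = FALSE)
  }
  structure(
    list(n_pairs = as.integer(n_pairs), severity_shape = severity_shape,
         severity_scale = severity_scale, cell_baseline = cell_baseline,
         severity_slope = severity_slope, rater_fn = rater_fn,
         rater_fp = rater_fp, treatment_threshold = treatment_threshold,
         cure_intercept = cure_intercept, cure_slope = cure_slope,
         cure_sd = cure_sd, censor_day = as.integer(censor_day),
         agent_use_prob = agent_use_prob, dropout_prob = dropout_prob,
         barrier_params = barrier_params,
         repeat_assessment = isTRUE(repeat_assessment),
         repeat_n = as.integer(repeat_n),
         judgment_noise_prob = judgment_noise_prob,
         seed = as.integer(seed)),
    class = "cohort_params"
  )
}

# Accept scalar, per-symptom vector, or full 4 x 9 matrix of logit intercepts.
expand_baseline <- function(b) {
  sy <- symptoms(); ar <- facial_areas("nine_area")
  if (is.matrix(b)) {
    if (!identical(dim(b), c(length(sy), length(ar)))) {
      stop("`cell_baseline` matrix must be 4 symptoms x 9 areas", call. = FALSE)
    }
    dimnames(b) <- list(sy, ar)
    return(b)
  }
  if (length(b) == 1) b <- rep(b, length(sy))
  if (length(b) != length(sy)) {
    stop("`cell_baseline` must be a scalar, length-4 vector, or 4 x 9 matrix",
         call. = FALSE)
  }
  matrix(as.numeric(b), length(sy), length(ar),
         dimnames = list(sy, ar))
}

#' Generate a synthetic infant cohort
#'
#' Draws `n_pairs` infant records under the latent-severity model described
#' in [cohort_params()]. Generation is fully deterministic given the
#' parameter set (including its `seed`); the caller's RNG state is left
#' untouched.
#'
#' @param params A [cohort_params()] object.
#' @return An `ifsat_cohort`: a list of infant records, each a list with
#'   `infant_id`, `severity` (latent), `true_grid`, `grids` (named list of
#'   observed nine-area grids per role, plus `pediatrician_t2` for the
#'   two-occasion subsample), `needs_treatment`, `needs_treatment_rater2`
#'   (subsample only, else `NA`), `used_dermatologic_agent`, `dropout`,
#'   `cure_period_days` (`NA` when censored), `censored`, `tewl`, `sch`,
#'   `sebum`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_params(n_pairs = 10, seed = 42))
#' length(cohort)
generate_cohort <- function(params = cohort_params()) {
  if (!inherits(params, "cohort_params")) {
    stop("`params` must come from cohort_params()", call. = FALSE)
  }
  local_seed(params$seed, {
    records <- vector("list", params$n_pairs)
    for (i in seq_len(params$n_pairs)) {
      records[[i]] <- generate_record(i, params)
    }
    structure(records, class = "ifsat_cohort", params = params)
  })
}

generate_record <- function(i, params) {
  sev <- stats::rgamma(1, shape = params$severity_shape,
                       scale = params$severity_scale)
  p_cell <- stats::plogis(params$cell_baseline + params$severity_slope * sev)
  true_m <- matrix(stats::runif(length(p_cell)) < p_cell,
                   nrow(p_cell), ncol(p_cell), dimnames = dimnames(p_cell))
  true_grid <- assessment_grid(true_m)

  in_repeat <- params$repeat_assessment && i <= params$repeat_n
  roles <- c("pediatrician", "nurse", "caregiver")
  grids <- lapply(roles, function(r) {
    observe_grid(true_grid, params$rater_fn[[r]], params$rater_fp[[r]])
  })
  names(grids) <- roles
  if (in_repeat) {
    grids$pediatrician_t2 <- observe_grid(true_grid,
                                          params$rater_fn[["pediatrician"]],
                                          params$rater_fp[["pediatrician"]])
  }

  needs <- sev > params$treatment_threshold
  needs2 <- NA
  if (in_repeat) {
    needs2 <- needs
    if (params$judgment_noise_prob > 0 &&
        stats::runif(1) < params$judgment_noise_prob) {
      needs2 <- !needs2
    }
  }

  cure_raw <- round(exp(params$cure_intercept + params$cure_slope * sev +
                          stats::rnorm(1, 0, params$cure_sd)))
  censored <- cure_raw > params$censor_day
  cure_days <- if (censored) NA_integer_ else as.integer(max(cure_raw, 0))

  bp <- params$barrier_params
  barrier <- vapply(c("tewl", "sch", "sebum"), function(nm) {
    b <- bp[[nm]]
    max(stats::rnorm(1, b[["mean"]] + b[["severity_slope"]] * sev, b[["sd"]]), 0)
  }, numeric(1))

  list(infant_id = sprintf("I%03d", i), severity = sev,
       true_grid = true_grid, grids = grids,
       needs_treatment = needs, needs_treatment_rater2 = needs2,
       used_dermatologic_agent = stats::runif(1) < params$agent_use_prob,
       dropout = stats::runif(1) < params$dropout_prob,
       cure_period_days = cure_days, censored = censored,
       tewl = barrier[["tewl"]], sch = barrier[["sch"]],
       sebum = barrier[["sebum"]])
}

# Pass a true grid through a rater's misclassification channel.
observe_grid <- function(true_grid, fn, fp) {
  m <- unclass(true_grid)
  u <- matrix(stats::runif(length(m)), nrow(m), ncol(m))
  obs <- ifelse(m, u >= fn, u < fp)
  assessment_grid(matrix(obs, nrow(m), ncol(m), dimnames = dimnames(m)))
}

#' @export
print.ifsat_cohort <- function(x, ...) {
  cat("Synthetic IFSAT cohort:", length(x), "infant-caregiver pairs\n")
  if (length(x)) {
    needs <- vapply(x, `[[`, logical(1), "needs_treatment")
    drop <- vapply(x, `[[`, logical(1), "dropout")
    agent <- vapply(x, `[[`, logical(1), "used_dermatologic_agent")
    cat("  needs treatment:", sum(needs),
        " dropouts:", sum(drop),
        " dermatologic-agent users:", sum(agent), "\n")
  }
  invisible(x)
}

#' Cure-period group of a completed-follow-up record
#'
#' Bins the cure period (days from the 1-month checkup until the caregiver
#' reported the skin problems disappeared) into the four ordered groups
#' 0-7, 8-14, 15-28 and over 28 days; censored records ("did not disappear
#' within 4 weeks") fall in the over-28 group.
#'
#' @param record An infant record from [generate_cohort()] or
#'   [read_cohort()].
#' @return An ordered factor level among `0-7`, `8-14`, `15-28`, `over_28`.
#' @export
assign_cure_group <- function(record) {
  if (isTRUE(record$dropout)) {
    stop("cure group is undefined for a dropout record (no follow-up)",
         call. = FALSE)
  }
  lv <- cure_group_levels()
  if (isTRUE(record$censored) || (!is.na(record$cure_period_days) &&
                                  record$cure_period_days > 28)) {
    return(factor("over_28", levels = lv, ordered = TRUE))
  }
  d <- record$cure_period_days
  if (is.na(d)) stop("record has no cure period and is not censored",
                     call. = FALSE)
  g <- if (d <= 7) "0-7" else if (d <= 14) "8-14" else "15-28"
  factor(g, levels = lv, ordered = TRUE)
}

cure_group_levels <- function() c("0-7", "8-14", "15-28", "over_28")
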