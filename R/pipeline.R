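#' Analysis configuration for the validation pipeline
#'
#' @param scoring_version Version used for the cutoff, predictive,
#'   reliability and concurrent analyses (`"v2"` is the finalized method;
#'   trend and AUC tables are always computed for all three versions).
#' @param censor_day Follow-up horizon in days.
#' @param icc_form ICC form, `"agreement"` or `"consistency"` (see
#'   [icc_two_way()]).
#' @param jonckheere_sidedness Sidedness of the trend test.
#' @param exact_n_max Total-N threshold below which trend and rank tests use
#'   exact permutation p-values.
#' @param include_dropouts_outside_cure If `TRUE` (default), dropouts are
#'   excluded only from cure-period trend analyses and retained in AUC,
#'   predictive, reliability and concurrent analyses.
#' @param mc_seed Seed for any Monte Carlo permutation fallback, so a run
#'   on a fixed cohort is bit-reproducible.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(scoring_version = c("v2", "v1", "original"),
                            censor_day = 28,
                            icc_form = c("agreement", "consistency"),
                            jonckheere_sidedness = c("two_sided", "increasing"),
                            exact_n_max = 20,
                            include_dropouts_outside_cure = TRUE,
                            mc_seed = 1L) {
  scoring_version <- match.arg(scoring_version)
  icc_form <- match.arg(icc_form)
  jonckheere_sidedness <- match.arg(jonckheere_sidedness)
  if (censor_day <= 0) stop("`censor_day` must be positive", call. = FALSE)
  structure(
    list(scoring_version = scoring_version, censor_day = as.integer(censor_day),
         icc_form = icc_form, jonckheere_sidedness = jonckheere_sidedness,
         exact_n_max = exact_n_max,
         include_dropouts_outside_cure = isTRUE(include_dropouts_outside_cure),
         mc_seed = as.integer(mc_seed)),
    class = "analysis_config"
  )
}

#' @rdname analysis_config
#' @param path Path to a YAML file whose keys match the arguments of
#'   `analysis_config()`.
#' @export
read_analysis_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown analysis config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(analysis_config, vals)
}

roles3 <- function() c("pediatrician", "nurse", "caregiver")
versions3 <- function() c("original", "v1", "v2")

#' Run the full reliability and validity analysis on a cohort
#'
#' Reproduces the validation design end to end: scores every rater's grid
#' under all three scoring methods; runs the cure-period trend analysis
#' (Jonckheere-Terpstra across the ordered cure groups, on follow-up
#' completers who did not use dermatologic agents); computes ROC/AUC for
#' every rater x version against the pediatrician's treatment-need judgment
#' on all completed-checkup records; selects the caregiver Youden cutoff for
#' the configured version; compares need vs no-need score distributions per
#' rater (Mann-Whitney); computes intra-examiner and inter-rater ICCs and
#' the between-pediatrician agreement rate; and correlates scores with the
#' skin-barrier readings (Spearman).
#'
#' @param cohort An `ifsat_cohort` from [generate_cohort()] or
#'   [read_cohort()].
#' @param config An [analysis_config()].
#' @return A `validation_report` list: `filter_counts`, `scores` (long
#'   data.frame), `trend_table`, `auc_table`, `youden`, `predictive_table`,
#'   `icc_intra`, `icc_inter`, `agreement_rate_pct`, `concurrent_table`,
#'   `config`.
#' @export
run_validation <- function(cohort, config = analysis_config()) {
  if (!length(cohort)) stop("cohort is empty", call. = FALSE)
  for (rec in cohort) {
    miss <- setdiff(roles3(), names(rec$grids))
    if (length(miss)) {
      stop("record ", rec$infant_id, " is missing rater grid(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }

  scores <- score_cohort(cohort)
  dropout <- vapply(cohort, `[[`, logical(1), "dropout")
  agent <- vapply(cohort, `[[`, logical(1), "used_dermatologic_agent")
  needs <- vapply(cohort, `[[`, logical(1), "needs_treatment")

  completed_fu <- !dropout
  cure_eligible <- completed_fu & !agent
  filter_counts <- c(
    recruited = length(cohort),
    completed_followup = sum(completed_fu),
    dropouts = sum(dropout),
    agent_excluded = sum(completed_fu & agent),
    analyzed_for_cure = sum(cure_eligible)
  )

  cure_groups <- rep(NA_character_, length(cohort))
  for (i in which(cure_eligible)) {
    cure_groups[i] <- as.character(assign_cure_group(cohort[[i]]))
  }

  trend_table <- trend_analysis(scores, cure_groups, cure_eligible, config)
  auc_table <- auc_analysis(scores, needs)

  ver <- config$scoring_version
  cg_scores <- score_vector(scores, "caregiver", ver)
  if (length(unique(needs)) < 2) {
    message("treatment-need judgment has a single class; ",
            "ROC/AUC and the Youden cutoff are not estimable")
    youden <- list(cutoff = NA_real_, sensitivity = NA_real_,
                   specificity = NA_real_, j = NA_real_)
  } else {
    youden <- youden_cutoff(empirical_roc(cg_scores, needs))
  }

  predictive_table <- predictive_analysis(scores, needs, config)
  rel <- reliability_analysis(cohort, scores, config)
  concurrent_table <- concurrent_analysis(cohort, scores, config)

  structure(
    list(filter_counts = filter_counts, scores = scores,
         trend_table = trend_table, auc_table = auc_table,
         youden = youden, predictive_table = predictive_table,
         icc_intra = rel$icc_intra, icc_inter = rel$icc_inter,
         agreement_rate_pct = rel$agreement_rate_pct,
         concurrent_table = concurrent_table, config = config),
    class = "validation_report"
  )
}

#' Score every rater grid of a cohort under all three methods
#'
#' @param cohort An `ifsat_cohort`.
#' @return Long data.frame with columns `infant_id`, `rater_role`,
#'   `version`, `score` (roles include `pediatrician_t2` where present).
#' @export
score_cohort <- function(cohort) {
  rows <- list()
  for (rec in cohort) {
    for (role in names(rec$grids)) {
      s <- score_set(rec$grids[[role]])
      rows[[length(rows) + 1L]] <- data.frame(
        infant_id = rec$infant_id, rater_role = role,
        version = versions3(), score = as.integer(s[versions3()]),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

score_vector <- function(scores, role, version) {
  sub <- scores[scores$rater_role == role & scores$version == version, ]
  ids <- unique(scores$infant_id)
  sub$score[match(ids, sub$infant_id)]
}

trend_analysis <- function(scores, cure_groups, eligible, config) {
  ids <- unique(scores$infant_id)
  lv <- cure_group_levels()
  rows <- list()
  for (ver in versions3()) {
    for (role in roles3()) {
      sc <- score_vector(scores, role, ver)
      groups <- lapply(lv, function(g) sc[eligible & cure_groups == g & !is.na(cure_groups)])
      nonempty <- lengths(groups) > 0
      if (sum(nonempty) < 3) {
        jt_p <- NA_real_
      } else {
        jt <- jonckheere_terpstra(groups[nonempty],
                                  sidedness = config$jonckheere_sidedness,
                                  exact_n_max = config$exact_n_max,
                                  mc_seed = config$mc_seed)
        jt_p <- jt$p_value
      }
      med <- lapply(groups, function(v) {
        if (!length(v)) c(n = 0, median = NA, q25 = NA, q75 = NA) else five_num(v)
      })
      row <- data.frame(version = ver, rater = role, stringsAsFactors = FALSE)
      for (gi in seq_along(lv)) {
        tag <- gsub("-", "_", lv[gi])
        row[[paste0("n_", tag)]] <- med[[gi]][["n"]]
        row[[paste0("median_", tag)]] <- med[[gi]][["median"]]
        row[[paste0("q25_", tag)]] <- med[[gi]][["q25"]]
        row[[paste0("q75_", tag)]] <- med[[gi]][["q75"]]
      }
      row$jt_p <- jt_p
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

auc_analysis <- function(scores, needs) {
  rows <- list()
  for (ver in versions3()) {
    for (role in roles3()) {
      sc <- score_vector(scores, role, ver)
      auc <- if (length(unique(needs)) < 2) NA_real_ else {
        empirical_roc(sc, needs)$auc
      }
      rows[[length(rows) + 1L]] <- data.frame(
        version = ver, rater = role, n = length(sc), auc = auc,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

predictive_analysis <- function(scores, needs, config) {
  rows <- list()
  for (role in roles3()) {
    sc <- score_vector(scores, role, config$scoring_version)
    x <- sc[needs]; y <- sc[!needs]
    if (!length(x) || !length(y)) {
      rows[[length(rows) + 1L]] <- data.frame(
        rater = role, n_need = length(x), n_no_need = length(y),
        median_need = NA, q25_need = NA, q75_need = NA,
        median_no_need = NA, q25_no_need = NA, q75_no_need = NA,
        u_statistic = NA, p_value = NA, stringsAsFactors = FALSE
      )
      next
    }
    mw <- mann_whitney_u(x, y, exact_n_max = config$exact_n_max)
    rows[[length(rows) + 1L]] <- data.frame(
      rater = role, n_need = length(x), n_no_need = length(y),
      median_need = mw$summary["x", "median"],
      q25_need = mw$summary["x", "q25"], q75_need = mw$summary["x", "q75"],
      median_no_need = mw$summary["y", "median"],
      q25_no_need = mw$summary["y", "q25"], q75_no_need = mw$summary["y", "q75"],
      u_statistic = mw$u_statistic, p_value = mw$p_value,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

reliability_analysis <- function(cohort, scores, config) {
  ver <- config$scoring_version
  has_t2 <- vapply(cohort, function(r) "pediatrician_t2" %in% names(r$grids),
                   logical(1))
  icc_intra <- NULL
  if (sum(has_t2) >= 2) {
    ids2 <- vapply(cohort[has_t2], `[[`, character(1), "infant_id")
    all_ids <- unique(scores$infant_id)
    t1 <- score_vector(scores, "pediatrician", ver)[match(ids2, all_ids)]
    sub <- scores[scores$rater_role == "pediatrician_t2" & scores$version == ver, ]
    t2 <- sub$score[match(ids2, sub$infant_id)]
    icc_intra <- tryCatch(icc_two_way(cbind(t1 = t1, t2 = t2),
                                      form = config$icc_form),
                          error = function(e) NULL)
  }

  icc_inter <- list()
  cg <- score_vector(scores, "caregiver", ver)
  for (role in c("pediatrician", "nurse")) {
    m <- cbind(score_vector(scores, role, ver), cg)
    colnames(m) <- c(role, "caregiver")
    icc_inter[[paste0(role, "_caregiver")]] <-
      tryCatch(icc_two_way(m, form = config$icc_form), error = function(e) NULL)
  }

  agree <- NA_real_
  j2 <- vapply(cohort, function(r) {
    v <- r$needs_treatment_rater2
    if (is.null(v)) NA else v
  }, logical(1))
  have2 <- !is.na(j2)
  if (any(have2)) {
    j1 <- vapply(cohort, `[[`, logical(1), "needs_treatment")
    agree <- agreement_rate(j1[have2], j2[have2])
  }

  list(icc_intra = icc_intra, icc_inter = icc_inter,
       agreement_rate_pct = agree)
}

concurrent_analysis <- function(cohort, scores, config) {
  ver <- config$scoring_version
  rows <- list()
  measures <- c("tewl", "sch", "sebum")
  vals <- lapply(measures, function(m) vapply(cohort, `[[`, numeric(1), m))
  names(vals) <- measures
  for (role in roles3()) {
    sc <- score_vector(scores, role, ver)
    row <- data.frame(rater = role, stringsAsFactors = FALSE)
    for (m in measures) {
      row[[m]] <- tryCatch(spearman_rho(sc, vals[[m]]),
                           error = function(e) NA_real_)
    }
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.validation_report <- function(x, ...) {
  fc <- x$filter_counts
  cat("IFSAT validation report (scoring version:",
      x$config$scoring_version, ")\n")
  cat("  flow: recruited", fc[["recruited"]],
      "-> completed follow-up", fc[["completed_followup"]],
      "(dropouts", paste0(fc[["dropouts"]], ")"),
      "-> cure-period analysis", fc[["analyzed_for_cure"]],
      "(agent-excluded", paste0(fc[["agent_excluded"]], ")\n"))
  cat("\nTrend p-values (Jonckheere-Terpstra) by version x rater:\n")
  print(x$trend_table[, c("version", "rater", "jt_p")], row.names = FALSE)
  cat("\nAUC vs need-for-treatment:\n")
  print(x$auc_table, row.names = FALSE)
  cat("\nCaregiver Youden cutoff: >=", x$youden$cutoff,
      " sens =", round(x$youden$sensitivity, 3),
      " spec =", round(x$youden$specificity, 3),
      " J =", round(x$youden$j, 3), "\n")
  cat("\nNeed vs no-need (Mann-Whitney):\n")
  print(x$predictive_table[, c("rater", "n_need", "median_need",
                               "median_no_need", "p_value")],
        row.names = FALSE)
  if (!is.null(x$icc_intra)) {
    cat("\nIntra-examiner ICC:", round(x$icc_intra$estimate, 3),
        sprintf("[%.3f, %.3f]", x$icc_intra$ci_low, x$icc_intra$ci_high), "\n")
  }
  for (nm in names(x$icc_inter)) {
    r <- x$icc_inter[[nm]]
    if (!is.null(r)) {
      cat("Inter-rater ICC", nm, ":", round(r$estimate, 3),
          sprintf("[%.3f, %.3f]", r$ci_low, r$ci_high), "\n")
    }
  }
  cat("Pediatrician agreement on treatment need:",
      x$agreement_rate_pct, "%\n")
  cat("\nSpearman rho vs skin-barrier measures:\n")
  print(x$concurrent_table, row.names = FALSE)
  invisible(x)
}
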