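#' Write and read a cohort as paired CSV files
#'
#' A cohort serializes to two plain-text CSVs whose schemas are part of the
#' package contract:
#'
#' * **grids CSV** — long format, one row per observed cell:
#'   `infant_id`, `rater_role` (`pediatrician`, `nurse`, `caregiver`,
#'   `pediatrician_t2`), `symptom`, `area`, `present` (0/1), in canonical
#'   symptom-major order within each grid.
#' * **outcomes CSV** — one row per infant: `infant_id`, `needs_treatment`,
#'   `needs_treatment_rater2` (blank when not assessed),
#'   `used_dermatologic_agent`, `dropout`, `cure_period_days` (blank when
#'   censored or dropped out), `censored`, `tewl`, `sch`, `sebum`.
#'
#' The latent severity and true grid are simulator internals and are not
#' serialized; `read_cohort()` therefore returns observed data only. A
#' write-read-write round trip is byte-identical.
#'
#' @param cohort An `ifsat_cohort`.
#' @param grids_path,outcomes_path CSV file paths.
#' @return `write_cohort()`: the paths, invisibly. `read_cohort()`: an
#'   `ifsat_cohort`.
#' @export
write_cohort <- function(cohort, grids_path, outcomes_path) {
  grid_rows <- list()
  out_rows <- list()
  for (rec in cohort) {
    for (role in names(rec$grids)) {
      grid_rows[[length(grid_rows) + 1L]] <-
        grid_to_long(rec$grids[[role]], infant_id = rec$infant_id,
                     rater_role = role)
    }
    out_rows[[length(out_rows) + 1L]] <- data.frame(
      infant_id = rec$infant_id,
      needs_treatment = as.integer(rec$needs_treatment),
      needs_treatment_rater2 = if (is.null(rec$needs_treatment_rater2) ||
                                   is.na(rec$needs_treatment_rater2)) {
        NA_integer_
      } else as.integer(rec$needs_treatment_rater2),
      used_dermatologic_agent = as.integer(rec$used_dermatologic_agent),
      dropout = as.integer(rec$dropout),
      cure_period_days = if (is.null(rec$cure_period_days)) NA_integer_ else
        rec$cure_period_days,
      censored = as.integer(isTRUE(rec$censored)),
      tewl = rec$tewl, sch = rec$sch, sebum = rec$sebum,
      stringsAsFactors = FALSE
    )
  }
  grids <- do.call(rbind, grid_rows)
  outcomes <- do.call(rbind, out_rows)
  utils::write.csv(grids, grids_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(outcomes, outcomes_path, row.names = FALSE, quote = FALSE)
  invisible(c(grids = grids_path, outcomes = outcomes_path))
}

#' @rdname write_cohort
#' @export
read_cohort <- function(grids_path, outcomes_path) {
  grids <- utils::read.csv(grids_path, stringsAsFactors = FALSE)
  outcomes <- utils::read.csv(outcomes_path, stringsAsFactors = FALSE)
  check_columns(grids, c("infant_id", "rater_role", "symptom", "area",
                         "present"), basename(grids_path))
  check_columns(outcomes, c("infant_id", "needs_treatment",
                            "needs_treatment_rater2",
                            "used_dermatologic_agent", "dropout",
                            "cure_period_days", "censored", "tewl", "sch",
                            "sebum"), basename(outcomes_path))
  if (!all(grids$present %in% c(0, 1))) {
    bad <- which(!grids$present %in% c(0, 1))[1]
    stop("grids file ", basename(grids_path), ": `present` must be 0/1 (row ",
         bad, ")", call. = FALSE)
  }
  orphan <- setdiff(grids$infant_id, outcomes$infant_id)
  if (length(orphan)) {
    stop("grids file has infant_id(s) missing from outcomes: ",
         paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
  }

  records <- vector("list", nrow(outcomes))
  for (i in seq_len(nrow(outcomes))) {
    o <- outcomes[i, ]
    sub <- grids[grids$infant_id == o$infant_id, ]
    rec_grids <- list()
    for (role in unique(sub$rater_role)) {
      rec_grids[[role]] <- long_to_grid(sub[sub$rater_role == role, ])
    }
    records[[i]] <- list(
      infant_id = o$infant_id, severity = NA_real_, true_grid = NULL,
      grids = rec_grids,
      needs_treatment = o$needs_treatment == 1,
      needs_treatment_rater2 = if (is.na(o$needs_treatment_rater2)) NA else
        o$needs_treatment_rater2 == 1,
      used_dermatologic_agent = o$used_dermatologic_agent == 1,
      dropout = o$dropout == 1,
      cure_period_days = if (is.na(o$cure_period_days)) NA_integer_ else
        as.integer(o$cure_period_days),
      censored = o$censored == 1,
      tewl = o$tewl, sch = o$sch, sebum = o$sebum
    )
  }
  structure(records, class = "ifsat_cohort")
}

check_columns <- function(df, need, file) {
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("file ", file, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' Serialize a validation report
#'
#' Writes the report as machine-readable JSON (full double precision) and,
#' optionally, a set of markdown tables mirroring the trend, predictive and
#' concurrent-validity table layouts.
#'
#' @param report A `validation_report` from [run_validation()].
#' @param path Output path for the JSON file.
#' @param markdown_path Optional path for a markdown rendering.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, markdown_path = NULL) {
  icc_json <- function(r) {
    if (is.null(r)) return(NULL)
    list(estimate = r$estimate, ci_low = r$ci_low, ci_high = r$ci_high,
         model = r$model, n_subjects = r$n_subjects, n_raters = r$n_raters)
  }
  obj <- list(
    filter_counts = as.list(report$filter_counts),
    trend_table = report$trend_table,
    auc_table = report$auc_table,
    youden = report$youden,
    predictive_table = report$predictive_table,
    icc_intra = icc_json(report$icc_intra),
    icc_inter = lapply(report$icc_inter, icc_json),
    agreement_rate_pct = report$agreement_rate_pct,
    concurrent_table = report$concurrent_table,
    config = unclass(report$config)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null", null = "null")
  if (!is.null(markdown_path)) {
    writeLines(report_markdown(report), markdown_path)
  }
  invisible(path)
}

md_table <- function(df, digits = 3) {
  fmt <- function(v) {
    if (is.numeric(v)) ifelse(is.na(v), "", format(round(v, digits))) else
      as.character(v)
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}

report_markdown <- function(report) {
  fc <- report$filter_counts
  c(
    "# IFSAT validation report",
    "",
    sprintf("Participant flow: %d recruited, %d completed follow-up (%d dropouts), %d excluded for dermatologic-agent use, %d analyzed for cure period.",
            fc[["recruited"]], fc[["completed_followup"]], fc[["dropouts"]],
            fc[["agent_excluded"]], fc[["analyzed_for_cure"]]),
    "",
    "## Cure-period trend and AUC by scoring version and rater",
    "",
    md_table(report$trend_table[, c("version", "rater", "n_0_7", "median_0_7",
                                    "n_8_14", "median_8_14", "n_15_28",
                                    "median_15_28", "n_over_28",
                                    "median_over_28", "jt_p")]),
    "",
    md_table(report$auc_table),
    "",
    sprintf("Caregiver Youden cutoff (version %s): score >= %s (sensitivity %.2f, specificity %.2f, J = %.2f).",
            report$config$scoring_version, format(report$youden$cutoff),
            report$youden$sensitivity, report$youden$specificity,
            report$youden$j),
    "",
    "## Need vs no-need for medical treatment (Mann-Whitney U)",
    "",
    md_table(report$predictive_table),
    "",
    "## Reliability",
    "",
    if (!is.null(report$icc_intra)) {
      sprintf("- Intra-examiner ICC: %.2f (95%% CI %.2f-%.2f)",
              report$icc_intra$estimate, report$icc_intra$ci_low,
              report$icc_intra$ci_high)
    } else "- Intra-examiner ICC: not available (no two-occasion ratings)",
    vapply(names(report$icc_inter), function(nm) {
      r <- report$icc_inter[[nm]]
      if (is.null(r)) return(sprintf("- Inter-rater ICC (%s): not available", nm))
      sprintf("- Inter-rater ICC (%s): %.2f (95%% CI %.2f-%.2f)", nm,
              r$estimate, r$ci_low, r$ci_high)
    }, character(1)),
    sprintf("- Pediatrician agreement on treatment need: %s%%",
            format(report$agreement_rate_pct)),
    "",
    "## Concurrent validity (Spearman rho vs skin-barrier measures)",
    "",
    md_table(report$concurrent_table)
  )
}
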