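# Independent oracles used across the suite. These are deliberately coded
# from first principles (literal weight lists, explicit pair loops,
# exhaustive enumeration) and share no code with the package internals.

random_grid <- function(p = 0.3) {
  m <- matrix(runif(36) < p, 4, 9,
              dimnames = list(symptoms(), facial_areas("nine_area")))
  assessment_grid(m)
}

# Literal per-cell weight list for the nine-area version-1 method, typed out
# cell by cell from the doubled-item list.
oracle_v1_weight <- function(symptom, area) {
  doubled <- list(
    c("erythema", "left_forehead"), c("erythema", "right_forehead"),
    c("papules", "left_forehead"), c("papules", "right_forehead"),
    c("papules", "left_cheek"), c("papules", "right_cheek"),
    c("papules", "mouth_jaw")
  )
  if (symptom %in% c("dryness", "exudate_yellow_scaling")) return(2)
  for (d in doubled) if (d[1] == symptom && d[2] == area) return(2)
  1
}

# Literal weight list on the combined eight-area layout for version 2.
oracle_v2_weight <- function(symptom, area) {
  doubled <- list(
    c("erythema", "forehead"), c("papules", "forehead"),
    c("papules", "left_cheek"), c("papules", "right_cheek"),
    c("papules", "mouth_jaw")
  )
  if (symptom %in% c("dryness", "exudate_yellow_scaling")) return(2)
  for (d in doubled) if (d[1] == symptom && d[2] == area) return(2)
  1
}

oracle_scores <- function(grid) {
  sy <- rownames(grid)
  a9 <- colnames(grid)
  orig <- 0; v1 <- 0
  for (s in sy) for (a in a9) {
    if (grid[s, a]) {
      orig <- orig + 1
      v1 <- v1 + oracle_v1_weight(s, a)
    }
  }
  # combine foreheads by OR, then apply the eight-area list
  a8 <- c("scalp_hairline", "forehead", "eyebrows_eyes", "nose",
          "right_cheek", "left_cheek", "mouth_jaw", "ears")
  v2 <- 0
  for (s in sy) for (a in a8) {
    present <- if (a == "forehead") {
      grid[s, "left_forehead"] || grid[s, "right_forehead"]
    } else grid[s, a]
    if (present) v2 <- v2 + oracle_v2_weight(s, a)
  }
  c(original = orig, v1 = v1, v2 = v2)
}

# Brute-force tie-adjusted AUC: loop over every positive-negative pair.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Brute-force JT count: explicit loops over ordered group pairs.
brute_jt <- function(groups) {
  k <- length(groups); tot <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    for (a in groups[[i]]) for (b in groups[[j]]) {
      tot <- tot + if (b > a) 1 else if (b == a) 0.5 else 0
    }
  }
  tot
}

# Exhaustive permutation distribution of the JT count, enumerating every
# assignment of the pooled values to the ordered group sizes.
oracle_jt_perm <- function(groups) {
  sizes <- lengths(groups)
  pooled <- unlist(groups)
  stats_out <- numeric(0)
  recurse <- function(remaining, built) {
    gi <- length(built) + 1L
    if (gi == length(sizes)) {
      gs <- c(built, list(pooled[remaining]))
      stats_out[length(stats_out) + 1L] <<- brute_jt(gs)
      return(invisible(NULL))
    }
    for (pick in utils::combn(remaining, sizes[gi], simplify = FALSE)) {
      recurse(setdiff(remaining, pick), c(built, list(pooled[pick])))
    }
  }
  recurse(seq_along(pooled), list())
  stats_out
}

# Two-way ANOVA mean squares computed by definition sums (not via aov or
# the package), for the ICC oracle.
oracle_two_way_ms <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- sum(m) / (n * k)
  ssr <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (mean(m[i, ]) - grand)^2
  ssc <- 0
  for (j in seq_len(k)) ssc <- ssc + n * (mean(m[, j]) - grand)^2
  sse <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) {
    sse <- sse + (m[i, j] - mean(m[i, ]) - mean(m[, j]) + grand)^2
  }
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)))
}

# Small constructed cohort: observed grids identical across raters, cure
# period a supplied function of the caregiver v2 score.
make_constructed_cohort <- function(n, cure_fun, agent = rep(FALSE, n),
                                    dropout = rep(FALSE, n),
                                    needs_cut = NULL, seed = 11) {
  set.seed(seed)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    g <- random_grid(p = runif(1, 0.05, 0.6))
    s <- score_v2(g)
    cure <- cure_fun(s)
    records[[i]] <- list(
      infant_id = sprintf("C%03d", i), severity = s, true_grid = g,
      grids = list(pediatrician = g, nurse = g, caregiver = g),
      needs_treatment = if (is.null(needs_cut)) FALSE else s >= needs_cut,
      needs_treatment_rater2 = NA,
      used_dermatologic_agent = agent[i], dropout = dropout[i],
      cure_period_days = if (cure > 28) NA_integer_ else as.integer(cure),
      censored = cure > 28,
      tewl = rnorm(1, 12, 4), sch = rnorm(1, 40, 12),
      sebum = abs(rnorm(1, 8, 6))
    )
  }
  structure(records, class = "ifsat_cohort")
}
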