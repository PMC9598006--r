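#' Jonckheere-Terpstra test for an ordered trend across groups
#'
#' Tests for a monotone trend in a numeric response across k >= 3 a-priori
#' ordered groups. The statistic is the sum over ordered group pairs
#' (i < j) of Mann-Whitney counts: pairs where the later group's value
#' exceeds the earlier group's count 1, ties count 1/2. Under the null of
#' identical distributions the statistic has mean `sum(n_i n_j) / 2`; the
#' asymptotic p-value uses the tie-corrected normal approximation with a
#' continuity correction of 1/2, and the exact method evaluates the
#' permutation distribution of group labels (exhaustively when feasible,
#' otherwise by seeded Monte Carlo resampling).
#'
#' @param groups List of numeric vectors, one per group, in hypothesized
#'   order (lowest to highest response).
#' @param sidedness `"two_sided"` (default) or `"increasing"` (upper tail).
#' @param method `"auto"` uses the exact permutation distribution when the
#'   total sample size is at most `exact_n_max`, else the asymptotic
#'   approximation; `"asymptotic"` and `"exact"` force a choice.
#' @param exact_n_max Largest total N for which `"auto"` picks the exact
#'   method.
#' @param max_arrangements When the number of distinct label arrangements
#'   exceeds this, the exact method switches to Monte Carlo sampling.
#' @param n_mc Number of Monte Carlo permutations for the fallback.
#' @param mc_seed Seed for the Monte Carlo fallback (local to the call;
#'   the global RNG state is untouched).
#' @return An object of class `jt_test`: list with `statistic` (JT count),
#'   `null_mean`, `null_sd`, `p_value`, `method`
#'   (`"asymptotic_tie_corrected"` or `"exact_permutation"`), `sidedness`,
#'   `n` (group sizes).
#' @export
#' @examples
#' jonckheere_terpstra(list(c(1, 2), c(3, 4), c(5, 6)))$statistic  # 12
jonckheere_terpstra <- function(groups,
                                sidedness = c("two_sided", "increasing"),
                                method = c("auto", "asymptotic", "exact"),
                                exact_n_max = 20,
                                max_arrangements = 2e4,
                                n_mc = 10000,
                                mc_seed = 1L) {
  sidedness <- match.arg(sidedness)
  method <- match.arg(method)
  groups <- lapply(groups, as.numeric)
  if (length(groups) < 3) {
    stop("a trend needs at least 3 ordered groups", call. = FALSE)
  }
  sizes <- lengths(groups)
  if (any(sizes == 0)) stop("every group must be non-empty", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  if (anyNA(x)) stop("missing values are not supported", call. = FALSE)
  n_tot <- length(x)
  if (length(unique(x)) == 1) {
    stop("all observations are identical; the trend statistic has zero variance",
         call. = FALSE)
  }
  g <- rep(seq_along(groups), sizes)

  stat <- jt_statistic(x, g)
  null_mean <- sum(utils::combn(sizes, 2, function(p) p[1] * p[2])) / 2
  null_sd <- sqrt(jt_null_variance(sizes, x))

  if (method == "auto") {
    method <- if (n_tot <= exact_n_max) "exact" else "asymptotic"
  }

  if (method == "asymptotic") {
    p <- jt_tail_p(stat, null_mean, null_sd, sidedness)
    used <- "asymptotic_tie_corrected"
  } else {
    n_arr <- n_arrangements(sizes)
    if (n_arr <= max_arrangements) {
      stats_perm <- jt_exact_distribution(x, sizes)
    } else {
      stats_perm <- local_seed(mc_seed, {
        replicate(n_mc, jt_statistic(sample(x), g))
      })
    }
    p <- perm_p(stat, stats_perm, null_mean, sidedness)
    used <- "exact_permutation"
  }

  structure(
    list(statistic = stat, null_mean = null_mean, null_sd = null_sd,
         p_value = p, method = used, sidedness = sidedness, n = sizes),
    class = "jt_test"
  )
}

#' @export
print.jt_test <- function(x, ...) {
  cat("Jonckheere-Terpstra trend test (", x$method, ")\n", sep = "")
  cat("  groups:", paste(x$n, collapse = ", "),
      " JT =", format(x$statistic),
      " E0 =", format(x$null_mean),
      " sd0 =", format(round(x$null_sd, 4)), "\n")
  cat("  ", x$sidedness, " p = ", format.pval(x$p_value), "\n", sep = "")
  invisible(x)
}

# JT count from pooled data and group indices: sum over i<j of wins + half-ties.
jt_statistic <- function(x, g) {
  k <- max(g)
  total <- 0
  for (i in seq_len(k - 1)) {
    xi <- x[g == i]
    for (j in seq((i + 1), k)) {
      xj <- x[g == j]
      cmp <- outer(xj, xi, "-")
      total <- total + sum(cmp > 0) + 0.5 * sum(cmp == 0)
    }
  }
  total
}

# Tie-corrected null variance of the JT statistic (Hollander & Wolfe form).
jt_null_variance <- function(sizes, x) {
  n <- sum(sizes)
  t_j <- table(x)
  term1 <- (n * (n - 1) * (2 * n + 5) -
              sum(sizes * (sizes - 1) * (2 * sizes + 5)) -
              sum(t_j * (t_j - 1) * (2 * t_j + 5))) / 72
  term2 <- sum(sizes * (sizes - 1) * (sizes - 2)) *
    sum(t_j * (t_j - 1) * (t_j - 2)) /
    (36 * n * (n - 1) * (n - 2))
  term3 <- sum(sizes * (sizes - 1)) * sum(t_j * (t_j - 1)) /
    (8 * n * (n - 1))
  term1 + term2 + term3
}

# Normal-approximation tail probability with continuity correction.
jt_tail_p <- function(stat, null_mean, null_sd, sidedness) {
  if (null_sd <= 0) stop("zero null variance", call. = FALSE)
  if (sidedness == "increasing") {
    z <- (stat - null_mean - 0.5) / null_sd
    return(min(1, stats::pnorm(z, lower.tail = FALSE)))
  }
  z <- (abs(stat - null_mean) - 0.5) / null_sd
  min(1, 2 * stats::pnorm(max(z, 0), lower.tail = FALSE))
}

# Number of distinct ordered assignments of pooled values to groups.
n_arrangements <- function(sizes) {
  exp(lgamma(sum(sizes) + 1) - sum(lgamma(sizes + 1)))
}

# Exhaustive permutation distribution of the JT statistic: recursively choose
# which pooled indices land in each group (multiset permutations of labels).
jt_exact_distribution <- function(x, sizes) {
  out <- numeric(0)
  k <- length(sizes)
  recurse <- function(remaining, assigned) {
    gi <- length(assigned) + 1L
    if (gi == k) {
      groups_idx <- c(assigned, list(remaining))
      g <- integer(length(x))
      for (ii in seq_len(k)) g[groups_idx[[ii]]] <- ii
      out[[length(out) + 1L]] <<- jt_statistic(x, g)
      return(invisible(NULL))
    }
    picks <- utils::combn(remaining, sizes[gi], simplify = FALSE)
    for (p in picks) recurse(setdiff(remaining, p), c(assigned, list(p)))
  }
  recurse(seq_along(x), list())
  unlist(out)
}

# Permutation p-value: upper tail for "increasing", symmetric deviation
# around the null mean for "two_sided".
perm_p <- function(stat, perm_stats, null_mean, sidedness) {
  eps <- 1e-9
  if (sidedness == "increasing") {
    return(mean(perm_stats >= stat - eps))
  }
  mean(abs(perm_stats - null_mean) >= abs(stat - null_mean) - eps)
}

# Evaluate `expr` under a temporary RNG state.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Empirical ROC curve with tie-adjusted AUC and Youden cutoff
#'
#' Builds the empirical receiver operating characteristic of a numeric score
#' against a binary outcome, with the orientation "positive = score at or
#' above the cutoff". The AUC is computed by direct positive-negative pair
#' counting with ties contributing 1/2, i.e. the tie-adjusted Mann-Whitney
#' concordance probability. Candidate cutoffs are the distinct observed
#' scores plus one value above the maximum (the all-negative operating
#' point); the Youden cutoff is the smallest cutoff maximizing
#' J = sensitivity + specificity - 1, favoring sensitivity on ties.
#'
#' @param scores Numeric vector.
#' @param labels Binary vector (0/1 or logical) of the same length; 1 = case.
#' @return An object of class `roc_result`: list with `thresholds`,
#'   `sensitivity`, `specificity` (parallel vectors), `auc`,
#'   `youden_cutoff`, `youden_sensitivity`, `youden_specificity`,
#'   `youden_j`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' r <- empirical_roc(c(1, 2, 2, 3), c(0, 1, 0, 1))
#' r$auc  # 0.875
empirical_roc <- function(scores, labels) {
  scores <- as.numeric(scores)
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) {
    stop("`scores` and `labels` must have equal length", call. = FALSE)
  }
  if (anyNA(scores) || anyNA(labels)) {
    stop("missing values are not supported", call. = FALSE)
  }
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) {
    stop("AUC is undefined unless both outcome classes are present",
         call. = FALSE)
  }
  cmp <- outer(pos, neg, "-")
  auc <- (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / (length(pos) * length(neg))

  thr <- c(sort(unique(scores)), max(scores) + 1)
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg < t), numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)[1]

  structure(
    list(thresholds = thr, sensitivity = sens, specificity = spec, auc = auc,
         youden_cutoff = thr[best], youden_sensitivity = sens[best],
         youden_specificity = spec[best], youden_j = j[best],
         n_pos = length(pos), n_neg = length(neg)),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat("Empirical ROC:", x$n_pos, "cases /", x$n_neg, "controls\n")
  cat("  AUC =", format(round(x$auc, 4)), "\n")
  cat("  Youden cutoff >=", format(x$youden_cutoff),
      " sens =", format(round(x$youden_sensitivity, 3)),
      " spec =", format(round(x$youden_specificity, 3)),
      " J =", format(round(x$youden_j, 3)), "\n")
  invisible(x)
}

#' Youden operating point of an ROC curve
#'
#' `youden_cutoff()` extracts the selected operating point from a
#' [empirical_roc()] result; `youden_j()` is the defining identity
#' J = sensitivity + specificity - 1.
#'
#' @param roc An object returned by [empirical_roc()].
#' @return `youden_cutoff()`: list with `cutoff`, `sensitivity`,
#'   `specificity`, `j`. `youden_j()`: numeric J.
#' @export
youden_cutoff <- function(roc) {
  if (!inherits(roc, "roc_result")) {
    stop("expected a `roc_result` from empirical_roc()", call. = FALSE)
  }
  list(cutoff = roc$youden_cutoff, sensitivity = roc$youden_sensitivity,
       specificity = roc$youden_specificity, j = roc$youden_j)
}

#' @rdname youden_cutoff
#' @param sensitivity,specificity Proportions in \[0, 1\].
#' @export
youden_j <- function(sensitivity, specificity) {
  sensitivity + specificity - 1
}

#' Two-way intraclass correlation coefficient
#'
#' Single-measure ICC from the two-way crossed design (every rater or
#' occasion rates every subject), computed from the two-way ANOVA mean
#' squares. Both the absolute-agreement form ICC(A,1) — two-way random
#' effects, raters a random sample, systematic rater differences count as
#' disagreement — and the consistency form ICC(C,1) are available; absolute
#' agreement is the default. 95% confidence intervals use the standard
#' F-distribution construction (Satterthwaite degrees of freedom for the
#' agreement form).
#'
#' @param ratings Numeric matrix, subjects in rows, raters/occasions in
#'   columns; no missing cells.
#' @param form `"agreement"` (ICC(A,1), default) or `"consistency"`
#'   (ICC(C,1)).
#' @param conf_level Confidence level for the interval.
#' @return An object of class `icc_result`: list with `estimate`, `ci_low`,
#'   `ci_high`, `model` (descriptor string), `form`, `n_subjects`,
#'   `n_raters`, and the mean squares `ms` (MSR, MSC, MSE).
#' @export
#' @examples
#' m <- cbind(1:6, 1:6 + 0.1)
#' icc_two_way(m)$estimate  # close to 1
icc_two_way <- function(ratings, form = c("agreement", "consistency"),
                        conf_level = 0.95) {
  form <- match.arg(form)
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("missing cells are not supported", call. = FALSE)
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 2 || k < 2) {
    stop("need at least 2 subjects and 2 raters/occasions", call. = FALSE)
  }

  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols

  msr <- ss_rows / (n - 1)       # between subjects
  msc <- ss_cols / (k - 1)       # between raters
  mse <- ss_err / ((n - 1) * (k - 1))

  if (msr <= 0 && msc <= 0 && mse <= 0) {
    stop("all variance components are zero; ICC undefined", call. = FALSE)
  }

  alpha <- 1 - conf_level
  if (form == "agreement") {
    denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
    if (denom == 0) stop("zero denominator; ICC undefined", call. = FALSE)
    est <- (msr - mse) / denom
    # Satterthwaite df for the (a*MSC + b*MSE) combination
    a <- (k * est) / (n * (1 - est))
    b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    ci_low <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    ci_high <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    model <- "two-way random effects, absolute agreement, single measure"
  } else {
    denom <- msr + (k - 1) * mse
    if (denom == 0) stop("zero denominator; ICC undefined", call. = FALSE)
    est <- (msr - mse) / denom
    f_obs <- msr / mse
    f_l <- f_obs / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    f_u <- f_obs * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    ci_low <- (f_l - 1) / (f_l + k - 1)
    ci_high <- (f_u - 1) / (f_u + k - 1)
    model <- "two-way random effects, consistency, single measure"
  }

  structure(
    list(estimate = est, ci_low = ci_low, ci_high = ci_high, model = model,
         form = form, n_subjects = n, n_raters = k,
         ms = c(MSR = msr, MSC = msc, MSE = mse),
         conf_level = conf_level),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat("ICC (", x$model, ")\n", sep = "")
  cat("  estimate =", format(round(x$estimate, 3)),
      sprintf(" %d%% CI [%.3f, %.3f]", round(100 * x$conf_level),
              x$ci_low, x$ci_high), "\n")
  cat("  ", x$n_subjects, "subjects x", x$n_raters, "raters/occasions\n")
  invisible(x)
}

#' Mann-Whitney U comparison of two samples
#'
#' U counts the pairs where an `x` observation exceeds a `y` observation,
#' ties counting 1/2 (so `U = 0` means every `x` falls below every `y`). The
#' p-value uses exhaustive enumeration of label assignments when the
#' combined sample size is small and the tie-corrected normal approximation
#' with continuity correction otherwise. Group medians and interquartile
#' ranges (25th-75th percentile, linear-interpolation quantiles) are
#' attached for reporting.
#'
#' @param x,y Non-empty numeric vectors.
#' @param alternative `"two_sided"` (default), `"greater"` (x tends larger)
#'   or `"less"`.
#' @param method `"auto"` (exact when `length(x) + length(y) <= exact_n_max`),
#'   `"exact"`, or `"asymptotic"`.
#' @param exact_n_max Combined-size limit for the automatic exact method.
#' @return An object of class `mw_test`: list with `u_statistic`, `p_value`,
#'   `method`, `alternative`, and per-group `summary` (n, median, q25, q75).
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$u_statistic  # 0
mann_whitney_u <- function(x, y,
                           alternative = c("two_sided", "greater", "less"),
                           method = c("auto", "exact", "asymptotic"),
                           exact_n_max = 12) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported", call. = FALSE)
  nx <- length(x); ny <- length(y); n <- nx + ny

  u <- mw_u_statistic(x, y)

  if (method == "auto") {
    method <- if (n <= exact_n_max) "exact" else "asymptotic"
  }

  null_mean <- nx * ny / 2
  if (method == "exact") {
    pooled <- c(x, y)
    idx_sets <- utils::combn(n, nx, simplify = FALSE)
    us <- vapply(idx_sets, function(ix) {
      mw_u_statistic(pooled[ix], pooled[-ix])
    }, numeric(1))
    eps <- 1e-9
    p <- switch(alternative,
      greater = mean(us >= u - eps),
      less = mean(us <= u + eps),
      two_sided = mean(abs(us - null_mean) >= abs(u - null_mean) - eps)
    )
    used <- "exact_permutation"
  } else {
    pooled <- c(x, y)
    t_j <- table(pooled)
    sigma2 <- nx * ny / 12 *
      ((n + 1) - sum(t_j^3 - t_j) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      sigma <- sqrt(sigma2)
      p <- switch(alternative,
        greater = stats::pnorm((u - null_mean - 0.5) / sigma, lower.tail = FALSE),
        less = stats::pnorm((u - null_mean + 0.5) / sigma),
        two_sided = min(1, 2 * stats::pnorm(
          (max(abs(u - null_mean) - 0.5, 0)) / sigma, lower.tail = FALSE))
      )
      p <- min(1, p)
    }
    used <- "asymptotic_tie_corrected"
  }

  summ <- rbind(five_num(x), five_num(y))
  rownames(summ) <- c("x", "y")

  structure(
    list(u_statistic = u, p_value = p, method = used,
         alternative = alternative, summary = summ),
    class = "mw_test"
  )
}

# U = #(x_i > y_j) + 1/2 #(x_i == y_j), via midranks.
mw_u_statistic <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

five_num <- function(v) {
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(n = length(v), median = q[2], q25 = q[1], q75 = q[3])
}

#' @export
print.mw_test <- function(x, ...) {
  cat("Mann-Whitney U test (", x$method, ")\n", sep = "")
  cat("  U =", format(x$u_statistic), " ", x$alternative,
      " p =", format.pval(x$p_value), "\n")
  print(round(x$summary, 3))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks; ties receive average ranks.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in \[-1, 1\].
#' @export
#' @examples
#' spearman_rho(1:5, c(2, 4, 6, 8, 10))  # 1
spearman_rho <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("equal lengths required", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  stats::cor(rx, ry)
}

#' Percent agreement between two binary vectors
#'
#' @param a,b Equal-length binary (0/1 or logical) vectors.
#' @return Percentage of positions where `a == b`, in \[0, 100\].
#' @export
#' @examples
#' agreement_rate(c(1, 1, 0, 0), c(1, 1, 0, 1))  # 75
agreement_rate <- function(a, b) {
  a <- as.integer(as.logical(a)); b <- as.integer(as.logical(b))
  if (length(a) != length(b)) {
    stop("vectors must have equal length", call. = FALSE)
  }
  if (!length(a)) stop("vectors must be non-empty", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("missing values are not supported", call. = FALSE)
  100 * mean(a == b)
}
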