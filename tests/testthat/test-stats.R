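test_that("JT statistic equals brute-force pair counting at the extremes and in general", {
  expect_equal(jonckheere_terpstra(list(c(1, 2), c(3, 4), c(5, 6)))$statistic, 12)
  expect_equal(jonckheere_terpstra(list(c(5, 6), c(3, 4), c(1, 2)))$statistic, 0)

  set.seed(42)
  for (i in 1:30) {
    groups <- lapply(sample(2:4, 3, replace = TRUE),
                     function(n) sample(1:6, n, replace = TRUE))
    if (length(unique(unlist(groups))) == 1) next
    expect_equal(jonckheere_terpstra(groups, method = "asymptotic")$statistic,
                 brute_jt(groups))
  }
})

test_that("JT exact p-value matches exhaustive arrangement enumeration", {
  groups <- list(c(1, 2), c(3, 4), c(5, 6))
  perm <- oracle_jt_perm(groups)
  obs <- brute_jt(groups)
  jt_inc <- jonckheere_terpstra(groups, sidedness = "increasing", method = "exact")
  expect_equal(jt_inc$p_value, mean(perm >= obs))
  expect_equal(jt_inc$method, "exact_permutation")

  null_mean <- (2 * 2 + 2 * 2 + 2 * 2) / 2
  jt_two <- jonckheere_terpstra(groups, sidedness = "two_sided", method = "exact")
  expect_equal(jt_two$p_value, mean(abs(perm - null_mean) >= abs(obs - null_mean)))

  # with ties
  groups_t <- list(c(1, 1, 2), c(2, 3), c(3, 3))
  perm_t <- oracle_jt_perm(groups_t)
  obs_t <- brute_jt(groups_t)
  jt_t <- jonckheere_terpstra(groups_t, sidedness = "increasing", method = "exact")
  expect_equal(jt_t$p_value, mean(perm_t >= obs_t - 1e-9))
})

test_that("reversing group order complements the JT count for tie-free data", {
  set.seed(7)
  for (i in 1:20) {
    sizes <- sample(2:4, 3, replace = TRUE)
    vals <- sample(1:100, sum(sizes))  # no ties
    groups <- split(vals, rep(seq_along(sizes), sizes))
    jt <- jonckheere_terpstra(groups, method = "asymptotic")$statistic
    jt_rev <- jonckheere_terpstra(rev(groups), method = "asymptotic")$statistic
    max_pairs <- sum(utils::combn(sizes, 2, function(p) p[1] * p[2]))
    expect_equal(jt + jt_rev, max_pairs)
  }
})

test_that("JT rejects degenerate inputs", {
  expect_error(jonckheere_terpstra(list(1:3, 4:6)), "at least 3")
  expect_error(jonckheere_terpstra(list(1:2, numeric(0), 1:2)), "non-empty")
  expect_error(jonckheere_terpstra(list(c(2, 2), c(2, 2), c(2, 2))),
               "zero variance")
})

test_that("empirical AUC equals brute-force pair counting with half-ties", {
  expect_equal(empirical_roc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1.0)
  expect_equal(empirical_roc(c(3, 3, 3, 3), c(0, 1, 0, 1))$auc, 0.5)
  expect_equal(empirical_roc(c(1, 2, 2, 3), c(0, 1, 0, 1))$auc, 0.875)

  set.seed(12)
  for (i in 1:40) {
    n <- sample(6:20, 1)
    sc <- sample(1:8, n, replace = TRUE)
    lb <- rbinom(n, 1, 0.4)
    if (length(unique(lb)) < 2) next
    expect_equal(empirical_roc(sc, lb)$auc, brute_auc(sc, lb))
  }
  expect_error(empirical_roc(1:4, c(1, 1, 1, 1)), "both outcome classes")
})

test_that("AUC is invariant under strictly increasing transforms and complements under label swap", {
  set.seed(23)
  maps <- list(function(x) 2 * x + 1, exp, function(x) x^3, atan)
  for (i in 1:25) {
    n <- sample(8:25, 1)
    sc <- sample(1:10, n, replace = TRUE)
    lb <- rbinom(n, 1, 0.5)
    if (length(unique(lb)) < 2) next
    a <- empirical_roc(sc, lb)$auc
    f <- maps[[sample(length(maps), 1)]]
    expect_equal(empirical_roc(f(sc), lb)$auc, a)
    expect_equal(a + empirical_roc(sc, 1 - lb)$auc, 1)
  }
})

test_that("empirical AUC agrees with an independent ROC library", {
  skip_if_not_installed("pROC")
  set.seed(9)
  for (i in 1:10) {
    sc <- sample(1:12, 30, replace = TRUE)
    lb <- rbinom(30, 1, 0.3)
    if (length(unique(lb)) < 2) next
    ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                          direction = "<")))
    expect_equal(empirical_roc(sc, lb)$auc, ref)
  }
})

test_that("Youden selection maximizes J over enumerated cutoffs, smallest cutoff on ties", {
  r <- empirical_roc(c(1, 2, 3, 4, 5, 6), c(0, 0, 0, 1, 1, 1))
  y <- youden_cutoff(r)
  expect_equal(y$j, 1)
  expect_equal(y$cutoff, 4)  # positive means score >= cutoff

  set.seed(3)
  for (i in 1:30) {
    n <- sample(8:25, 1)
    sc <- sample(1:6, n, replace = TRUE)
    lb <- rbinom(n, 1, 0.5)
    if (length(unique(lb)) < 2) next
    r <- empirical_roc(sc, lb)
    # exhaustive enumeration over every candidate cutoff
    cand <- c(sort(unique(sc)), max(sc) + 1)
    js <- sapply(cand, function(t) mean(sc[lb == 1] >= t) + mean(sc[lb == 0] < t) - 1)
    expect_equal(r$youden_j, max(js))
    expect_equal(r$youden_cutoff, cand[which(js >= max(js) - 1e-12)[1]])
  }
})

test_that("two-way ICC matches a definition-sums ANOVA oracle and handles edge structure", {
  # identical columns with subject variation: perfect agreement
  m <- cbind(1:6, 1:6)
  expect_equal(icc_two_way(m)$estimate, 1)

  m4 <- matrix(c(9, 2, 5, 8,
                 6, 1, 3, 2), ncol = 2)
  res <- icc_two_way(m4, form = "agreement")
  ms <- oracle_two_way_ms(m4)
  n <- 4; k <- 2
  expected <- (ms$msr - ms$mse) /
    (ms$msr + (k - 1) * ms$mse + (k / n) * (ms$msc - ms$mse))
  expect_equal(res$estimate, expected)
  expect_equal(unname(res$ms["MSR"]), ms$msr)
  expect_equal(unname(res$ms["MSC"]), ms$msc)
  expect_equal(unname(res$ms["MSE"]), ms$mse)
  expect_lte(res$ci_low, res$estimate)
  expect_gte(res$ci_high, res$estimate)

  resc <- icc_two_way(m4, form = "consistency")
  expect_equal(resc$estimate,
               (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse))

  expect_error(icc_two_way(matrix(1, 1, 2)), "at least 2")
  expect_error(icc_two_way(matrix(3, 5, 3)), "undefined")
})

test_that("ICC of pure noise columns centers on zero", {
  set.seed(64)
  est <- replicate(400, icc_two_way(matrix(rnorm(30 * 2), 30, 2))$estimate)
  expect_lt(abs(mean(est)), 0.05)
})

test_that("Mann-Whitney U counts x-over-y wins and its exact p matches enumeration", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$u_statistic, 0)
  expect_equal(mann_whitney_u(c(4, 5, 6), c(1, 2, 3))$u_statistic, 9)

  same <- mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$p_value, 1, tolerance = 1e-9)

  set.seed(20)
  for (i in 1:20) {
    nx <- sample(3:5, 1); ny <- sample(3:5, 1)
    x <- sample(1:6, nx, replace = TRUE)
    y <- sample(1:6, ny, replace = TRUE)
    res <- mann_whitney_u(x, y, method = "exact")
    # enumeration oracle: all label assignments of the pooled sample
    pooled <- c(x, y)
    null_mean <- nx * ny / 2
    us <- utils::combn(nx + ny, nx, function(ix) {
      xs <- pooled[ix]; ys <- pooled[-ix]
      tot <- 0
      for (a in xs) for (b in ys) tot <- tot + (a > b) + 0.5 * (a == b)
      tot
    })
    expect_equal(res$u_statistic, sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "==")))
    expect_equal(res$p_value,
                 mean(abs(us - null_mean) >= abs(res$u_statistic - null_mean) - 1e-9))
  }
})

test_that("Mann-Whitney asymptotic p agrees with the standard library implementation", {
  set.seed(77)
  for (i in 1:10) {
    x <- rnorm(20); y <- rnorm(25, 0.5)  # tie-free
    ours <- mann_whitney_u(x, y, method = "asymptotic")$p_value
    ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-10)
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney summaries carry medians and type-7 IQRs per group", {
  res <- mann_whitney_u(c(1, 2, 3, 10), c(4, 4, 5))
  expect_equal(unname(res$summary["x", "median"]), 2.5)
  expect_equal(unname(res$summary["x", "q25"]),
               unname(stats::quantile(c(1, 2, 3, 10), 0.25)))
  expect_true(all(res$summary[, "q25"] <= res$summary[, "median"]))
  expect_true(all(res$summary[, "median"] <= res$summary[, "q75"]))
})

test_that("Spearman rho is the Pearson correlation of midranks", {
  expect_equal(spearman_rho(1:5, (1:5)^3), 1)
  expect_equal(spearman_rho(1:5, rev(1:5)), -1)

  set.seed(15)
  for (i in 1:20) {
    x <- sample(1:5, 12, replace = TRUE)
    y <- sample(1:5, 12, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearman_rho(x, y),
                 stats::cor(x, y, method = "spearman"))
    expect_equal(spearman_rho(x, y), stats::cor(rank(x), rank(y)))
  }
  expect_error(spearman_rho(c(2, 2, 2), 1:3), "constant")
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})

test_that("agreement rate is a symmetric percent match", {
  expect_equal(agreement_rate(c(1, 0, 1), c(1, 0, 1)), 100)
  expect_equal(agreement_rate(c(1, 0), c(0, 1)), 0)
  a <- c(rep(1, 10), rep(0, 10))
  b <- a; b[c(3, 17)] <- 1 - b[c(3, 17)]
  expect_equal(agreement_rate(a, b), 90)
  expect_equal(agreement_rate(a, b), agreement_rate(b, a))
  expect_error(agreement_rate(c(1, 0), c(1, 0, 1)), "equal length")
})
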