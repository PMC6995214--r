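test_that("Kaplan-Meier estimate equals the hand-computed product limit", {
  # simple all-event case
  km <- km_estimate(surv_fixture(c(1, 2, 3), c(1, 1, 1)))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # all censored -> S(t) = 1 everywhere
  km2 <- km_estimate(surv_fixture(c(1, 2, 3), c(0, 0, 0)))
  expect_true(all(km2$surv == 1))
  # ties and censoring, against a manual product-limit table:
  # times 1(d),1(d),2(c),3(d),3(d),4(c),5(d),5(c)
  fx <- surv_fixture(c(1, 1, 2, 3, 3, 4, 5, 5),
                     c(1, 1, 0, 1, 1, 0, 1, 0))
  km3 <- km_estimate(fx)
  # manual: S(1)=6/8; S(3)=6/8*3/5; S(5)=6/8*3/5*1/2
  s <- km3$surv[match(c(1, 3, 5), km3$time)]
  expect_equal(s, c(6 / 8, 6 / 8 * 3 / 5, 6 / 8 * 3 / 5 * 1 / 2),
               tolerance = 1e-12)
  # estimator is non-increasing and within [0, 1]
  expect_true(all(diff(km3$surv) <= 0))
  expect_true(all(km3$surv >= 0 & km3$surv <= 1))
  expect_error(km_estimate(surv_fixture(c(1, -2), c(1, 1))), "positive")
})

test_that("log-rank test handles identical groups and zero events", {
  fx <- surv_fixture(c(1, 2, 3, 4, 1, 2, 3, 4), rep(1L, 8))
  lr <- logrank_test(fx, rep(c("a", "b"), each = 4))
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)
  expect_equal(lr$df, 1)
  expect_warning(
    lr0 <- logrank_test(surv_fixture(1:6, rep(0L, 6)), rep(c("a", "b"), 3)),
    "no events")
  expect_equal(lr0$p, 1)
  expect_error(logrank_test(fx, rep("a", 8)), "two non-empty")
})

test_that("log-rank chi-square p agrees with a permutation null", {
  set.seed(41)
  time <- c(2, 4, 5, 7, 9, 12, 15, 18, 20, 24)
  event <- c(1, 1, 0, 1, 1, 1, 0, 1, 1, 0)
  group <- rep(c(0, 1), 5)
  fx <- surv_fixture(time, event)
  lr <- logrank_test(fx, group)
  n_perm <- 20000
  perms <- replicate(n_perm, sample(group))
  stats <- logrank_chisq_perm(time, event, perms)
  obs <- logrank_chisq_perm(time, event, matrix(group, ncol = 1))
  expect_equal(obs[1], lr$statistic, tolerance = 1e-8)
  p_perm <- (1 + sum(stats >= obs[1] - 1e-12)) / (n_perm + 1)
  mc_se <- sqrt(p_perm * (1 - p_perm) / n_perm)
  expect_lt(abs(lr$p - p_perm), 3 * mc_se + 0.01)
})

test_that("optimal cutpoint scan respects constraints and is self-consistent", {
  set.seed(8)
  n <- 60
  marker <- runif(n, 0, 100)
  fx <- surv_fixture(rexp(n, 0.02 * ifelse(marker > 50, 3, 1)),
                     rbinom(n, 1, 0.9))
  res <- optimal_cutpoint(fx, marker, criterion = "marker")
  # every admissible candidate leaves >= min_prop per side
  n_low <- vapply(res$scan$cutpoint, function(cp) sum(marker <= cp),
                  numeric(1))
  expect_true(all(n_low >= 0.1 * n & (n - n_low) >= 0.1 * n))
  # reported p equals a re-run log-rank at the returned cutpoint
  lr <- logrank_test(fx, ifelse(marker <= res$cutpoint, "low", "high"))
  expect_equal(res$p, lr$p, tolerance = 1e-12)
  expect_equal(res$statistic, lr$statistic, tolerance = 1e-12)
  # groups partition the cohort
  expect_setequal(res$groups$sample, fx$sample)
  expect_error(optimal_cutpoint(fx, rep(1, n)), "constant")
})

test_that("optimal cutpoint recovers a planted hazard step", {
  set.seed(12)
  n <- 200
  in_gap <- logical(10)
  for (r in 1:10) {
    # marker measured at 5-unit granularity: candidate cutpoints between
    # tied values move several samples at once
    marker <- c(sample(seq(5, 40, 5), n / 2, TRUE),
                sample(seq(60, 100, 5), n / 2, TRUE))
    hazard <- ifelse(marker > 50, 0.08, 0.02)
    fx <- surv_fixture(rexp(n, hazard), rep(1L, n))
    res <- optimal_cutpoint(fx, marker)
    in_gap[r] <- res$cutpoint > 40 && res$cutpoint < 60
    expect_lt(res$p, 1e-4)
  }
  expect_gte(mean(in_gap), 0.8)
  # low group has longer median survival (last replicate)
  km <- res$km
  med <- vapply(c("low", "high"), function(g) {
    k <- km[km$group == g, ]
    k$time[which(k$surv <= 0.5)[1]]
  }, numeric(1))
  expect_gt(med["low"], med["high"])
})

test_that("srCNV clustering splits a block matrix with full support", {
  m <- rbind(matrix(1L, 33, 6), matrix(0L, 77, 6))
  # small noise keeps rows non-identical
  set.seed(2)
  noise_col <- rbinom(110, 1, 0.5)
  m <- cbind(m, noise_col)
  rownames(m) <- sprintf("P%03d", 1:110)
  cl <- cluster_srcnv(m, n_boot = 200, seed = 4)
  tab <- table(cl$groups$group)
  expect_equal(unname(tab[["H"]]), 33)
  expect_equal(unname(tab[["L"]]), 77)
  expect_gt(cl$support[["H"]], 0.95)
  expect_gt(cl$support[["L"]], 0.95)
  # H has the higher mean burden by construction
  agg <- tapply(cl$groups$burden, cl$groups$group, mean)
  expect_gt(agg[["H"]], agg[["L"]])
  # labels invariant under sample permutation
  perm <- sample(110)
  cl2 <- cluster_srcnv(m[perm, ], n_boot = 50, seed = 4)
  expect_equal(
    cl2$groups$group[match(cl$groups$sample, cl2$groups$sample)],
    cl$groups$group)
  expect_error(cluster_srcnv(matrix(1L, 5, 3)), "degenerate")
})

test_that("single srCNV column splits carriers from non-carriers", {
  m <- matrix(c(rep(1L, 4), rep(0L, 6)), ncol = 1)
  rownames(m) <- paste0("s", 1:10)
  cl <- cluster_srcnv(m, n_boot = 50, seed = 1)
  expect_equal(cl$groups$group, rep(c("H", "L"), c(4, 6)))
})

test_that("joint stratification crosses labels and tests non-empty groups", {
  set.seed(6)
  n <- 120
  loh_high <- rep(c(FALSE, TRUE), each = n / 2)
  srcnv_high <- rep(c(FALSE, TRUE), n / 2)
  lp <- 0.7 * loh_high + 0.7 * srcnv_high
  fx <- surv_fixture(rexp(n, 0.02 * exp(lp)), rbinom(n, 1, 0.9))
  res <- joint_stratify(fx, loh_high, srcnv_high)
  expect_setequal(unique(res$groups$group),
                  c("ClLl", "ClLh", "ChLl", "ChLh"))
  expect_equal(res$df, 3)
  expect_lt(res$p, 0.05)
  # alignment invariance: permuting records and labels together
  perm <- sample(n)
  res2 <- joint_stratify(fx[perm, ], loh_high[perm], srcnv_high[perm])
  expect_equal(res2$p, res$p, tolerance = 1e-12)
  expect_equal(
    res2$groups$group[match(fx$sample, res2$groups$sample)],
    res$groups$group)
  # all samples in one cell -> no test, warning
  expect_warning(
    res3 <- joint_stratify(fx, rep(FALSE, n), rep(FALSE, n)),
    "fewer than two")
  expect_true(is.na(res3$p))
  expect_setequal(res3$empty_groups, c("ClLh", "ChLl", "ChLh"))
})

test_that("Cox fit recovers a known coefficient and scales increments", {
  set.seed(14)
  n <- 500
  x <- rnorm(n)
  fx <- surv_fixture(rexp(n, 0.05 * exp(0.7 * x)), rep(1L, n))
  fit <- cox_single(fx, x, term = "x")
  se <- (log(fit$conf_high) - log(fit$conf_low)) / (2 * 1.96 * fit$increment)
  expect_lt(abs(fit$coef - 0.7), 3 * se)  # single-replicate sanity bound
  # increment reparameterization identity
  fit1000 <- cox_single(fx, x, increment = 1000, term = "x")
  expect_equal(fit1000$hr, exp(fit$coef)^1000 *
                 exp(0), tolerance = 1e-9)
  expect_equal(log(fit1000$hr), 1000 * fit$coef, tolerance = 1e-9)
  # null covariate -> HR near 1
  set.seed(15)
  z <- rnorm(1000)
  fx0 <- surv_fixture(rexp(1000, 0.05), rep(1L, 1000))
  fit0 <- cox_single(fx0, z, term = "z")
  expect_gt(fit0$hr, 0.9)
  expect_lt(fit0$hr, 1.1)
  # percent normalization reports per-1% increments
  fitp <- cox_single(fx, x, percent = TRUE, term = "x")
  expect_equal(fitp$coef, fit$coef * diff(range(x)) / 100, tolerance = 1e-8)
  expect_error(cox_single(surv_fixture(1:4, rep(0L, 4)), 1:4), "no events")
})

test_that("Fisher's exact test matches full hypergeometric enumeration", {
  # zero margin -> p = 1
  expect_equal(fisher_exact(matrix(c(0, 0, 3, 5), 2)), 1)
  # enumeration oracle on the metastasis-style table
  tab <- matrix(c(8, 2, 6, 9), 2)
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n2, k)
  p_oracle <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  expect_equal(fisher_exact(tab), p_oracle, tolerance = 1e-12)
  # transpose symmetry
  expect_equal(fisher_exact(tab), fisher_exact(t(tab)), tolerance = 1e-12)
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("stratification objects print, tidy and glance coherently", {
  set.seed(3)
  n <- 40
  marker <- runif(n)
  fx <- surv_fixture(rexp(n, 0.05), rbinom(n, 1, 0.8))
  res <- optimal_cutpoint(fx, marker, criterion = "m")
  expect_output(print(res), "log-rank")
  td <- tidy(res)
  expect_equal(nrow(td), n)
  gl <- glance(res)
  expect_equal(gl$criterion, "m")
  expect_equal(gl$cutpoint, res$cutpoint)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})
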