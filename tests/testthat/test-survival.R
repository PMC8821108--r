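test_that("KM curve matches the hand product-limit computation", {
  # times (1+, 2, 3+, 4): S = 2/3 after t=2, 0 after t=4
  km <- km_curve(c(1, 2, 3, 4), c(0, 1, 0, 1))
  expect_equal(km$survival, c(1, 2 / 3, 2 / 3, 0))
  expect_equal(km$n_risk, c(4, 3, 2, 1))

  # all censored: S identically 1
  km0 <- km_curve(c(1, 2, 3), c(0, 0, 0))
  expect_equal(km0$survival, rep(1, 3))

  # duplicating every subject leaves the curve unchanged
  set.seed(31)
  tt <- rexp(40) + 0.1
  ev <- rbinom(40, 1, 0.6)
  k1 <- km_curve(tt, ev)
  k2 <- km_curve(rep(tt, 2), rep(ev, 2))
  expect_equal(k2$survival, k1$survival)

  expect_error(km_curve(numeric(0), numeric(0)), "no samples")
})

test_that("KM and log-rank agree with the survival package", {
  skip_if_not_installed("survival")
  set.seed(32)
  tt <- round(rexp(60), 1) + 0.1   # induce ties
  ev <- rbinom(60, 1, 0.7)
  g <- sample(c("a", "b", "c"), 60, TRUE)
  km <- km_curve(tt, ev)
  sf <- summary(survival::survfit(survival::Surv(tt, ev) ~ 1),
                times = km$time)
  expect_equal(km$survival, sf$surv, tolerance = 1e-12)
  lr <- logrank_test(tt, ev, g)
  sd <- survival::survdiff(survival::Surv(tt, ev) ~ g)
  expect_equal(lr$statistic, sd$chisq, tolerance = 1e-9)
})

test_that("log-rank is null for exchangeable groups and exact on a toy", {
  tt <- c(1, 2, 3, 4, 1, 2, 3, 4)
  ev <- c(1, 0, 1, 1, 1, 0, 1, 1)
  g <- rep(c("x", "y"), each = 4)
  lr <- logrank_test(tt, ev, g)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)

  # early deaths in A, late in B, no censoring: direct O/E/V tabulation
  tt2 <- c(1, 2, 3, 4)
  ev2 <- rep(1, 4)
  g2 <- c("A", "A", "B", "B")
  lr2 <- logrank_test(tt2, ev2, g2)
  orc <- oracle_logrank2(tt2, ev2, g2 == "A")
  expect_equal(lr2$statistic, orc$chi2, tolerance = 1e-12)

  expect_error(logrank_test(tt2, ev2, rep("A", 4)), "2 groups")
})

test_that("Cox fit maximizes the brute-force Efron partial likelihood", {
  # untied toy data, one covariate: compare to a grid-search maximizer
  tt <- c(3.1, 1.2, 5.4, 2.3, 4.5, 6.6)
  ev <- c(1, 1, 0, 1, 1, 1)
  x <- c(0.5, -1.2, 0.3, 1.8, -0.7, 0.9)
  fit <- cox_fit(tt, ev, cbind(x = x))
  grid <- seq(-2, 2, by = 1e-5)
  ll <- vapply(grid, oracle_cox_loglik, numeric(1), time = tt,
               event = ev, x = x)
  expect_equal(unname(fit$beta), grid[which.max(ll)], tolerance = 1e-4)
  expect_equal(fit$loglik, max(ll), tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("Cox fit agrees with survival::coxph under heavy ties", {
  skip_if_not_installed("survival")
  set.seed(33)
  n <- 120
  x1 <- rnorm(n)
  x2 <- rbinom(n, 1, 0.5)
  tt <- ceiling(rexp(n, exp(0.4 * x1 - 0.6 * x2)) * 4) / 4
  ev <- rbinom(n, 1, 0.75)
  fit <- cox_fit(tt, ev, cbind(a = x1, b = x2))
  ref <- survival::coxph(survival::Surv(tt, ev) ~ x1 + x2, ties = "efron")
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-7)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-7)
  expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-9)
})

test_that("Cox beta is null for a group-balanced covariate", {
  tt <- rep(c(1, 2, 3, 4, 5), 2)
  ev <- rep(c(1, 1, 0, 1, 0), 2)
  x <- rep(c(0, 1), each = 5)
  fit <- cox_fit(tt, ev, cbind(g = x))
  expect_lt(abs(fit$beta), 1e-6)
})

test_that("Cox fit flags separation and rejects bad inputs", {
  # perfectly separated: all early deaths have x = 1
  tt <- c(1, 2, 3, 10, 11, 12, 13, 14)
  ev <- rep(1, 8)
  x <- c(1, 1, 1, 0, 0, 0, 0, 0)
  expect_warning(fit <- cox_fit(tt, ev, cbind(x = x)), "monotone")
  expect_true(fit$separated)
  expect_lte(abs(unname(fit$beta)), 20)

  expect_error(cox_fit(tt, ev, cbind(k = rep(1, 8))), "constant")
  expect_error(cox_fit(tt[1:2], ev[1:2], cbind(a = 1:2, b = 2:1, c = c(1, 3))))
})

test_that("Cox recovers a known log-hazard ratio with nominal coverage", {
  set.seed(34)
  n_rep <- 60
  est <- se <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    x <- rnorm(300)
    tt <- rexp(300, rate = 0.1 * exp(0.5 * x))
    cens <- runif(300, 0, quantile(tt, 0.9) * 2)
    fit <- cox_fit(pmin(tt, cens), as.integer(tt <= cens), cbind(x = x))
    est[r] <- fit$beta
    se[r] <- fit$se
  }
  expect_lt(abs(mean(est) - 0.5), 0.05)
  cover <- mean(est - 1.96 * se <= 0.5 & 0.5 <= est + 1.96 * se)
  expect_gte(cover, 0.85)
})

test_that("best cutpoint reproduces an exhaustive scan", {
  set.seed(35)
  for (r in 1:5) {
    n <- 60
    sc <- rnorm(n)
    tt <- rexp(n, 0.2 * exp(0.5 * sc)) + 0.01
    ev <- rbinom(n, 1, 0.7)
    got <- best_cutpoint(sc, tt, ev, minprop = 0.1)
    # independent exhaustive scan over admissible distinct values
    vals <- sort(unique(sc))
    zbest <- -Inf
    cbest <- NA
    for (v in vals) {
      high <- sc > v
      if (sum(high) < ceiling(0.1 * n) || sum(!high) < ceiling(0.1 * n)) next
      orc <- oracle_logrank2(tt, ev, high)
      if (orc$v <= 0) next
      z <- abs(orc$oe) / sqrt(orc$v)
      if (z > zbest + 1e-12) { zbest <- z; cbest <- v }
    }
    expect_equal(abs(got$statistic), zbest, tolerance = 1e-9)
    expect_equal(sum(sc > got$cutpoint), sum(sc > cbest))
  }
})

test_that("cutpoint grouping is invariant under monotone transforms", {
  set.seed(36)
  sc <- rnorm(50)
  tt <- rexp(50, 0.2 * exp(0.6 * sc)) + 0.01
  ev <- rbinom(50, 1, 0.8)
  g1 <- dichotomize_score(sc, tt, ev)
  g2 <- dichotomize_score(exp(sc) + 5, tt, ev)
  expect_identical(g1, g2)
})

test_that("a separable score cuts between the clusters", {
  sc <- c(seq(-5, -4, length.out = 20), seq(4, 5, length.out = 20))
  tt <- c(seq(50, 60, length.out = 20), seq(1, 2, length.out = 20))
  ev <- rep(1, 40)   # high-score cluster dies first, deterministically
  cp <- best_cutpoint(sc, tt, ev, minprop = 0.1)
  expect_gt(cp$cutpoint, -4)
  expect_lt(cp$cutpoint, 4)
  expect_gt(cp$statistic, 0)  # high group at excess risk
  expect_error(best_cutpoint(sc[1:3], tt[1:3], ev[1:3], minprop = 0.49))
})

test_that("two-group log-rank chi-square equals the squared cutpoint statistic", {
  set.seed(37)
  sc <- rnorm(40)
  tt <- rexp(40, 0.3) + 0.01
  ev <- rbinom(40, 1, 0.7)
  cp <- best_cutpoint(sc, tt, ev)
  grp <- ifelse(sc > cp$cutpoint, "high", "low")
  lr <- logrank_test(tt, ev, grp)
  expect_equal(lr$statistic, cp$statistic^2, tolerance = 1e-9)
})
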