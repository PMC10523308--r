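test_that("Cox fit handles degenerate and toy inputs", {
  # no covariate variation: score at beta = 0 vanishes
  f <- fit_cox(matrix(1, 2, 1), time = c(1, 2), event = c(1, 1))
  expect_equal(unname(f$coefficients), 0)
  expect_equal(unname(f$wald), 0)

  expect_error(fit_cox(matrix(rnorm(4)), c(1, 2, 3, 4), c(0, 0, 0, 0)),
               "no events")
})

test_that("Cox coefficient matches grid-search maximization of the partial likelihood", {
  # n = 6 two-group exponential toy data, distinct times, all events
  x <- matrix(c(0, 0, 0, 1, 1, 1), ncol = 1)
  time <- c(3.1, 5.2, 9.4, 1.2, 2.3, 4.1)
  event <- rep(1, 6)
  grid <- seq(-4, 4, by = 1e-4)
  ll <- vapply(grid, oracle_cox_loglik, numeric(1), x = x,
               time = time, event = event)
  beta_grid <- grid[which.max(ll)]
  f <- fit_cox(x, time, event)
  expect_equal(unname(f$coefficients), beta_grid, tolerance = 1e-4)
})

test_that("Cox fit matches an independent Newton-Raphson oracle", {
  set.seed(11)
  n <- 30
  x <- matrix(rnorm(2 * n), n, 2)
  time <- rexp(n, 0.2 * exp(0.6 * x[, 1] - 0.4 * x[, 2]))
  event <- rbinom(n, 1, 0.8)
  event[1:2] <- 1
  f <- fit_cox(x, time, event)
  o <- oracle_cox_newton(x, time, event)
  expect_equal(unname(f$coefficients), o$beta, tolerance = 1e-6)
  expect_equal(unname(f$se), o$se, tolerance = 1e-6)
  expect_equal(unname(f$wald), (o$beta / o$se)^2, tolerance = 1e-5)
})

test_that("batch univariate Cox agrees with coxph with and without ties and offsets", {
  set.seed(21)
  n <- 60
  x <- matrix(rnorm(4 * n), n, 4)
  event <- rbinom(n, 1, 0.7)
  off <- rnorm(n)
  for (time in list(rexp(n, 0.1), ceiling(rexp(n, 0.1)) + 0.5)) {
    b <- cox_univariate_batch(x, time, event, offset = off)
    for (j in 1:4) {
      ref <- survival::coxph(survival::Surv(time, event) ~ x[, j] +
                               offset(off), ties = "efron")
      expect_equal(b$coefficients[j], unname(coef(ref)), tolerance = 1e-7)
      expect_equal(b$se[j], sqrt(unname(vcov(ref)[1, 1])), tolerance = 1e-7)
    }
  }
})

test_that("Kaplan-Meier matches the product-limit closed forms", {
  # 4 uncensored events: empirical survivor function
  km <- kaplan_meier(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$survival, c(0.75, 0.5, 0.25, 0))

  # all censored: no steps, survival identically 1
  km <- kaplan_meier(c(1, 2, 3), c(0, 0, 0))
  expect_length(km$times, 0)
  expect_equal(km_surv_at(km, c(0.5, 2, 10)), c(1, 1, 1))

  # events {2, 4}, censored {3}: S(2) = 2/3; at t = 4 a single subject
  # remains at risk and fails, so S(4) = 0
  km <- kaplan_meier(c(2, 3, 4), c(1, 0, 1))
  expect_equal(km$survival, c(2 / 3, 0))

  expect_error(kaplan_meier(numeric(0), numeric(0)), "empty")
})

test_that("log-rank test matches hand computation and detects no difference in copies", {
  # identical groups: observed = expected
  time <- c(1, 2, 3, 4)
  event <- c(1, 1, 0, 1)
  lr <- log_rank_test(c(time, time), c(event, event), rep(c("a", "b"), each = 4))
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1, tolerance = 1e-12)

  # A events {1,2}, B events {3,4}, no censoring: hand O-E/V
  # t=1: n=4, nA=2, e=1: E_A = 1/2, V = (2*2*1*3)/(16*3) = 1/4
  # t=2: n=3, nA=1, e=1: E_A = 1/3, V = (1*2*1*2)/(9*2)  = 2/9
  # t=3: n=2, nA=0: contributes 0;  t=4: n=1: V = 0
  o_minus_e <- (1 - 1 / 2) + (1 - 1 / 3)
  v <- 1 / 4 + 2 / 9
  lr <- log_rank_test(c(1, 2, 3, 4), rep(1, 4), c("A", "A", "B", "B"))
  expect_equal(lr$statistic, o_minus_e^2 / v, tolerance = 1e-10)
  expect_equal(lr$df, 1)

  expect_error(log_rank_test(time, event, rep("a", 4)), "2 groups")
})

test_that("two-group log-rank equals the Cox score test on random instances", {
  set.seed(31)
  for (r in 1:100) {
    n <- sample(20:40, 1)
    time <- rexp(n)                      # continuous: no ties
    event <- rbinom(n, 1, 0.7)
    g <- rbinom(n, 1, 0.5)
    if (sum(event) == 0 || length(unique(g)) < 2) next
    lr <- log_rank_test(time, event, g)
    sc <- survival::coxph(survival::Surv(time, event) ~ g)$score
    expect_equal(lr$statistic, unname(sc), tolerance = 1e-6)
  }
})

test_that("Pearson chi-square reproduces printed clinical-table p-values", {
  sex <- rbind(c(35, 91), c(66, 171), c(35, 104))
  expect_equal(round(pearson_chi_square(sex)$p_value, 2), 0.84)
  tert <- rbind(c(117, 7), c(225, 10), c(118, 19))
  expect_equal(round(pearson_chi_square(tert)$p_value, 3), 0.002)
})

test_that("Pearson chi-square invariances and degenerate tables", {
  # proportional rows: statistic 0, p = 1
  tab <- rbind(c(10, 20, 30), c(20, 40, 60))
  r <- pearson_chi_square(tab)
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1)

  set.seed(5)
  tab <- matrix(rpois(12, 20) + 1, 3, 4)
  r0 <- pearson_chi_square(tab)
  r1 <- pearson_chi_square(tab[sample(3), sample(4)])
  expect_equal(r1$statistic, r0$statistic)
  expect_equal(r1$df, r0$df)

  expect_error(pearson_chi_square(rbind(c(0, 0), c(1, 2))), "margin")
  expect_error(pearson_chi_square(rbind(c(1.5, 2), c(1, 2))), "integer")
})

test_that("Fisher exact two-sided p-values on 2x2 tables", {
  expect_equal(fisher_exact_2x2(rbind(c(1, 1), c(1, 1)))$p_value, 1)
  # margins (3,3)/(3,3): the two extreme tables each have prob 1/20
  expect_equal(fisher_exact_2x2(rbind(c(3, 0), c(0, 3)))$p_value, 0.1,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(rbind(c(0, 0), c(2, 3)))$p_value, 1)
})

test_that("Kruskal-Wallis H statistic, ties, and permutation calibration", {
  r <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(r$statistic, 7.2, tolerance = 1e-12)
  expect_equal(r$df, 2)

  # identical groups: H = 0
  r <- kruskal_wallis(list(c(2, 5, 9), c(2, 5, 9)))
  expect_equal(r$statistic, 0, tolerance = 1e-12)

  # all values identical: returned as H = 0, p = 1, not an error
  r <- kruskal_wallis(list(c(1, 1), c(1, 1)))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # chi-square p within Monte-Carlo error of a permutation oracle
  set.seed(41)
  vals <- c(rnorm(5), rnorm(5, 1), rnorm(5, 0.5))
  grp <- rep(1:3, each = 5)
  obs <- kruskal_wallis(vals, grp)
  perm <- replicate(1e4, kruskal_wallis(vals, sample(grp))$statistic)
  p_perm <- mean(perm >= obs$statistic - 1e-12)
  expect_lt(abs(obs$p_value - p_perm), 0.05)
})

test_that("IPCW time-dependent AUC: null, perfect, and enumeration oracle", {
  set.seed(51)
  n <- 500
  time <- rexp(n, 0.02)
  event <- rbinom(n, 1, 0.8)
  marker <- rnorm(n)                      # independent of outcome
  a <- cumulative_dynamic_auc(marker, time, event, horizon = 30)
  expect_lt(abs(a$auc - 0.5), 0.05)

  # marker perfectly ordering cases above controls, no censoring
  time2 <- c(rep(10, 6), rep(80, 6))
  event2 <- rep(1, 12)
  marker2 <- c(rep(2, 6), rep(-1, 6))
  expect_equal(cumulative_dynamic_auc(marker2, time2, event2, 60)$auc, 1.0)

  # n = 12 mixed cohort vs exhaustive weighted-pair enumeration
  time3 <- c(5, 12, 18, 25, 33, 41, 47, 55, 64, 72, 85, 99)
  event3 <- c(1, 0, 1, 1, 0, 1, 0, 1, 0, 1, 0, 0)
  marker3 <- c(2.1, 0.3, 1.7, -0.2, 0.9, 1.1, -1.4, 0.5, 0.0, -0.7, 0.2, -1.0)
  a3 <- cumulative_dynamic_auc(marker3, time3, event3, horizon = 60)
  expect_equal(a3$auc, oracle_ipcw_auc(marker3, time3, event3, 60),
               tolerance = 1e-12)
  expect_equal(a3$n_cases, sum(time3 <= 60 & event3 == 1))
  expect_equal(a3$n_controls, sum(time3 > 60))

  expect_error(cumulative_dynamic_auc(marker3, time3, event3, horizon = 2),
               "no cases")
})

test_that("AUC is invariant under strictly monotone marker transforms", {
  set.seed(61)
  n <- 80
  marker <- rnorm(n)
  time <- rexp(n, 0.05 * exp(0.8 * marker))
  event <- rbinom(n, 1, 0.75)
  a0 <- cumulative_dynamic_auc(marker, time, event, 20)$auc
  for (f in list(function(m) 3 * m - 7, exp, function(m) m^3)) {
    expect_equal(cumulative_dynamic_auc(f(marker), time, event, 20)$auc, a0)
  }
})

test_that("Cox Wald statistics are invariant to covariate scaling", {
  set.seed(71)
  n <- 50
  x <- matrix(rnorm(2 * n), n, 2)
  time <- rexp(n, 0.1 * exp(0.5 * x[, 1]))
  event <- rbinom(n, 1, 0.8)
  f1 <- fit_cox(x, time, event)
  f2 <- fit_cox(sweep(x, 2, c(10, 0.2), `*`), time, event)
  expect_equal(unname(f2$coefficients), unname(f1$coefficients) / c(10, 0.2),
               tolerance = 1e-6)
  expect_equal(unname(f2$wald), unname(f1$wald), tolerance = 1e-6)
})
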