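test_that("KM estimate matches closed forms and the hand-computed oracle", {
  km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$survival_prob, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$median_survival, 2)

  flat <- km_estimate(c(3, 6, 9), c(0, 0, 0))
  expect_length(flat$event_times, 0L)
  expect_true(is.na(flat$median_survival))

  # hand product-limit: drops at t=1 (n=5), t=3 (n=3), t=5 (n=1)
  km2 <- km_estimate(c(1, 2, 3, 4, 5), c(1, 0, 1, 0, 1))
  expect_equal(km2$event_times, c(1, 3, 5))
  expect_equal(km2$survival_prob, c(4 / 5, 4 / 5 * 2 / 3, 0))
  expect_equal(km2$median_survival, 5)

  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
})

test_that("KM equals brute-force product over risk sets on random data", {
  set.seed(101)
  for (i in 1:60) {
    inst <- random_surv_instance(sample(3:40, 1))
    km <- km_estimate(inst$times, inst$events)
    orc <- oracle_km(inst$times, inst$events)
    expect_identical(km$event_times, orc$time)
    expect_equal(km$survival_prob, orc$surv, tolerance = 1e-12)
  }
})

test_that("logrank matches direct O/E/V evaluation and symmetry", {
  # identical (time, event) multisets in both groups
  t0 <- c(1, 3, 5, 7)
  e0 <- c(1, 1, 0, 1)
  lr0 <- logrank_test(c(t0, t0), c(e0, e0), rep(c("a", "b"), each = 4))
  expect_equal(lr0$chi_square, 0)
  expect_equal(lr0$p_value, 1)

  # separated event clusters, no censoring
  times <- c(1, 2, 5, 6)
  events <- rep(1, 4)
  grp <- c("A", "A", "B", "B")
  lr <- logrank_test(times, events, grp)
  expect_equal(lr$chi_square,
               oracle_logrank_chisq(times, events, as.integer(grp == "B")),
               tolerance = 1e-12)
  expect_equal(sum(lr$observed), sum(lr$expected), tolerance = 1e-9)

  set.seed(102)
  for (i in 1:40) {
    inst <- random_surv_instance(sample(6:50, 1))
    x <- rbinom(length(inst$times), 1, 0.5)
    if (length(unique(x)) < 2 || sum(inst$events) == 0) next
    lr_i <- suppressWarnings(
      logrank_test(inst$times, inst$events, factor(x)))
    expect_equal(lr_i$chi_square,
                 oracle_logrank_chisq(inst$times, inst$events, x),
                 tolerance = 1e-10)
  }
})

test_that("logrank degenerate inputs are handled explicitly", {
  expect_error(logrank_test(1:4, rep(1, 4), rep("a", 4)), "two")
  expect_warning(lr <- logrank_test(1:4, rep(0, 4), c("a", "a", "b", "b")),
                 "no events")
  expect_equal(lr$p_value, 1)
})

test_that("logrank p agrees with a 10,000-draw permutation null", {
  set.seed(103)
  n <- 20
  times <- rexp(n, 0.2) * exp(0.6 * rep(0:1, each = n / 2))
  events <- rbinom(n, 1, 0.8)
  grp <- rep(c("lo", "hi"), each = n / 2)
  obs <- logrank_test(times, events, grp)
  perm <- replicate(10000, {
    logrank_test(times, events, sample(grp))$chi_square
  })
  p_perm <- mean(perm >= obs$chi_square - 1e-12)
  expect_lt(abs(p_perm - obs$p_value), 0.05)
})

test_that("Cox fit is symmetric, scale-invariant and matches brute force", {
  # identical event-time distributions in both groups -> beta ~ 0
  t0 <- c(2, 4, 6, 8, 10)
  e0 <- c(1, 1, 0, 1, 1)
  sym <- cox_fit_binary(c(t0, t0), c(e0, e0), rep(c("a", "b"), each = 5))
  expect_lt(abs(sym$beta), 1e-6)

  # 12-subject toy cohort vs brute-force partial-likelihood maximization
  set.seed(104)
  for (ties in c("efron", "breslow")) {
    for (i in 1:8) {
      n <- 12
      x <- rep(0:1, each = 6)
      times <- round(rexp(n, 0.1) * exp(0.8 * x), 1) + 0.1
      events <- rbinom(n, 1, 0.85)
      if (sum(events[x == 0]) == 0 || sum(events[x == 1]) == 0) next
      fit <- cox_fit_binary(times, events, factor(x), ties = ties)
      if (!fit$converged) next
      expect_equal(fit$beta, oracle_cox_beta(times, events, x, ties),
                   tolerance = 1e-4)
    }
  }

  # rank invariance: multiplying all times by 10 leaves beta unchanged
  times <- c(1, 2, 3, 4, 5, 6, 7, 8)
  events <- c(1, 1, 0, 1, 1, 0, 1, 1)
  x <- c(0, 1, 0, 1, 1, 0, 1, 0)
  f1 <- cox_fit_binary(times, events, factor(x))
  f2 <- cox_fit_binary(times * 10, events, factor(x))
  expect_equal(f1$beta, f2$beta, tolerance = 1e-12)
})

test_that("Cox fit agrees with survival::coxph on a realistic instance", {
  library(survival)
  set.seed(105)
  n <- 150
  x <- rbinom(n, 1, 0.5)
  times <- round(rexp(n, 0.05) * exp(-0.7 * x), 1) + 0.1
  events <- rbinom(n, 1, 0.75)
  for (ties in c("efron", "breslow")) {
    mine <- cox_fit_binary(times, events, factor(x), ties = ties)
    ref <- coxph(Surv(times, events) ~ x, ties = ties)
    expect_equal(mine$beta, unname(coef(ref)), tolerance = 1e-7)
    expect_equal(mine$se_beta, sqrt(unname(vcov(ref)[1, 1])),
                 tolerance = 1e-7)
  }
})

test_that("Efron and Breslow agree to 1e-9 on tie-free data", {
  set.seed(106)
  n <- 60
  x <- rbinom(n, 1, 0.5)
  times <- rexp(n, 0.1) * exp(0.5 * x)   # continuous, no ties
  events <- rbinom(n, 1, 0.8)
  fe <- cox_fit_binary(times, events, factor(x), ties = "efron")
  fb <- cox_fit_binary(times, events, factor(x), ties = "breslow")
  expect_lt(abs(fe$beta - fb$beta), 1e-9)
  expect_lt(abs(fe$se_beta - fb$se_beta), 1e-9)
})

test_that("logrank chi-square equals the Cox (Breslow) score test, tie-free", {
  set.seed(107)
  for (i in 1:10) {
    n <- 40
    x <- rbinom(n, 1, 0.5)
    times <- rexp(n, 0.15) * exp(0.4 * x)
    events <- rbinom(n, 1, 0.8)
    if (sum(events) == 0 || length(unique(x)) < 2) next
    lr <- suppressWarnings(logrank_test(times, events, factor(x)))
    # score statistic U(0)^2 / I(0) from the naive partial likelihood,
    # by central finite differences
    h <- 1e-4
    ll <- function(b) oracle_cox_loglik(times, events, x, b, "breslow")
    u0 <- (ll(h) - ll(-h)) / (2 * h)
    i0 <- -(ll(h) - 2 * ll(0) + ll(-h)) / h^2
    expect_equal(lr$chi_square, u0^2 / i0, tolerance = 1e-5)
  }
})

test_that("monotone likelihood is capped and flagged non-converged", {
  # every group-1 event precedes all group-0 events: beta diverges
  times <- c(1, 2, 3, 10, 11, 12)
  events <- c(1, 1, 1, 1, 1, 1)
  x <- c(1, 1, 1, 0, 0, 0)
  fit <- cox_fit_binary(times, events, factor(x))
  expect_false(fit$converged)
  expect_equal(abs(fit$beta), 20)
})
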