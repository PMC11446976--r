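test_that("KM estimates follow the product-limit definition", {
  # no events: survival stays at 1
  km0 <- kmFit(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(km0$surv == 1))
  # all events, one group: empirical survivor function
  km1 <- kmFit(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km1$surv, c(2 / 3, 1 / 3, 0))
  # censoring at t = 2 removes the subject from the risk set at t = 3
  km2 <- kmFit(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$n_risk[km2$time == 3], 1)
  expect_equal(km2$surv[km2$time == 3], (2 / 3) * 0)
  # without censoring KM equals the empirical survivor function exactly
  set.seed(41)
  tt <- rexp(40)
  km3 <- kmFit(tt, rep(1, 40))
  emp <- vapply(km3$time, function(u) mean(tt > u), numeric(1))
  expect_equal(km3$surv, emp, tolerance = 1e-12)
})

test_that("log-rank is null on identical groups and relabel-invariant", {
  tt <- c(1, 2, 3, 4, 5, 6); ev <- rep(1, 6)
  lr <- logrankTest(rep(tt, 2), rep(ev, 2), rep(c("a", "b"), each = 6))
  expect_equal(lr$chi2, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1, tolerance = 1e-12)
  set.seed(42)
  t2 <- rexp(60); e2 <- rbinom(60, 1, 0.7)
  g <- rep(c("x", "y", "z"), 20)
  a <- logrankTest(t2, e2, g)
  b <- logrankTest(t2, e2, c(x = "G1", y = "G2", z = "G3")[g])
  expect_equal(a$chi2, b$chi2, tolerance = 1e-12)
  expect_equal(a$df, 2L)
})

test_that("planted subgroup hazards separate survival at cohort scale", {
  b <- cohortFixture(1)
  lab <- b@truth$labels
  i <- match(names(lab), b@clinical$sample)
  lr <- logrankTest(b@clinical$os_time_months[i], b@clinical$os_event[i], lab)
  expect_lt(lr$p, 0.05)
})

test_that("Cox recovers a planted binary hazard ratio and covers the null", {
  set.seed(43)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  tt <- rexp(n, 0.02 * 2^x)
  cens <- rexp(n, 0.01)
  clin <- data.frame(sample = sprintf("s%04d", 1:n),
                     sex = "F", age = 60, stage = "I",
                     os_time_months = pmin(tt, cens),
                     os_event = as.integer(tt <= cens),
                     purity = 0.8, stringsAsFactors = FALSE)
  labels <- setNames(ifelse(x == 1, "P", "I"), clin$sample)
  fit <- coxphFit(clin, labels, covariates = "subtype")
  hr <- fit$table$hr[fit$table$term == "subtypeP"]
  expect_gte(hr, 1.8); expect_lte(hr, 2.2)
  # null covariate: 95% CI covers 1 at roughly the nominal rate
  cover <- replicate(400, {
    m <- 50
    x0 <- rbinom(m, 1, 0.5)
    t0 <- rexp(m, 0.05)
    d <- data.frame(os_time_months = t0, os_event = 1L,
                    x = factor(x0))
    f <- survival::coxph(survival::Surv(os_time_months, os_event) ~ x,
                         data = d, ties = "efron")
    ci <- exp(confint(f))
    ci[1] <= 1 && 1 <= ci[2]
  })
  expect_gt(mean(cover), 0.92)
  expect_lt(mean(cover), 0.98)
})

test_that("Cox partial likelihood agrees with brute-force maximization", {
  set.seed(44)
  n <- 40
  x <- rbinom(n, 1, 0.5)
  tt <- rexp(n, 0.05 * exp(0.7 * x))  # continuous: no ties
  clin <- data.frame(sample = sprintf("s%02d", 1:n), sex = "F", age = 50,
                     stage = "I", os_time_months = tt, os_event = 1L,
                     purity = 0.9, stringsAsFactors = FALSE)
  labels <- setNames(ifelse(x == 1, "P", "I"), clin$sample)
  fit <- coxphFit(clin, labels, covariates = "subtype")
  betaHat <- fit$table$beta[fit$table$term == "subtypeP"]
  grid <- optimize(function(b) -coxPartialLogLik(b, tt, rep(1, n), x),
                   c(-3, 3), tol = 1e-8)
  expect_equal(betaHat, grid$minimum, tolerance = 1e-4)
})

test_that("degenerate survival inputs fail loudly", {
  clin <- data.frame(sample = c("a", "b", "c"), sex = "F", age = 60,
                     stage = "I", os_time_months = c(1, 2, 3),
                     os_event = c(1L, 1L, 1L), purity = 0.9,
                     stringsAsFactors = FALSE)
  # zero-event stratum
  clin2 <- clin; clin2$os_event <- c(1L, 0L, 0L)
  labels <- setNames(c("P", "I", "I"), clin$sample)
  expect_error(coxphFit(clin2, labels, covariates = "subtype"),
               "zero-event subtype stratum: I")
  # n = 3 with perfect separation: numeric failure is reported, not silent
  clin3 <- clin; clin3$os_time_months <- c(1, 10, 11)
  expect_error(coxphFit(clin3, setNames(c("P", "I", "I"), clin3$sample),
                        covariates = "subtype"),
               "unstable|failed")
})
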