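# Two-part estimation: likelihood, Newton probit, OLS, and the combined
# per-quintile fit.

test_that("probit_loglik matches closed forms and handles empty data", {
  expect_equal(probit_loglik(0, matrix(1, 2, 1), c(1, 0)), 2 * log(0.5))
  expect_equal(probit_loglik(c(1, 2), matrix(0, 0, 2), numeric(0)), 0)
  expect_error(probit_loglik(c(1, 2), matrix(1, 3, 2), c(1, 0)),
               "length")
  expect_error(probit_loglik(1, matrix(1, 2, 2), c(1, 0)), "columns")
})

test_that("probit_loglik equals a per-row summation oracle", {
  set.seed(401)
  W <- cbind(1, matrix(rnorm(20), 10, 2))
  z <- rbinom(10, 1, 0.5)
  a <- c(0.3, -0.2, 0.1)
  oracle <- 0
  for (i in 1:10) {
    pi <- pnorm(sum(W[i, ] * a))
    oracle <- oracle + z[i] * log(pi) + (1 - z[i]) * log(1 - pi)
  }
  expect_equal(probit_loglik(a, W, z), oracle, tolerance = 1e-12)
})

test_that("intercept-only probit inverts the participation rate", {
  n <- 2000L
  z <- c(rep(1L, 1000L), rep(0L, 1000L))
  f <- fit_probit(matrix(1, n, 1), z)
  expect_true(f$converged)
  expect_equal(unname(f$coefficients), 0, tolerance = 1e-6)

  z <- c(rep(1L, 1950L), rep(0L, 50L))  # 97.5% participation
  f <- fit_probit(matrix(1, n, 1), z)
  expect_equal(unname(f$coefficients), qnorm(0.975), tolerance = 1e-6)
  expect_equal(f$participation_rate, 0.975)
})

test_that("fit_probit agrees with glm's probit on synthetic data", {
  hh <- generate_households(default_dgp_params(2, n_per_quintile = 3000,
                                               seed = 77))
  W <- probit_design(hh)
  f <- fit_probit(W, hh$smoke)
  g <- suppressWarnings(
    glm.fit(W, hh$smoke, family = binomial("probit")))
  expect_true(f$converged)
  expect_equal(unname(f$coefficients), unname(g$coefficients),
               tolerance = 1e-5)
  # glm's IRLS weights give expected information; ours is observed --
  # they agree asymptotically, so compare loosely
  se_glm <- sqrt(diag(chol2inv(chol(
    crossprod(W * g$weights, W)))))
  expect_equal(unname(f$standard_errors), unname(se_glm),
               tolerance = 0.05)
})

test_that("fit_probit rejects bad designs and flags separation", {
  expect_error(fit_probit(matrix(1, 10, 1), rep(1, 10)), "single class")
  W <- cbind(1, 1:10, 2 * (1:10))
  expect_error(fit_probit(W, rep(c(0, 1), 5)), "rank deficient")
  # perfect separation on x
  x <- c(-(5:1), 1:5)
  z <- as.integer(x > 0)
  f <- fit_probit(cbind(1, x), z)
  expect_false(f$converged)
})

test_that("fitted loglik is a maximum (above the DGP coefficients)", {
  p <- default_dgp_params(1, n_per_quintile = 4000, seed = 31)
  hh <- generate_households(p)
  W <- probit_design(hh)
  f <- fit_probit(W, hh$smoke)
  expect_gte(f$loglik, probit_loglik(p$alpha, W, hh$smoke))
})

test_that("probit probabilities are invariant to recentring ln_price", {
  hh <- generate_households(default_dgp_params(4, n_per_quintile = 2500,
                                               seed = 55))
  f1 <- fit_probit(probit_design(hh), hh$smoke)
  hh2 <- hh
  hh2$ln_price <- hh2$ln_price + 3
  f2 <- fit_probit(probit_design(hh2), hh2$smoke)
  p1 <- pnorm(drop(probit_design(hh) %*% f1$coefficients))
  p2 <- pnorm(drop(probit_design(hh2) %*% f2$coefficients))
  expect_equal(p1, p2, tolerance = 1e-5)
})

test_that("fit_ols interpolates noiseless data and matches lm", {
  x1 <- c(1, 2, 3, 4, 5, 6)
  x2 <- c(2, 1, 4, 3, 6, 5)
  y <- 7.9 + 0.039 * x1 - 0.389 * x2
  f <- fit_ols(cbind(`(Intercept)` = 1, x1 = x1, x2 = x2), y)
  expect_equal(unname(f$coefficients), c(7.9, 0.039, -0.389),
               tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)

  set.seed(402)
  X <- cbind(1, matrix(rnorm(300), 100, 3))
  colnames(X) <- c("(Intercept)", "a", "b", "c")
  y <- drop(X %*% c(1, 0.5, -0.2, 0)) + rnorm(100)
  f <- fit_ols(X, y)
  lm_fit <- lm(y ~ a + b + c, data = as.data.frame(X[, -1]))
  expect_equal(unname(f$coefficients), unname(coef(lm_fit)),
               tolerance = 1e-10)
  expect_equal(unname(f$standard_errors),
               unname(coef(summary(lm_fit))[, "Std. Error"]),
               tolerance = 1e-10)
  expect_equal(f$r_squared, summary(lm_fit)$r.squared, tolerance = 1e-10)
})

test_that("fit_ols handles degenerate responses and rejects bad designs", {
  set.seed(403)
  X <- cbind(1, rnorm(20))
  f <- fit_ols(X, rep(4, 20))
  expect_equal(unname(f$coefficients), c(4, 0), tolerance = 1e-10)
  expect_error(fit_ols(cbind(1, 1:10, 2 * (1:10)), rnorm(10)),
               "rank deficient")
  expect_error(fit_ols(matrix(rnorm(4), 2, 2), rnorm(2)),
               "more observations")
})

test_that("OLS residuals are orthogonal to every design column", {
  hh <- generate_households(default_dgp_params(5, n_per_quintile = 5000,
                                               seed = 19))
  smokers <- hh[hh$smoke == 1, ]
  X <- ols_design(smokers)
  f <- fit_ols(X, log(smokers$sticks_month))
  expect_lt(max(abs(crossprod(X, f$residuals))) / nrow(X), 1e-8)
})

test_that("fit_two_part splits participation and conditional samples", {
  hh <- tiny_households()
  # 6-row fixture, 3 smokers: part-two design has exactly 3 rows
  expect_equal(nrow(ols_design(hh[hh$smoke == 1, ])), 3L)
  expect_error(fit_two_part(hh[hh$smoke == 1, ], "all"), "both classes")
  expect_error(fit_two_part(hh, 5), "no households")

  pooled <- simulate_survey(1200, seed = 44)
  fits <- lapply(1:5, function(q) fit_two_part(pooled, q))
  expect_length(fits, 5L)
  for (f in fits) {
    expect_equal(f$n_participation, 1200L)
    expect_lt(f$n_conditional, f$n_participation)
    expect_equal(f$n_conditional, f$ols$n)
  }
})

test_that("two-part recovery: price coefficients near their DGP values", {
  p <- default_dgp_params(2, n_per_quintile = 50000, seed = 61)
  hh <- generate_households(p)
  f <- fit_two_part(hh, 2)
  expect_lt(abs(f$probit$coefficients[["ln_price"]] - (-0.086)),
            3 * f$probit$standard_errors[["ln_price"]])
  expect_lt(abs(f$ols$coefficients[["ln_price"]] - (-0.356)),
            3 * f$ols$standard_errors[["ln_price"]])
})
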