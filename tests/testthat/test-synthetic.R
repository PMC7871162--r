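# Synthetic survey generator: defaults, determinism, distributional
# agreement with the generating model.

test_that("default_dgp_params carries the published coefficient columns", {
  p5 <- default_dgp_params(5)
  expect_equal(p5$alpha[["ln_price"]], -0.099)
  expect_equal(p5$beta[["ln_price"]], -0.320)

  p1 <- default_dgp_params(1)
  expect_equal(p1$alpha[["ln_income"]], 0.031)
  income_slots <- vapply(1:5, function(q)
    default_dgp_params(q)$alpha[["ln_income"]], numeric(1))
  expect_equal(which(income_slots > 0), 1L)  # only Q1 is positive

  for (q in 1:5) {
    p <- default_dgp_params(q)
    expect_length(p$alpha, 14L)
    expect_length(p$beta, 11L)
    expect_gt(p$sigma, 0)
    shares <- p$covariate_config$head_edu_probs
    expect_equal(sum(shares), 1, tolerance = 1e-12)
  }
})

test_that("default_dgp_params is deterministic and rejects bad quintiles", {
  expect_identical(default_dgp_params(2), default_dgp_params(2))
  expect_error(default_dgp_params(0), "between 1 and 5")
  expect_error(default_dgp_params(6), "between 1 and 5")
  expect_error(default_dgp_params(2.5), "between 1 and 5")
})

test_that("dgp_params validates its invariants", {
  p <- default_dgp_params(1)
  expect_error(dgp_params(p$alpha[-1], p$beta, p$sigma,
                          p$covariate_config, 1, 10), "length 14")
  expect_error(dgp_params(p$alpha, p$beta[-1], p$sigma,
                          p$covariate_config, 1, 10), "length 11")
  expect_error(dgp_params(p$alpha, p$beta, 0, p$covariate_config, 1, 10),
               "positive")
  expect_error(dgp_params(p$alpha, p$beta, p$sigma, p$covariate_config,
                          1, 0), "positive integer")
})

test_that("identical params give byte-identical tables; seeds matter", {
  p <- default_dgp_params(2, n_per_quintile = 400, seed = 99)
  expect_identical(generate_households(p), generate_households(p))
  p2 <- p
  p2$seed <- 100L
  expect_false(identical(generate_households(p), generate_households(p2)))
})

test_that("consumption exists exactly for smoker households", {
  hh <- generate_households(default_dgp_params(4, n_per_quintile = 2000,
                                               seed = 5))
  expect_true(all(hh$sticks_month[hh$smoke == 1] > 0))
  expect_true(all(is.na(hh$sticks_month[hh$smoke == 0])))
  expect_true(all(hh$quintile == 4L))
  shares <- hh[grep("^share_", names(hh))]
  expect_true(all(shares >= 0 & shares <= 1))
  expect_true(all(is.finite(hh$ln_price)))
})

test_that("degenerate participation indices behave as limits demand", {
  p <- default_dgp_params(3, n_per_quintile = 500, seed = 8)
  p$alpha[] <- 0
  p$alpha[["(Intercept)"]] <- -30  # effectively -Inf on the probit scale
  hh <- generate_households(p)
  expect_equal(sum(hh$smoke), 0L)
  expect_true(all(is.na(hh$sticks_month)))

  n <- 20000L
  p$n_per_quintile <- n
  p$alpha[["(Intercept)"]] <- 0  # all-zero index: prevalence 1/2
  hh <- generate_households(p)
  expect_lt(abs(mean(hh$smoke) - 0.5), 3 * sqrt(0.25 / n))
})

test_that("empirical moments match the generating model (oracle)", {
  p <- default_dgp_params(3, n_per_quintile = 50000, seed = 12)
  hh <- generate_households(p)
  W <- probit_design(hh)
  probs <- pnorm(drop(W %*% p$alpha))
  mc_se <- sqrt(mean(probs * (1 - probs)) / nrow(hh))
  expect_lt(abs(mean(hh$smoke) - mean(probs)), 3 * mc_se)

  sm <- hh$smoke == 1
  X <- ols_design(hh[sm, ])
  mu <- drop(X %*% p$beta)
  expect_lt(abs(mean(log(hh$sticks_month[sm])) - mean(mu)),
            3 * p$sigma / sqrt(sum(sm)))
})

test_that("prevalence is ~20% and peaks in the middle quintiles", {
  hh <- simulate_survey(4000, seed = 21)
  prev <- tapply(hh$smoke, hh$quintile, mean)
  expect_true(all(prev > 0.10 & prev < 0.30))
  expect_gt(max(prev[2:4]), max(prev[c(1, 5)]))
})

test_that("degenerate covariate configs are rejected", {
  p <- default_dgp_params(1, n_per_quintile = 100)
  p$covariate_config$ln_price[c("province_sd", "year_sd",
                                "household_sd", "year_slope")] <- 0
  expect_error(generate_households(p), "price")
  p <- default_dgp_params(1, n_per_quintile = 100)
  p$covariate_config$ln_income[["sd"]] <- 0
  expect_error(generate_households(p), "ln_income")
})

test_that("simulate_survey pools five equal quintile blocks", {
  hh <- simulate_survey(300, seed = 3)
  expect_equal(nrow(hh), 1500L)
  expect_equal(as.integer(table(hh$quintile)), rep(300L, 5))
  # expenditure bands are disjoint, so pooled re-ranking reproduces labels
  relabeled <- assign_quintiles(hh)
  expect_equal(relabeled$quintile, hh$quintile)
})
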