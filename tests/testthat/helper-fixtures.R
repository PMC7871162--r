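# Shared fixtures: stub fits and hand-built household tables.

# probit stub whose participation elasticity equals the price/income
# coefficient exactly: with index 0 and rate dnorm(0), the density and the
# rate cancel.
probit_stub <- function(price, income, idx = 0, rate = stats::dnorm(0)) {
  structure(
    list(coefficients = c("(Intercept)" = 0, ln_income = income,
                          ln_price = price),
         converged = TRUE,
         mean_linear_index = idx,
         participation_rate = rate),
    class = "probit_fit"
  )
}

ols_stub <- function(price, income) {
  structure(
    list(coefficients = c("(Intercept)" = 8, ln_income = income,
                          ln_price = price)),
    class = "ols_fit"
  )
}

two_part_stub <- function(quintile, p_price, p_income, c_price, c_income) {
  list(probit = probit_stub(p_price, p_income),
       ols = ols_stub(c_price, c_income),
       quintile = quintile)
}

# six households, three smokers, hand-checkable
tiny_households <- function() {
  data.frame(
    year = 2010L, province_id = 1L,
    expenditure_pea = c(1e6, 2e6, 3e6, 4e6, 5e6, 6e6),
    quintile = c(1L, 1L, 2L, 2L, 3L, 3L),
    ln_income = c(15, 15.2, 15.5, 15.7, 16, 16.2),
    ln_price = c(11.4, 11.5, 11.6, 11.4, 11.5, 11.6),
    divorce_rate = 2, unemployment_rate = 11,
    share_15_18 = 0.1, share_gt64 = 0.05,
    share_male_19_64 = 0.3, share_female_19_64 = 0.3,
    share_jobless = 0.1, share_primary_edu = 0.4,
    share_univ_edu = 0.1,
    head_age = c(40, 45, 50, 55, 60, 65),
    head_sex = c(1L, 1L, 1L, 0L, 1L, 1L),
    head_education = factor(
      c("none", "elementary", "junior_high", "none", "diploma",
        "bachelor"),
      levels = cigdemand:::EDU_LEVELS),
    smoke = c(1L, 0L, 1L, 0L, 1L, 0L),
    sticks_month = c(300, NA, 450, NA, 600, NA)
  )
}
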