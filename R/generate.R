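# Household microdata simulation from a two-part demand DGP.

#' Simulate household survey records from a two-part demand model
#'
#' Draws covariates for `params$n_per_quintile` households, forms the latent
#' participation index `Z* = W'alpha + e` with `e ~ N(0, 1)`, sets
#' `smoke = 1` iff `Z* > 0`, and for smoker households draws
#' `ln(sticks_month) = X'beta + mu` with `mu ~ N(0, sigma)`. Participation
#' and intensity errors are independent (a two-part, not a selection,
#' model). Prices and province-level rates vary across province-by-year
#' cells so the price coefficient is identifiable from the output.
#'
#' The draw is fully determined by `params` (including `params$seed`): the
#' same object always yields an identical table.
#'
#' @param params a [dgp_params] object.
#' @return A `data.frame` with one row per household and the columns
#'   `year`, `province_id`, `expenditure_pea`, `quintile`, `ln_income`,
#'   `ln_price`, `divorce_rate`, `unemployment_rate`, the seven member-share
#'   columns, `head_age`, `head_sex`, `head_education` (factor),
#'   `smoke` (0/1) and `sticks_month` (positive for smokers, `NA`
#'   otherwise).
#' @examples
#' hh <- generate_households(default_dgp_params(3, n_per_quintile = 500))
#' mean(hh$smoke)
#' @export
generate_households <- function(params) {
  if (!inherits(params, "dgp_params"))
    stop("`params` must be a dgp_params object; see default_dgp_params()")
  cc <- params$covariate_config
  check_covariate_config(cc)
  n <- params$n_per_quintile

  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(params$seed)

  years <- as.integer(cc$years)
  n_prov <- as.integer(cc$n_provinces)
  n_cells <- n_prov * length(years)

  # province-by-year cells: price level plus province-level social rates
  prov_price <- stats::rnorm(n_prov, 0, cc$ln_price[["province_sd"]])
  year_price <- cc$ln_price[["year_slope"]] *
    (years - stats::median(years)) +
    stats::rnorm(length(years), 0, cc$ln_price[["year_sd"]])
  prov_divorce <- pmax(cc$divorce[["min"]],
                       stats::rnorm(n_prov, cc$divorce[["mean"]],
                                    cc$divorce[["sd"]]))
  prov_unemp <- pmax(cc$unemployment[["min"]],
                     stats::rnorm(n_prov, cc$unemployment[["mean"]],
                                  cc$unemployment[["sd"]]))

  province_id <- sample.int(n_prov, n, replace = TRUE)
  year <- sample(years, n, replace = TRUE)
  year_idx <- match(year, years)

  ln_price <- cc$ln_price[["base"]] + prov_price[province_id] +
    year_price[year_idx] +
    stats::rnorm(n, 0, cc$ln_price[["household_sd"]])

  hh <- data.frame(
    year = year,
    province_id = province_id,
    expenditure_pea = rlnorm_trunc(n, cc$expenditure[["meanlog"]],
                                   cc$expenditure[["sdlog"]],
                                   cc$expenditure[["lo"]],
                                   cc$expenditure[["hi"]]),
    quintile = rep.int(params$quintile, n),
    ln_income = stats::rnorm(n, cc$ln_income[["mean"]],
                             cc$ln_income[["sd"]]),
    ln_price = ln_price,
    divorce_rate = prov_divorce[province_id],
    unemployment_rate = prov_unemp[province_id],
    share_15_18 = rbeta2(n, cc$share_15_18),
    share_gt64 = rbeta2(n, cc$share_gt64),
    share_male_19_64 = rbeta2(n, cc$share_male_19_64),
    share_female_19_64 = rbeta2(n, cc$share_female_19_64),
    share_jobless = rbeta2(n, cc$share_jobless),
    share_primary_edu = rbeta2(n, cc$share_primary_edu),
    share_univ_edu = rbeta2(n, cc$share_univ_edu),
    head_age = round(rnorm_trunc(n, cc$head_age[["mean"]],
                                 cc$head_age[["sd"]],
                                 cc$head_age[["lo"]], cc$head_age[["hi"]])),
    head_sex = stats::rbinom(n, 1L, cc$head_sex_p),
    head_education = factor(
      sample(EDU_LEVELS, n, replace = TRUE, prob = cc$head_edu_probs),
      levels = EDU_LEVELS)
  )

  W <- probit_design(hh)
  z_star <- drop(W %*% params$alpha) + stats::rnorm(n)
  hh$smoke <- as.integer(z_star > 0)

  hh$sticks_month <- NA_real_
  sm <- hh$smoke == 1L
  if (any(sm)) {
    X <- ols_design(hh[sm, , drop = FALSE])
    hh$sticks_month[sm] <- exp(drop(X %*% params$beta) +
                                 stats::rnorm(sum(sm), 0, params$sigma))
  }
  hh
}

#' Simulate a full five-quintile survey
#'
#' Convenience wrapper calling [generate_households()] on
#' [default_dgp_params()] for each quintile and row-binding the results.
#' Per-quintile seeds are derived from `seed` so the pooled table is
#' reproducible.
#'
#' @param n_per_quintile households per quintile.
#' @param seed base RNG seed.
#' @param params_list optional list of five `dgp_params` objects overriding
#'   the defaults (seeds inside are still rederived from `seed`).
#' @return pooled household `data.frame` (see [generate_households()]).
#' @export
simulate_survey <- function(n_per_quintile = 1000L, seed = 1L,
                            params_list = NULL) {
  if (is.null(params_list)) {
    params_list <- lapply(1:5, default_dgp_params,
                          n_per_quintile = n_per_quintile)
  }
  if (length(params_list) != 5L)
    stop("`params_list` must contain exactly five dgp_params objects")
  out <- lapply(1:5, function(q) {
    p <- params_list[[q]]
    p$seed <- (as.integer(seed) * 5L + q) %% .Machine$integer.max
    generate_households(p)
  })
  do.call(rbind, out)
}

#' Build the participation-model design matrix from household records
#'
#' Columns follow `PROBIT_TERMS`: an intercept, log income, log price, the
#' two province-level rates, the seven member-share variables, head's age
#' and head's sex.
#'
#' @param hh household `data.frame` in the [generate_households()] layout.
#' @return numeric matrix with `length(PROBIT_TERMS)` columns.
#' @export
probit_design <- function(hh) {
  cols <- PROBIT_TERMS[-1L]
  missing_cols <- setdiff(cols, names(hh))
  if (length(missing_cols))
    stop("household table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  m <- cbind(1, as.matrix(hh[cols]))
  colnames(m) <- PROBIT_TERMS
  storage.mode(m) <- "double"
  m
}

#' Build the conditional-demand design matrix from household records
#'
#' Columns follow `OLS_TERMS`: an intercept, log income, log price, the two
#' province-level rates, and six head-education dummies with "no education"
#' as the omitted reference level.
#'
#' @inheritParams probit_design
#' @return numeric matrix with `length(OLS_TERMS)` columns.
#' @export
ols_design <- function(hh) {
  base_cols <- c("ln_income", "ln_price", "divorce_rate",
                 "unemployment_rate")
  missing_cols <- setdiff(c(base_cols, "head_education"), names(hh))
  if (length(missing_cols))
    stop("household table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  edu <- factor(hh$head_education, levels = EDU_LEVELS)
  dummies <- vapply(EDU_LEVELS[-1L], function(lv) as.numeric(edu == lv),
                    numeric(nrow(hh)))
  if (nrow(hh) == 1L) dummies <- matrix(dummies, nrow = 1L)
  m <- cbind(1, as.matrix(hh[base_cols]), dummies)
  colnames(m) <- OLS_TERMS
  storage.mode(m) <- "double"
  m
}

check_covariate_config <- function(cc) {
  required <- c("n_provinces", "years", "ln_income", "ln_price", "divorce",
                "unemployment", "share_15_18", "share_gt64",
                "share_male_19_64", "share_female_19_64", "share_jobless",
                "share_primary_edu", "share_univ_edu", "head_age",
                "head_sex_p", "head_edu_probs", "expenditure")
  missing_entries <- setdiff(required, names(cc))
  if (length(missing_entries))
    stop("covariate_config lacks entries: ",
         paste(missing_entries, collapse = ", "))
  # degenerate configs make downstream estimation non-identified
  price_var <- sum(cc$ln_price[c("province_sd", "year_sd",
                                 "household_sd")]^2) +
    cc$ln_price[["year_slope"]]^2 * stats::var(as.numeric(cc$years))
  if (price_var <= 0)
    stop("degenerate covariate_config: ln_price has zero variance, the ",
         "price coefficient would not be identified")
  if (cc$ln_income[["sd"]] <= 0)
    stop("degenerate covariate_config: ln_income has zero variance")
  if (cc$divorce[["sd"]] <= 0 || cc$unemployment[["sd"]] <= 0)
    stop("degenerate covariate_config: province rates have zero variance")
  invisible(TRUE)
}

# truncated normal / lognormal via inverse-CDF sampling
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, p_lo, p_hi), mean, sd)
}

rlnorm_trunc <- function(n, meanlog, sdlog, lo, hi) {
  p_lo <- stats::plnorm(lo, meanlog, sdlog)
  p_hi <- stats::plnorm(hi, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, p_lo, p_hi), meanlog, sdlog)
}

rbeta2 <- function(n, shapes) {
  stats::rbeta(n, shapes[["shape1"]], shapes[["shape2"]])
}
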