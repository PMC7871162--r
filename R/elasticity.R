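# Elasticity decomposition: participation (from the probit), conditional
# (log-log coefficient read-off) and total (their sum).

#' Participation elasticity from a fitted probit
#'
#' For a log-transformed regressor `v` with fitted probit coefficient
#' `b_v`, the participation elasticity is
#' `b_v * dnorm(mean_linear_index) / participation_rate`: the standard
#' normal density evaluated at the mean linear index, scaled by the
#' coefficient and divided by the observed participation rate.
#'
#' @param fit a converged `probit_fit`.
#' @param variable `"price"` or `"income"`.
#' @return scalar elasticity (dimensionless).
#' @examples
#' f <- structure(list(coefficients = c(ln_price = 1),
#'                     converged = TRUE, mean_linear_index = 0,
#'                     participation_rate = 0.5), class = "probit_fit")
#' participation_elasticity(f, "price")  # dnorm(0) / 0.5 = 0.7978846
#' @export
participation_elasticity <- function(fit, variable = c("price", "income")) {
  variable <- match.arg(variable)
  if (!inherits(fit, "probit_fit"))
    stop("`fit` must be a probit_fit")
  if (!isTRUE(fit$converged))
    stop("probit fit did not converge; elasticity would be unreliable")
  r <- fit$participation_rate
  if (!is.finite(r) || r <= 0 || r >= 1)
    stop("participation rate must lie strictly in (0, 1), got ", r)
  b <- fit$coefficients[[elasticity_term(variable)]]
  b * stats::dnorm(fit$mean_linear_index) / r
}

#' Conditional elasticity from the log-log demand fit
#'
#' In a log-log demand regression the elasticity with respect to a
#' log-transformed regressor is its coefficient, returned unchanged.
#'
#' @param fit an `ols_fit`.
#' @param variable `"price"` or `"income"`.
#' @return scalar elasticity.
#' @export
conditional_elasticity <- function(fit, variable = c("price", "income")) {
  variable <- match.arg(variable)
  if (!inherits(fit, "ols_fit"))
    stop("`fit` must be an ols_fit")
  fit$coefficients[[elasticity_term(variable)]]
}

#' Total elasticity
#'
#' The total elasticity is the exact sum of the participation and
#' conditional components.
#'
#' @param participation participation elasticity (finite scalar).
#' @param conditional conditional elasticity (finite scalar).
#' @return their sum.
#' @export
total_elasticity <- function(participation, conditional) {
  if (!is.finite(participation) || !is.finite(conditional))
    stop("both elasticity components must be finite")
  participation + conditional
}

#' Per-quintile elasticity decomposition table
#'
#' Maps five per-quintile two-part fits to a 10-row table (5 quintiles x
#' price/income) of participation, conditional and total elasticities.
#' Totals satisfy the additive decomposition exactly by construction.
#'
#' @param fits list of five [fit_two_part()] results, quintiles 1..5.
#' @return `data.frame` with columns `quintile`, `variable`,
#'   `participation`, `conditional`, `total`.
#' @export
elasticity_table <- function(fits) {
  if (length(fits) != 5L)
    stop("`fits` must contain five (probit, ols) pairs, one per quintile; ",
         "got ", length(fits))
  qs <- vapply(fits, function(f) as.integer(f$quintile), integer(1))
  if (!setequal(qs, 1:5))
    stop("fits must cover quintiles 1..5 exactly; got: ",
         paste(sort(qs), collapse = ", "))
  fits <- fits[order(qs)]
  rows <- lapply(1:5, function(q) {
    f <- fits[[q]]
    do.call(rbind, lapply(c("price", "income"), function(v) {
      ep <- participation_elasticity(f$probit, v)
      ec <- conditional_elasticity(f$ols, v)
      data.frame(quintile = q, variable = v, participation = ep,
                 conditional = ec, total = total_elasticity(ep, ec))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Overall elasticity across quintiles
#'
#' Summarizes a decomposition table into a single figure per variable.
#' `method = "mean"` (default) takes the unweighted mean of the five
#' quintile totals; `method = "pooled"` requires the household table and
#' refits the two-part model on the pooled sample.
#'
#' @param tab an [elasticity_table()] result (for `method = "mean"`).
#' @param variable `"price"` or `"income"`.
#' @param method `"mean"` or `"pooled"`.
#' @param table pooled household table, required when `method = "pooled"`.
#' @return scalar overall total elasticity.
#' @export
overall_elasticity <- function(tab, variable = c("price", "income"),
                               method = c("mean", "pooled"), table = NULL) {
  variable <- match.arg(variable)
  method <- match.arg(method)
  if (method == "mean") {
    sub <- tab[tab$variable == variable, , drop = FALSE]
    if (nrow(sub) != 5L)
      stop("expected five quintile rows for variable ", variable)
    return(mean(sub$total))
  }
  if (is.null(table))
    stop("`table` is required for the pooled estimate")
  f <- fit_two_part(table, "all")
  total_elasticity(participation_elasticity(f$probit, variable),
                   conditional_elasticity(f$ols, variable))
}

elasticity_term <- function(variable) {
  switch(variable,
         price = "ln_price",
         income = "ln_income",
         stop("unknown variable: ", variable))
}
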