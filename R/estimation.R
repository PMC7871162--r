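# Two-part model estimation: probit participation by Newton ascent and
# least-squares conditional demand on the smoker subsample.

# probabilities are clipped to [EPS, 1 - EPS] inside the likelihood so
# log() stays finite under separation
PROBIT_EPS <- 1e-10

#' Probit log-likelihood
#'
#' Evaluates `sum(z * log(pnorm(W a)) + (1 - z) * log(1 - pnorm(W a)))`,
#' the binary-participation log-likelihood of the two-part model, with
#' probabilities clipped away from 0 and 1 by `1e-10`.
#'
#' @param coefficients numeric coefficient vector, one per design column.
#' @param design numeric covariate matrix (rows = observations).
#' @param outcome binary 0/1 vector, one per design row.
#' @return scalar log-likelihood (0 for empty data).
#' @examples
#' probit_loglik(0, matrix(1, 2, 1), c(1, 0))  # 2 * log(0.5)
#' @export
probit_loglik <- function(coefficients, design, outcome) {
  design <- as.matrix(design)
  if (nrow(design) == 0L) return(0)
  if (length(outcome) != nrow(design))
    stop("`outcome` length (", length(outcome),
         ") must match design rows (", nrow(design), ")")
  if (length(coefficients) != ncol(design))
    stop("coefficient length (", length(coefficients),
         ") must match design columns (", ncol(design), ")")
  if (!all(outcome %in% c(0, 1)))
    stop("`outcome` must be binary 0/1")
  p <- stats::pnorm(drop(design %*% coefficients))
  p <- pmin(pmax(p, PROBIT_EPS), 1 - PROBIT_EPS)
  sum(outcome * log(p) + (1 - outcome) * log1p(-p))
}

#' Fit a probit participation model by Newton ascent
#'
#' Maximizes [probit_loglik()] with analytic gradient and observed Hessian,
#' using step-halving when a full Newton step fails to improve the
#' likelihood. Standard errors come from the inverse of the observed
#' information at the optimum. The returned object also carries the mean
#' linear index (coefficients evaluated at the covariate means) and the
#' sample participation rate, the two ingredients of the participation
#' elasticity.
#'
#' @param design numeric covariate matrix including any intercept column.
#' @param outcome binary 0/1 vector.
#' @param tol convergence tolerance: the fit converges when the max
#'   absolute gradient falls below `tol * (1 + abs(loglik))` (relative to
#'   the likelihood scale, since the summed gradient grows with n).
#' @param max_iter maximum Newton iterations.
#' @return an object of class `probit_fit` with elements `coefficients`,
#'   `standard_errors`, `loglik`, `converged`, `n`, `mean_linear_index`,
#'   `participation_rate`, `iterations`.
#' @export
fit_probit <- function(design, outcome, tol = 1e-6, max_iter = 100L) {
  design <- as.matrix(design)
  storage.mode(design) <- "double"
  n <- nrow(design)
  p <- ncol(design)
  if (length(outcome) != n)
    stop("`outcome` length must match design rows")
  if (!all(outcome %in% c(0, 1)))
    stop("`outcome` must be binary 0/1")
  rate <- mean(outcome)
  if (rate <= 0 || rate >= 1)
    stop("outcome has a single class (participation rate ", rate,
         "); the probit is not estimable")
  check_full_rank(design)

  terms <- colnames(design)
  if (is.null(terms)) terms <- paste0("x", seq_len(p))
  z <- as.numeric(outcome)

  # start at intercept-only solution when an intercept column is present
  coef <- numeric(p)
  ic <- which(apply(design, 2L, function(col) all(col == col[1L]) &&
                      col[1L] != 0))[1L]
  if (!is.na(ic)) coef[ic] <- stats::qnorm(rate) / design[1L, ic]

  ll <- probit_loglik(coef, design, z)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- drop(design %*% coef)
    phi <- stats::dnorm(eta)
    P <- pmin(pmax(stats::pnorm(eta), PROBIT_EPS), 1 - PROBIT_EPS)
    lambda <- ifelse(z == 1, phi / P, -phi / (1 - P))  # score per obs
    grad <- drop(crossprod(design, lambda))
    gtol <- tol * (1 + abs(ll))
    if (max(abs(grad)) < gtol) { converged <- TRUE; break }
    if (iter > max_iter) break
    wt <- lambda * (lambda + eta)  # observed information weights
    H <- crossprod(design * wt, design)
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) break
    # step-halving ascent; accept up to summation round-off on ll
    s <- 1
    improved <- FALSE
    for (h in 1:30) {
      cand <- coef + s * step
      ll_new <- probit_loglik(cand, design, z)
      if (is.finite(ll_new) && ll_new > ll - 1e-10 * (1 + abs(ll))) {
        coef <- cand; ll <- ll_new; improved <- TRUE; break
      }
      s <- s / 2
    }
    if (!improved) {
      # stalled at floating-point resolution of the summed likelihood;
      # converged if the gradient is already negligible at this scale
      converged <- max(abs(grad)) < 1e-4 * (1 + abs(ll))
      break
    }
  }
  # quasi-separation: coefficients drifting without bound, or fitted
  # probabilities numerically 0/1 (the clipped likelihood flattens there,
  # so a small gradient is not evidence of an interior maximum)
  if (max(abs(coef)) > 50) converged <- FALSE
  if (max(abs(drop(design %*% coef))) > 7) converged <- FALSE

  eta <- drop(design %*% coef)
  phi <- stats::dnorm(eta)
  P <- pmin(pmax(stats::pnorm(eta), PROBIT_EPS), 1 - PROBIT_EPS)
  lambda <- ifelse(z == 1, phi / P, -phi / (1 - P))
  info <- crossprod(design * (lambda * (lambda + eta)), design)
  se <- rep(NA_real_, p)
  vcov_ok <- tryCatch({
    v <- solve(info)
    se <- sqrt(pmax(diag(v), 0))
    TRUE
  }, error = function(e) FALSE)
  if (!vcov_ok) converged <- FALSE

  structure(
    list(coefficients = stats::setNames(coef, terms),
         standard_errors = stats::setNames(se, terms),
         loglik = ll,
         converged = converged,
         n = n,
         mean_linear_index = sum(coef * colMeans(design)),
         participation_rate = rate,
         iterations = iter),
    class = "probit_fit"
  )
}

#' @export
print.probit_fit <- function(x, ...) {
  cat("Probit participation model: n =", x$n,
      "| logLik =", format(x$loglik, digits = 7),
      "|", if (x$converged) "converged" else "NOT CONVERGED", "\n")
  print(round(cbind(estimate = x$coefficients, se = x$standard_errors), 4))
  invisible(x)
}

#' Fit the conditional demand model by ordinary least squares
#'
#' Least-squares fit of log monthly consumption on the demand covariates,
#' smoker households only. Uses a QR decomposition; classical homoskedastic
#' standard errors.
#'
#' @param design numeric full-rank covariate matrix (rows = smoker
#'   households).
#' @param ln_consumption numeric response, log of monthly sticks smoked.
#' @return an object of class `ols_fit` with elements `coefficients`,
#'   `standard_errors`, `r_squared`, `n`, `residuals`, `sigma`.
#' @export
fit_ols <- function(design, ln_consumption) {
  design <- as.matrix(design)
  storage.mode(design) <- "double"
  n <- nrow(design)
  p <- ncol(design)
  if (length(ln_consumption) != n)
    stop("response length must match design rows")
  if (n <= p)
    stop("need more observations (", n, ") than coefficients (", p, ")")
  check_full_rank(design)
  terms <- colnames(design)
  if (is.null(terms)) terms <- paste0("x", seq_len(p))

  qr_d <- qr(design)
  coef <- qr.coef(qr_d, ln_consumption)
  resid <- ln_consumption - drop(design %*% coef)
  rss <- sum(resid^2)
  tss <- sum((ln_consumption - mean(ln_consumption))^2)
  s2 <- rss / (n - p)
  xtx_inv <- chol2inv(qr.R(qr_d))
  se <- sqrt(diag(xtx_inv) * s2)
  structure(
    list(coefficients = stats::setNames(as.numeric(coef), terms),
         standard_errors = stats::setNames(se, terms),
         r_squared = if (tss > 0) 1 - rss / tss else 0,
         n = n,
         residuals = resid,
         sigma = sqrt(s2)),
    class = "ols_fit"
  )
}

#' @export
print.ols_fit <- function(x, ...) {
  cat("Conditional demand (OLS): n =", x$n,
      "| R^2 =", format(x$r_squared, digits = 4), "\n")
  print(round(cbind(estimate = x$coefficients, se = x$standard_errors), 4))
  invisible(x)
}

#' Fit the two-part model for one expenditure quintile
#'
#' Subsets the household table to the requested quintile, fits the probit
#' participation model on all of its households and the log-linear demand
#' model on its smoker households, and returns both fits.
#'
#' @param table household `data.frame` in the [generate_households()]
#'   layout with a `quintile` column.
#' @param quintile quintile to fit (1..5), or `"all"` to pool every
#'   household.
#' @param verbose print the two estimation sample sizes.
#' @return list with elements `probit` ([fit_probit()] result), `ols`
#'   ([fit_ols()] result), `quintile`, `n_participation`, `n_conditional`.
#' @export
fit_two_part <- function(table, quintile, verbose = FALSE) {
  if (identical(quintile, "all")) {
    sub <- table
  } else {
    quintile <- check_quintile(quintile)
    sub <- table[table$quintile == quintile, , drop = FALSE]
    if (nrow(sub) == 0L)
      stop("no households in quintile ", quintile)
  }
  n_smokers <- sum(sub$smoke == 1L)
  if (n_smokers == 0L || n_smokers == nrow(sub))
    stop("quintile ", paste(quintile), " has ", n_smokers, " smokers out of ",
         nrow(sub), " households; both classes are required")
  W <- probit_design(sub)
  probit <- fit_probit(W, sub$smoke)
  smokers <- sub[sub$smoke == 1L, , drop = FALSE]
  X <- ols_design(smokers)
  ols <- fit_ols(X, log(smokers$sticks_month))
  if (verbose)
    message("quintile ", paste(quintile), ": participation n = ", nrow(sub),
            ", conditional n = ", nrow(smokers))
  list(probit = probit, ols = ols, quintile = quintile,
       n_participation = nrow(sub), n_conditional = nrow(smokers))
}

# rank / conditioning screen shared by both fitters
check_full_rank <- function(design, kappa_max = 1e8) {
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    bad <- colnames(design)[qr_d$pivot[(qr_d$rank + 1L):ncol(design)]]
    stop("design matrix is rank deficient; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  d <- abs(diag(qr.R(qr_d)))
  if (max(d) / min(d) > kappa_max)
    stop("design matrix is ill-conditioned (condition estimate > 1e8); ",
         "check for collinear covariates")
  invisible(TRUE)
}
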