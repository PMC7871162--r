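# Static excise-tax simulation: participation elasticities applied to
# stratum smoker counts under price-increase scenarios. No RNG anywhere.

#' Smokers in a population stratum
#'
#' Number of smokers implied by a stratum population and its smoking
#' prevalence, rounded to whole persons. A directly supplied smoker count
#' (as published projection tables often carry, computed from unrounded
#' prevalences) overrides the product.
#'
#' @param population persons in the stratum (non-negative).
#' @param prevalence smoking prevalence in `[0, 1]`.
#' @param smokers optional explicit smoker count overriding the product.
#' @return integer smoker count.
#' @examples
#' smokers_in_stratum(1e6, 0.2)  # 200000
#' @export
smokers_in_stratum <- function(population, prevalence, smokers = NULL) {
  if (!is.null(smokers)) {
    if (smokers < 0) stop("`smokers` must be non-negative")
    return(as.integer(round_half_away(smokers)))
  }
  if (!is.finite(population) || population < 0)
    stop("`population` must be a non-negative number")
  if (!is.finite(prevalence) || prevalence < 0 || prevalence > 1)
    stop("`prevalence` must lie in [0, 1]")
  as.integer(round_half_away(population * prevalence))
}

#' Smokers who quit under a price increase
#'
#' The static model: quitters = smokers x participation elasticity
#' (magnitude) x proportional price increase, rounded half-away-from-zero
#' to whole persons. When the elasticity-price product exceeds 1 the count
#' is capped at the current smokers with a warning.
#'
#' @param smokers current smokers in the stratum (non-negative).
#' @param participation_elasticity magnitude (absolute value) of the
#'   participation elasticity, non-negative.
#' @param price_increase proportional price increase (0.25 for +25%).
#' @return integer count of quitters.
#' @examples
#' quitters(1344040, 0.12, 0.50)  # 80642
#' @export
quitters <- function(smokers, participation_elasticity, price_increase) {
  if (!is.finite(smokers) || smokers < 0)
    stop("`smokers` must be non-negative")
  if (!is.finite(participation_elasticity) || participation_elasticity < 0)
    stop("`participation_elasticity` must be a non-negative magnitude")
  if (!is.finite(price_increase) || price_increase < 0)
    stop("`price_increase` must be non-negative")
  frac <- participation_elasticity * price_increase
  if (frac > 1) {
    warning("elasticity x price increase exceeds 1; quitters capped at ",
            "current smokers")
    frac <- 1
  }
  as.integer(round_half_away(smokers * frac))
}

#' Build a table of population strata
#'
#' Validates stratum inputs and derives smoker counts where not given.
#'
#' @param label stratum names (e.g. quintile labels).
#' @param population persons aged 15 and over per stratum.
#' @param prevalence smoking prevalence per stratum, in `[0, 1]`.
#' @param participation_elasticity non-negative elasticity magnitudes.
#' @param smokers optional explicit smoker counts (vector, NA to derive).
#' @return `data.frame` of class `population_strata`.
#' @export
population_strata <- function(label, population, prevalence,
                              participation_elasticity, smokers = NULL) {
  k <- length(label)
  if (!all(lengths(list(population, prevalence,
                        participation_elasticity)) == k))
    stop("all stratum vectors must share the length of `label`")
  if (any(population < 0)) stop("populations must be non-negative")
  if (any(prevalence < 0 | prevalence > 1))
    stop("prevalences must lie in [0, 1]")
  if (any(participation_elasticity < 0))
    stop("participation elasticities enter as non-negative magnitudes")
  if (is.null(smokers)) smokers <- rep(NA_real_, k)
  smokers <- vapply(seq_len(k), function(i) {
    if (is.na(smokers[i]))
      as.numeric(smokers_in_stratum(population[i], prevalence[i]))
    else as.numeric(smokers_in_stratum(population[i], prevalence[i],
                                       smokers = smokers[i]))
  }, numeric(1))
  if (any(smokers > population))
    stop("smokers cannot exceed the stratum population")
  structure(
    data.frame(label = as.character(label), population = population,
               prevalence = prevalence, smokers = smokers,
               participation_elasticity = participation_elasticity,
               stringsAsFactors = FALSE),
    class = c("population_strata", "data.frame")
  )
}

#' Default strata for the national male population aged 15+
#'
#' The published projection inputs: five expenditure quintiles of the male
#' population aged 15 and over (6,312,000 persons each), household smoking
#' prevalences 0.16/0.20/0.21/0.21/0.19, the smoker counts derived from
#' unrounded prevalences, and participation-elasticity magnitudes
#' 0.07-0.12. Household prevalence is taken as equivalent to prevalence
#' among males aged 15+, as the projection assumes.
#'
#' @return a [population_strata] table.
#' @export
default_strata <- function() {
  population_strata(
    label = c("Q1 (lowest)", "Q2", "Q3", "Q4", "Q5 (richest)"),
    population = rep(6312000, 5),
    prevalence = c(0.16, 0.20, 0.21, 0.21, 0.19),
    participation_elasticity = c(0.07, 0.11, 0.12, 0.12, 0.11),
    smokers = c(1041720, 1302300, 1344040, 1337630, 1256450)
  )
}

#' Published projection table (inputs and printed quitter cells)
#'
#' The full published projection of the national static simulation: for
#' each male expenditure quintile, the population aged 15+, household
#' smoking prevalence, smoker count, participation-elasticity magnitude,
#' and the printed quitter counts under 25/50/75% price increases. The
#' published Q1, Q2 and Q5 cells were evidently computed from unrounded
#' elasticities, so they differ slightly from products of the printed
#' inputs; this table records them as printed and does not recompute them.
#'
#' @return `data.frame` with columns `label`, `population`, `prevalence`,
#'   `smokers`, `participation_elasticity`, `quit_25`, `quit_50`,
#'   `quit_75`.
#' @seealso [default_strata()] for the input columns alone.
#' @export
published_projection <- function() {
  data.frame(
    label = c("Q1 (lowest)", "Q2", "Q3", "Q4", "Q5 (richest)"),
    population = rep(6312000, 5),
    prevalence = c(0.16, 0.20, 0.21, 0.21, 0.19),
    smokers = c(1041720, 1302300, 1344040, 1337630, 1256450),
    participation_elasticity = c(0.07, 0.11, 0.12, 0.12, 0.11),
    quit_25 = c(17709, 35162, 40321, 40129, 33924),
    quit_50 = c(35418, 70324, 80642, 80258, 67848),
    quit_75 = c(53127, 105486, 120963, 120387, 101772),
    stringsAsFactors = FALSE
  )
}

#' Run price-increase scenarios over population strata
#'
#' Fills the stratum-by-scenario quitter matrix cell by cell with
#' [quitters()]; totals are exact column sums and the percent quitting is
#' `100 * total_quitters / total_smokers`.
#'
#' @param strata a [population_strata] table (or data.frame with its
#'   columns).
#' @param price_increases numeric vector of proportional increases, e.g.
#'   `c(0.25, 0.5, 0.75)`.
#' @param include_baseline also include a zero-increase column.
#' @return object of class `scenario_result`: list with `strata`,
#'   `price_increases`, `quitters` (matrix stratum x scenario),
#'   `total_smokers`, `total_quitters` (per scenario), `percent_quit`.
#' @examples
#' res <- run_scenarios(default_strata(), c(0.25, 0.5, 0.75))
#' res$total_quitters
#' @export
run_scenarios <- function(strata, price_increases = c(0.25, 0.5, 0.75),
                          include_baseline = FALSE) {
  if (NROW(strata) == 0L) stop("`strata` must be non-empty")
  if (length(price_increases) == 0L)
    stop("`price_increases` must be non-empty")
  if (any(!is.finite(price_increases) | price_increases < 0))
    stop("price increases must be non-negative proportions")
  if (include_baseline) price_increases <- c(0, price_increases)
  need <- c("label", "smokers", "participation_elasticity")
  missing_cols <- setdiff(need, names(strata))
  if (length(missing_cols))
    stop("strata table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  qmat <- vapply(price_increases, function(dp) {
    vapply(seq_len(nrow(strata)), function(i) {
      quitters(strata$smokers[i], strata$participation_elasticity[i], dp)
    }, integer(1))
  }, integer(nrow(strata)))
  qmat <- matrix(qmat, nrow = nrow(strata),
                 dimnames = list(strata$label,
                                 paste0(100 * price_increases, "%")))
  total_smokers <- sum(strata$smokers)
  total_quitters <- colSums(qmat)
  structure(
    list(strata = strata,
         price_increases = price_increases,
         quitters = qmat,
         total_smokers = total_smokers,
         total_quitters = total_quitters,
         percent_quit = 100 * total_quitters / total_smokers),
    class = "scenario_result"
  )
}

#' Format a scenario projection as a report table
#'
#' Renders the stratum-by-scenario projection, the column totals and the
#' percent-quit line as a `data.frame` ready for printing or CSV export.
#'
#' @param result a [run_scenarios()] result.
#' @return `data.frame` with one row per stratum plus `Total` and
#'   `% of smokers` rows.
#' @export
scenario_report <- function(result) {
  if (!inherits(result, "scenario_result"))
    stop("`result` must come from run_scenarios()")
  s <- result$strata
  body <- data.frame(
    stratum = s$label,
    population = s$population,
    prevalence = s$prevalence,
    smokers = s$smokers,
    participation_elasticity = s$participation_elasticity,
    stringsAsFactors = FALSE
  )
  qcols <- as.data.frame(result$quitters)
  names(qcols) <- paste0("quit_", colnames(result$quitters))
  body <- cbind(body, qcols)
  total <- data.frame(
    stratum = "Total",
    population = sum(s$population),
    prevalence = NA_real_,
    smokers = result$total_smokers,
    participation_elasticity = NA_real_,
    stringsAsFactors = FALSE
  )
  total <- cbind(total,
                 stats::setNames(as.data.frame(t(result$total_quitters)),
                                 names(qcols)))
  pct <- data.frame(
    stratum = "% of smokers",
    population = NA_real_, prevalence = NA_real_, smokers = NA_real_,
    participation_elasticity = NA_real_,
    stringsAsFactors = FALSE
  )
  pct <- cbind(pct,
               stats::setNames(as.data.frame(t(round(result$percent_quit,
                                                     1))),
                               names(qcols)))
  rbind(body, total, pct)
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("Static price-increase projection:",
      format(x$total_smokers, big.mark = ","), "smokers\n")
  print(scenario_report(x), row.names = FALSE)
  invisible(x)
}

# round-half-away-from-zero (not R's banker rounding)
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}
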