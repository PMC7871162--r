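# Shared I/O: household CSV dialect, quintile assignment, descriptive
# statistics, coefficient tables.

#' Assign expenditure quintiles by ranking
#'
#' Ranks households by expenditure per equivalent adult and cuts the
#' ranking at the 20/40/60/80 percentiles into labels 1 (poorest) to 5
#' (richest). Ties are broken by stable input order. The degenerate case of
#' zero expenditure variance assigns every household to quintile 1 with a
#' warning.
#'
#' @param table household `data.frame` with a positive `expenditure_pea`
#'   column.
#' @return the table with its `quintile` column (re)written.
#' @export
assign_quintiles <- function(table) {
  if (!"expenditure_pea" %in% names(table))
    stop("table lacks an `expenditure_pea` column")
  x <- table$expenditure_pea
  n <- length(x)
  if (n < 5L)
    stop("need at least 5 households to form quintiles, got ", n)
  if (any(!is.finite(x) | x <= 0))
    stop("`expenditure_pea` must be positive and finite")
  if (stats::var(x) == 0) {
    warning("all expenditures identical; assigning every household to ",
            "quintile 1")
    table$quintile <- rep.int(1L, n)
    return(table)
  }
  ord <- order(x)  # stable: ties keep input order
  ranks <- integer(n)
  ranks[ord] <- seq_len(n)
  table$quintile <- as.integer(floor((ranks - 1L) * 5L / n) + 1L)
  table
}

#' Per-quintile descriptive statistics
#'
#' Summarizes a household table the way survey descriptives are reported:
#' per quintile, the household count, mean expenditure per equivalent
#' adult, the percentage of households smoking, the mean percentage of
#' expenditure spent on cigarettes among smokers, mean sticks smoked per
#' day among smokers (monthly sticks / 30), and the mean
#' university-education share. Smoker-conditional entries are `NA` for
#' quintiles without smokers.
#'
#' Cigarette spending is reconstructed as `exp(ln_price) * sticks_month /
#' 20`, treating the recorded price as a 20-stick pack price.
#'
#' @param table household `data.frame` with quintiles assigned.
#' @return `data.frame` with one row per quintile.
#' @export
descriptive_stats <- function(table) {
  if (!"quintile" %in% names(table))
    stop("assign quintiles before computing descriptive statistics")
  rows <- lapply(sort(unique(table$quintile)), function(q) {
    sub <- table[table$quintile == q, , drop = FALSE]
    smokers <- sub[sub$smoke == 1L, , drop = FALSE]
    has_smokers <- nrow(smokers) > 0L
    spend_share <- if (has_smokers) {
      spend <- exp(smokers$ln_price) * smokers$sticks_month / 20
      100 * mean(spend / smokers$expenditure_pea)
    } else NA_real_
    data.frame(
      quintile = q,
      n_households = nrow(sub),
      mean_expenditure_pea = mean(sub$expenditure_pea),
      pct_smoking = 100 * mean(sub$smoke),
      pct_spend_on_cigarettes = spend_share,
      mean_sticks_per_day = if (has_smokers)
        mean(smokers$sticks_month) / 30 else NA_real_,
      mean_univ_share = 100 * mean(sub$share_univ_edu)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a household table to CSV
#'
#' One header row, one row per household, comma-separated, UTF-8, decimal
#' point. Missing consumption is written as an empty field. Provenance
#' (package version and seed, when given) goes into `#`-prefixed comment
#' lines above the header.
#'
#' @param table household `data.frame`.
#' @param path output file path.
#' @param seed seed to record in the provenance header (optional).
#' @return `path`, invisibly.
#' @export
write_households <- function(table, path, seed = NULL) {
  write_csv_prov(table, path, seed = seed)
}

#' Read a household CSV written by [write_households()]
#'
#' @param path CSV path.
#' @return household `data.frame` with `head_education` restored as a
#'   factor.
#' @export
read_households <- function(path) {
  out <- utils::read.csv(path, comment.char = "#",
                         stringsAsFactors = FALSE)
  if ("head_education" %in% names(out))
    out$head_education <- factor(out$head_education, levels = EDU_LEVELS)
  if ("sticks_month" %in% names(out))
    out$sticks_month <- as.numeric(out$sticks_month)
  out
}

# CSV writer with provenance comment header; results only, never logs
write_csv_prov <- function(df, path, seed = NULL) {
  ver <- as.character(utils::packageVersion("cigdemand"))
  hdr <- c(paste0("# cigdemand ", ver),
           if (!is.null(seed)) paste0("# seed: ", seed))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, qmethod =
                       "double", na = "")
  invisible(path)
}

#' Coefficient table for reporting
#'
#' Flattens per-quintile two-part fits into a long table of terms,
#' estimates, standard errors and significance stars (at 0.05 / 0.01 /
#' 0.001) for each model part.
#'
#' @param fits list of [fit_two_part()] results.
#' @return `data.frame` with columns `quintile`, `part`, `term`,
#'   `estimate`, `se`, `stars`.
#' @export
coefficient_table <- function(fits) {
  rows <- lapply(fits, function(f) {
    one <- function(fit, part) {
      est <- fit$coefficients
      se <- fit$standard_errors
      zval <- est / se
      pval <- 2 * stats::pnorm(-abs(zval))
      data.frame(quintile = f$quintile, part = part, term = names(est),
                 estimate = as.numeric(est), se = as.numeric(se),
                 stars = stars_for(pval), stringsAsFactors = FALSE)
    }
    rbind(one(f$probit, "participation"), one(f$ols, "conditional"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

stars_for <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*",
                                                         "")))
}
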