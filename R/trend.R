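## Trend coding of Ne / suitable-area / temperature changes between paleo
## periods, contingency tables, chi-squared and Phi association statistics.

#' Code the change between two periods
#'
#' The change is `delta = earlier - later` (the most recent period's value
#' subtracted from the previous period's); negative deltas code as
#' `"increasing"`, positive as `"decreasing"`, zero as `"stable"`.
#'
#' @param value_earlier,value_later Finite numeric vectors (recycled).
#' @return Character vector over `"increasing"`, `"decreasing"`, `"stable"`.
#' @examples
#' code_change(100, 150)  # increasing
#' @export
code_change <- function(value_earlier, value_later) {
  if (any(!is.finite(value_earlier)) || any(!is.finite(value_later)))
    stop("values must be finite")
  delta <- value_earlier - value_later
  ifelse(delta < 0, "increasing", ifelse(delta > 0, "decreasing", "stable"))
}

#' Nominal ages (years BP) of the analysis periods
#' @return Named numeric vector.
#' @export
period_ages <- function() {
  c(present = 0, EarlyHolocene = 10e3, LGM = 20e3, LIG = 130e3,
    MIS19 = 787e3)
}

#' Build a per-species trend table over period pairs
#'
#' For each species and period pair (default MIS19 to LIG and LIG to LGM),
#' codes the change in Ne (trajectory value at each period's nominal age),
#' suitable area, and global temperature with [code_change()].
#'
#' @param trajectories Named list (by species) of year-scaled
#'   `demographic_trajectory` objects.
#' @param area_series Named list (by species) of `area_series` data frames
#'   from [project_and_area()].
#' @param temperature Data frame `age_years`, `temp_c` (a global
#'   mean-surface-temperature reconstruction); the same coding is applied to
#'   every species.
#' @param metadata Data frame with `species`, `habitat`, `climate` columns.
#' @param period_pairs List of `c(earlier, later)` period-label pairs.
#' @return Data frame `species`, `pair`, `ne_code`, `area_code`,
#'   `temp_code`, `habitat`, `climate`.
#' @export
build_trend_table <- function(trajectories, area_series, temperature,
                              metadata,
                              period_pairs = list(c("MIS19", "LIG"),
                                                  c("LIG", "LGM"))) {
  ages <- period_ages()
  temp_at <- function(age) approx(temperature$age_years, temperature$temp_c,
                                  xout = age, rule = 2)$y
  rows <- list()
  for (sp in names(trajectories)) {
    tr <- trajectories[[sp]]
    ar <- area_series[[sp]]
    md <- metadata[metadata$species == sp, , drop = FALSE]
    for (pp in period_pairs) {
      earlier <- pp[1L]; later <- pp[2L]
      ne_e <- trajectory_at(tr, ages[[earlier]])
      ne_l <- trajectory_at(tr, ages[[later]])
      a_e <- ar$area_km2[ar$period == earlier]
      a_l <- ar$area_km2[ar$period == later]
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, pair = paste0(earlier, "->", later),
        ne_code = code_change(ne_e, ne_l),
        area_code = code_change(a_e, a_l),
        temp_code = code_change(temp_at(ages[[earlier]]),
                                temp_at(ages[[later]])),
        habitat = if (nrow(md)) md$habitat[1L] else NA_character_,
        climate = if (nrow(md)) md$climate[1L] else NA_character_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-tabulate coded trends
#'
#' Builds the contingency table of two code columns of a trend table. With
#' `drop_stable = TRUE` (the Phi convention: Phi requires binomial data),
#' species carrying a `"stable"` code in either column are excluded first.
#'
#' @param trend_table A [build_trend_table()] data frame (or any data frame
#'   with the requested columns).
#' @param rows,cols Column names to cross-tabulate (default `ne_code` vs
#'   `area_code`).
#' @param subset Optional logical vector or expression result to filter rows
#'   (e.g. `trend_table$climate == "tropical"`).
#' @param drop_stable Drop rows with a `"stable"` code in either column.
#' @return A contingency matrix of counts.
#' @export
build_contingency <- function(trend_table, rows = "ne_code",
                              cols = "area_code", subset = NULL,
                              drop_stable = FALSE) {
  tt <- if (is.null(subset)) trend_table else trend_table[subset, ,
                                                          drop = FALSE]
  if (drop_stable)
    tt <- tt[tt[[rows]] != "stable" & tt[[cols]] != "stable", ,
             drop = FALSE]
  if (!nrow(tt)) stop("no species left after filtering")
  table(tt[[rows]], tt[[cols]], dnn = c(rows, cols))
}

#' Chi-squared independence test on a contingency table
#'
#' Pearson's chi-squared with `(r-1)(c-1)` degrees of freedom; for 2x2
#' tables the Yates continuity correction is applied by default (both
#' statistics are returned).
#'
#' @param counts Contingency matrix of non-negative counts.
#' @param correction Apply the continuity correction for 2x2 tables
#'   (default TRUE).
#' @return List with `chi2` (as requested by `correction`),
#'   `chi2_uncorrected`, `chi2_corrected` (NA unless 2x2), `df`, `p`, `n`.
#' @export
chi_squared <- function(counts, correction = TRUE) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal: chi-squared undefined")
  unc <- suppressWarnings(chisq.test(counts, correct = FALSE))
  is2x2 <- all(dim(counts) == 2L)
  cor2 <- if (is2x2)
    suppressWarnings(chisq.test(counts, correct = TRUE)) else NULL
  use <- if (correction && is2x2) cor2 else unc
  list(chi2 = unname(use$statistic),
       chi2_uncorrected = unname(unc$statistic),
       chi2_corrected = if (is2x2) unname(cor2$statistic) else NA_real_,
       df = unname(unc$parameter), p = unname(use$p.value),
       n = sum(counts))
}

#' Phi coefficient of a 2x2 contingency table
#'
#' `(ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d))`, uncorrected; ranges from -1
#' (negative association) to +1 (positive association). A zero marginal
#' leaves Phi undefined (NA).
#'
#' @param counts A 2x2 contingency matrix.
#' @return Phi in \[-1, 1\], or NA.
#' @export
phi_coefficient <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == 2L)) stop("phi requires a 2x2 table")
  a <- counts[1, 1]; b <- counts[1, 2]; c <- counts[2, 1]; d <- counts[2, 2]
  den <- sqrt(prod(c(a + b, c + d, a + c, b + d)))
  if (den == 0) return(NA_real_)
  (a * d - b * c) / den
}

#' Association report across trend-table subsets
#'
#' Runs the chi-squared test (corrected and uncorrected for 2x2) and, where
#' the table is 2x2 after dropping stable codes, the Phi coefficient, for
#' each requested subset of the trend table.
#'
#' @param trend_table A [build_trend_table()] data frame.
#' @param rows,cols Code columns to associate.
#' @param subsets Named list of logical vectors (NULL entry = all rows).
#' @return Data frame `subset`, `rows`, `cols`, `n`, `chi2_corrected`,
#'   `chi2_uncorrected`, `p`, `phi`, `n_phi`.
#' @export
association_report <- function(trend_table, rows = "ne_code",
                               cols = "area_code",
                               subsets = list(all = NULL)) {
  out <- list()
  for (nm in names(subsets)) {
    res <- data.frame(subset = nm, rows = rows, cols = cols, n = NA_integer_,
                      chi2_corrected = NA_real_, chi2_uncorrected = NA_real_,
                      p = NA_real_, phi = NA_real_, n_phi = NA_integer_)
    tab <- tryCatch(build_contingency(trend_table, rows, cols,
                                      subset = subsets[[nm]]),
                    error = function(e) NULL)
    if (!is.null(tab)) {
      cs <- tryCatch(chi_squared(tab), error = function(e) NULL)
      if (!is.null(cs)) {
        res$n <- cs$n; res$p <- cs$p
        res$chi2_corrected <- cs$chi2_corrected
        res$chi2_uncorrected <- cs$chi2_uncorrected
      }
    }
    tab2 <- tryCatch(build_contingency(trend_table, rows, cols,
                                       subset = subsets[[nm]],
                                       drop_stable = TRUE),
                     error = function(e) NULL)
    if (!is.null(tab2) && all(dim(tab2) == 2L)) {
      res$phi <- phi_coefficient(tab2)
      res$n_phi <- sum(tab2)
    }
    out[[nm]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
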