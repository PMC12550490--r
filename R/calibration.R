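## Real-time calibration of SMC trajectories, mean-Ne summaries, and
## normalized group-mean curves.

#' Calibrate the per-generation mutation rate from divergence data
#'
#' Generation time is `g = alpha + L / 2` (age at maturity plus half the
#' reproductive longevity); the genome-wide mutation rate follows from the
#' pairwise genomic distance `d` to the most recent ancestor and its
#' divergence time `T`: `mu_per_gen = d * g / (2 * T)` and
#' `mu_per_year = d / (2 * T)`. When the ancestral node spans several
#' species, pass the mean of the pairwise distances as `d`.
#'
#' @param d Pairwise genomic distance (substitutions per site).
#' @param T_years Divergence time in years.
#' @param alpha Age at sexual maturity (years).
#' @param L Reproductive longevity (years).
#' @return A `calibration_params` list: `d`, `T_years`, `alpha`, `L`, `g`,
#'   `mu_per_gen`, `mu_per_year`.
#' @examples
#' calibrate(d = 0.012, T_years = 3e7, alpha = 12, L = 30)
#' @export
calibrate <- function(d, T_years, alpha, L) {
  if (any(c(d, T_years, alpha, L) <= 0)) stop("all inputs must be positive")
  g <- alpha + L / 2
  structure(list(d = d, T_years = T_years, alpha = alpha, L = L, g = g,
                 mu_per_gen = d * g / (2 * T_years),
                 mu_per_year = d / (2 * T_years)),
            class = "calibration_params")
}

#' Scale a coalescent-unit trajectory to years and diploid Ne
#'
#' Computes the reference size `N0 = theta / (4 * mu_per_gen * bin_size)`
#' from the fitted scaled mutation rate; times (in `2 * N0` units) are
#' multiplied by `2 * N0 * g` years and relative sizes by `N0`.
#'
#' @param traj A `demographic_trajectory` in coalescent units.
#' @param calib A [calibrate()] result.
#' @param bin_size_bp Bin width the track was built with (default 100).
#' @return The trajectory in years/diploid-Ne units (`units = "years"`),
#'   with any bootstrap replicates scaled identically.
#' @export
scale_to_years <- function(traj, calib, bin_size_bp = 100L) {
  stopifnot(inherits(traj, "demographic_trajectory"),
            inherits(calib, "calibration_params"))
  if (identical(traj$units, "years")) stop("trajectory already in years")
  n0 <- traj$theta / (4 * calib$mu_per_gen * bin_size_bp)
  out <- traj
  out$steps$time <- traj$steps$time * 2 * n0 * calib$g
  out$steps$ne <- traj$steps$ne * n0
  out$units <- "years"
  out$n0 <- n0
  out$calibration <- calib
  if (!is.null(traj$bootstrap))
    out$bootstrap <- lapply(traj$bootstrap, scale_to_years, calib = calib,
                            bin_size_bp = bin_size_bp)
  out
}

#' Evaluate a stepwise trajectory at given times
#'
#' @param traj A `demographic_trajectory`.
#' @param times Times in the trajectory's units.
#' @return Ne values (step function, left-continuous from each step's time).
#' @export
trajectory_at <- function(traj, times) {
  idx <- findInterval(times, traj$steps$time)
  traj$steps$ne[pmax(idx, 1L)]
}

#' Mean Ne of a trajectory, excluding the most recent points
#'
#' Very recent SMC estimates are noisy (few coalescent events), so the mean
#' excludes the `exclude_recent` most recent time points (default 4), the
#' convention used for the comparative analyses.
#'
#' @param traj A `demographic_trajectory`.
#' @param exclude_recent Number of most recent steps to drop.
#' @return Arithmetic mean of the remaining step Ne values.
#' @export
mean_ne <- function(traj, exclude_recent = 4L) {
  st <- traj$steps[order(traj$steps$time), , drop = FALSE]
  if (nrow(st) <= exclude_recent)
    stop("trajectory has too few steps to exclude ", exclude_recent)
  if (exclude_recent > 0L) st <- st[-seq_len(exclude_recent), , drop = FALSE]
  mean(st$ne)
}

#' Min-max normalized, group-averaged Ne curves
#'
#' Each species' step trajectory (in years) is restricted to the time window,
#' normalized, evaluated on a common log-spaced time grid, and averaged per
#' group. Normalization is min-max to \[0, 1\] by default; `mode = "max"`
#' divides by the maximum only (the per-period display convention).
#'
#' @param trajectories Named list of year-scaled `demographic_trajectory`
#'   objects.
#' @param grouping Optional character vector (recycled/matched by name):
#'   group label per species; default one group `"all"`.
#' @param time_window Years, default `c(1e4, 1e7)` (10 kya to 10 Mya).
#' @param grid_n Number of log-spaced grid points (default 64).
#' @param mode `"minmax"` or `"max"`.
#' @return Data frame `group`, `time_years`, `mean_norm_ne`, `n_species`.
#' @export
normalize_and_average <- function(trajectories, grouping = NULL,
                                  time_window = c(1e4, 1e7), grid_n = 64L,
                                  mode = c("minmax", "max")) {
  mode <- match.arg(mode)
  stopifnot(length(trajectories) >= 1L)
  if (is.null(grouping)) grouping <- rep("all", length(trajectories))
  grouping <- rep(grouping, length.out = length(trajectories))
  grid <- exp(seq(log(time_window[1]), log(time_window[2]),
                  length.out = grid_n))
  norm_curves <- lapply(trajectories, function(tr) {
    stopifnot(inherits(tr, "demographic_trajectory"))
    if (!identical(tr$units, "years"))
      stop("trajectories must be scaled to years first")
    v <- trajectory_at(tr, grid)
    in_win <- tr$steps$time >= time_window[1] & tr$steps$time <= time_window[2]
    vals <- c(v, tr$steps$ne[in_win])
    lo <- min(vals); hi <- max(vals)
    if (hi == lo) {
      warning("constant trajectory in window: normalized to 0.5")
      return(rep(0.5, grid_n))
    }
    if (mode == "minmax") (v - lo) / (hi - lo) else v / hi
  })
  out <- do.call(rbind, lapply(unique(grouping), function(g) {
    m <- do.call(rbind, norm_curves[grouping == g])
    data.frame(group = g, time_years = grid, mean_norm_ne = colMeans(m),
               n_species = sum(grouping == g))
  }))
  rownames(out) <- NULL
  out
}

#' Write a trajectory (with bootstrap replicates) as TSV
#'
#' Columns `time_years` (or `time` for coalescent units), `ne`,
#' `replicate_id` (0 = point estimate).
#'
#' @param traj A `demographic_trajectory`.
#' @param path Output path.
#' @export
write_trajectory_tsv <- function(traj, path) {
  tcol <- if (identical(traj$units, "years")) "time_years" else "time"
  main <- data.frame(traj$steps$time, traj$steps$ne, 0L)
  names(main) <- c(tcol, "ne", "replicate_id")
  rows <- list(main)
  for (i in seq_along(traj$bootstrap)) {
    b <- traj$bootstrap[[i]]
    d <- data.frame(b$steps$time, b$steps$ne, i)
    names(d) <- names(main)
    rows[[i + 1L]] <- d
  }
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
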