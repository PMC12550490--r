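## End-to-end orchestration on synthetic data: configuration, the demo run
## wiring every stage together, and the combined report.

#' Default pipeline configuration
#'
#' All stage parameters with the study's settings as defaults: the
#' 64-atomic/`"2+2+25*2+4+6"` discretization with `t_max = 15` and
#' theta/rho ratio 5, 30 bootstrap replicates, 4.5 km occurrence thinning,
#' a 10-degree crop buffer, 10,000 background points, 4-fold evaluation with
#' an AUC gate of 0.7, the 0.36 suitability/area threshold, a PRR p-value
#' threshold of 0.01, and the binary at-risk/not-at-risk status dichotomy.
#' Unknown keys in `...` are rejected.
#'
#' @param ... Named overrides of the defaults.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(pattern = "2+2+25*2+4+6", n_atomic = 64L, t_max = 15,
              theta_rho_ratio = 5, n_bootstrap = 30L, bin_size_bp = 100L,
              thin_km = 4.5, buffer_deg = 10, n_background = 10000L,
              kfold = 4L, auc_min = 0.7, area_threshold = 0.36,
              prr_p_max = 0.01, exclude_recent_ne = 4L, min_occurrences = 15L,
              seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

## deterministic per-stage seed fan-out from one global seed
stage_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}

#' Run the full pipeline on a synthetic world
#'
#' Generates a small multi-species synthetic world (coalescent genomes with
#' distinct demographic histories, per-species niche worlds with period
#' shifts, a shared phylogeny) and runs every stage: heterozygosity, SMC
#' demographic inference, year scaling, niche model selection and
#' paleo-projection, trend coding and association tests, and the PGLS
#' comparative models. Deterministic given `seed`.
#'
#' @param seed Global seed; per-stage seeds are derived by stable hashing.
#' @param n_species Number of species (default 6).
#' @param sequence_length_bp Per-species genome length (default 5e5; demo
#'   scale).
#' @param n_em_iters EM iterations per SMC fit (default 10; demo scale).
#' @param grid_shape Niche grid (default 40 x 40).
#' @param n_occurrences Occurrences per species (default 150).
#' @param n_background Background points (default 2000; demo scale).
#' @param feature_grid Candidate feature classes (default `c("L", "LQ")`;
#'   demo scale).
#' @param n_bootstrap Bootstrap replicates per species (default 0; the full
#'   study setting is 30).
#' @param config A [pipeline_config()] for the remaining settings.
#' @return A `pipeline_result` list: per-species fits and trajectories,
#'   heterozygosities, area series, trend table, association reports, PGLS
#'   fits, and the inputs needed to plot.
#' @export
run_demo <- function(seed = 1L, n_species = 6L, sequence_length_bp = 5e5,
                     n_em_iters = 10L, grid_shape = c(40L, 40L),
                     n_occurrences = 150L, n_background = 2000L,
                     feature_grid = c("L", "LQ"), n_bootstrap = 0L,
                     config = pipeline_config(seed = seed)) {
  disc <- parse_pattern(config$pattern, config$n_atomic, config$t_max)
  species <- sprintf("sp%02d", seq_len(n_species))
  temperature <- synthetic_temperature_series()

  # distinct demographic histories cycling over three shapes
  shapes <- list(
    function(ne) data.frame(start_gen = 0, ne = ne),
    function(ne) data.frame(start_gen = c(0, 2 * ne), ne = c(ne / 4, ne)),
    function(ne) data.frame(start_gen = c(0, 2 * ne), ne = c(ne, ne / 4)))

  traj <- list(); hets <- numeric(0); fits <- list(); calibs <- list()
  for (i in seq_len(n_species)) {
    sp <- species[i]
    s_i <- stage_seed(seed, i)
    set.seed(s_i)
    ne_base <- round(runif(1, 8e3, 2e4))
    mu <- 10^runif(1, -8.3, -7.7)
    sc <- demography_scenario(shapes[[1L + (i - 1L) %% 3L]](ne_base),
                              mutation_rate = mu, recombination_rate = mu,
                              sequence_length_bp = sequence_length_bp,
                              seed = s_i)
    sim <- simulate_het_track(sc, bin_size_bp = config$bin_size_bp)
    fit <- fit_smc(sim$track, disc, n_em_iters = n_em_iters)
    if (n_bootstrap > 0L)
      fit$trajectory$bootstrap <- bootstrap_smc(
        sim$track, disc, n_reps = n_bootstrap,
        segment_size_bp = max(5e4, sequence_length_bp / 10),
        seed = stage_seed(seed, 100L + i), n_em_iters = n_em_iters)
    set.seed(stage_seed(seed, 200L + i))
    cal <- calibrate(d = runif(1, 0.005, 0.02), T_years = runif(1, 1e7, 5e7),
                     alpha = runif(1, 8, 20), L = runif(1, 20, 50))
    tr <- scale_to_years(fit$trajectory, cal, config$bin_size_bp)
    tr$species <- sp
    fits[[sp]] <- fit; calibs[[sp]] <- cal; traj[[sp]] <- tr
    hets[sp] <- length(sim$het_pos) / sc$sequence_length_bp
  }

  # niche worlds: per-species coefficients; LGM shift shrinks suitability
  areas <- list(); enms <- list()
  for (i in seq_len(n_species)) {
    sp <- species[i]
    ns <- niche_scenario(grid_shape = grid_shape,
                         coef = list(intercept = -4,
                                     linear = c(clim1 = 4, clim2 = -2)),
                         n_occurrences = n_occurrences,
                         seed = stage_seed(seed, 300L + i))
    world <- simulate_rasters_and_occurrences(ns, species = sp)
    occ <- thin_occurrences(world$occurrences, min_distance_km = config$thin_km,
                            seed = stage_seed(seed, 400L + i),
                            crs = "planar_km")
    pca <- raster_pca(world$stacks$present)
    sel <- evaluate_and_select(occ, pca$scores, feature_grid = feature_grid,
                               k = config$kfold,
                               n_background = n_background,
                               seed = stage_seed(seed, 500L + i),
                               auc_min = config$auc_min)
    if (is.null(sel$selected)) next
    areas[[sp]] <- project_and_area(sel$selected, world$stacks,
                                    pca$transform,
                                    threshold = config$area_threshold)
    enms[[sp]] <- list(world = world, occ = occ, pca = pca, selection = sel)
  }

  meta <- data.frame(species = species,
                     habitat = rep(c("aquatic", "terrestrial"),
                                   length.out = n_species),
                     climate = rep(c("tropical", "tropical", "temperate"),
                                   length.out = n_species))
  kept <- intersect(names(traj), names(areas))
  trends <- build_trend_table(traj[kept], areas[kept], temperature, meta)
  assoc_area <- association_report(trends, "ne_code", "area_code",
                                   subsets = list(
                                     all = NULL,
                                     "MIS19->LIG" = trends$pair == "MIS19->LIG",
                                     "LIG->LGM" = trends$pair == "LIG->LGM"))
  assoc_temp <- association_report(trends, "ne_code", "temp_code",
                                   subsets = list(
                                     all = NULL,
                                     tropical = trends$climate == "tropical",
                                     aquatic = trends$habitat == "aquatic"))

  # comparative table from the computed quantities on a shared random tree
  set.seed(stage_seed(seed, 900L))
  tree <- ape::rphylo(n_species, birth = 1, death = 0)
  tree$tip.label <- species
  comp <- data.frame(
    species = species,
    H = hets[species],
    mean_Ne = vapply(species, function(sp)
      mean_ne(traj[[sp]], config$exclude_recent_ne), numeric(1)),
    status = sample(c("At risk", "Not at risk"), n_species, replace = TRUE),
    current_area_km2 = vapply(species, function(sp)
      if (sp %in% kept) areas[[sp]]$area_km2[areas[[sp]]$period == "present"]
      else NA_real_, numeric(1)),
    mean_past_area_km2 = vapply(species, function(sp)
      if (sp %in% kept)
        mean(areas[[sp]]$area_km2[areas[[sp]]$period != "present"])
      else NA_real_, numeric(1)))
  comp <- comp[complete.cases(comp), , drop = FALSE]
  pgls <- if (nrow(comp) >= 4L) run_pgls_models(comp, tree) else list()

  structure(list(species = species, fits = fits, trajectories = traj,
                 heterozygosity = hets, calibrations = calibs,
                 area_series = areas, enms = enms, trend_table = trends,
                 association_area = assoc_area,
                 association_temperature = assoc_temp,
                 comparative = list(tree = tree, table = comp),
                 pgls = pgls, temperature = temperature,
                 config = config, seed = seed),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:", length(x$species), "species;",
      length(x$area_series), "with a selected niche model\n")
  cat("association (Ne vs area, all pairs): chi2_corr =",
      signif(x$association_area$chi2_corrected[1], 3), "\n")
  invisible(x)
}

#' Per-species demography / niche panel
#'
#' One species' year-scaled Ne trajectory (with bootstrap envelope when
#' available), the per-period suitable-area series, and the global
#' temperature curve, as a single faceted ggplot.
#'
#' @param traj Year-scaled `demographic_trajectory`.
#' @param area An `area_series` for the same species.
#' @param temperature Data frame `age_years`, `temp_c`.
#' @return A ggplot object.
#' @export
plot_species_panel <- function(traj, area, temperature) {
  ages <- period_ages()
  dd <- data.frame(time = traj$steps$time, value = traj$steps$ne,
                   panel = "Ne")
  tdf <- data.frame(time = temperature$age_years,
                    value = temperature$temp_c, panel = "Temperature")
  adf <- data.frame(time = unname(ages[area$period]),
                    value = area$area_km2, panel = "Suitable area")
  adf <- adf[adf$time > 0, , drop = FALSE]  # log axis: drop the present
  base <- ggplot2::ggplot(dd, ggplot2::aes(x = time, y = value))
  for (i in seq_along(traj$bootstrap)) {
    b <- traj$bootstrap[[i]]
    base <- base + ggplot2::geom_step(
      data = data.frame(time = b$steps$time, value = b$steps$ne,
                        panel = "Ne"),
      alpha = 0.2, colour = "grey60")
  }
  base +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::geom_line(data = tdf) +
    ggplot2::geom_point(data = adf) +
    ggplot2::geom_line(data = adf, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~panel, ncol = 1L, scales = "free_y") +
    ggplot2::labs(x = "years before present", y = NULL,
                  title = traj$species)
}

#' Combined report of a pipeline run
#'
#' @param result A [run_demo()] result.
#' @return List with `panels` (per-species ggplots), `group_curves`
#'   (normalized group-mean Ne data frame), `association` tables and `pgls`
#'   coefficient tables.
#' @export
report_demo <- function(result) {
  stopifnot(inherits(result, "pipeline_result"))
  kept <- names(result$area_series)
  panels <- lapply(kept, function(sp)
    plot_species_panel(result$trajectories[[sp]], result$area_series[[sp]],
                       result$temperature))
  names(panels) <- kept
  grouping <- result$comparative$table$status[
    match(names(result$trajectories), result$comparative$table$species)]
  grouping[is.na(grouping)] <- "all"
  curves <- normalize_and_average(result$trajectories, grouping)
  pgls_tabs <- lapply(result$pgls, function(f)
    if (is.null(f)) NULL else f$coefficients)
  list(panels = panels, group_curves = curves,
       association = list(area = result$association_area,
                          temperature = result$association_temperature),
       pgls = pgls_tabs)
}
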