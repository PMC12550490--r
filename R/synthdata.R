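## Synthetic-data generators: every input the pipeline consumes, with known
## ground truth, so downstream stages are testable without external data.

#' Define a piecewise-constant demographic scenario
#'
#' @param epochs Data frame with columns `start_gen` (epoch start times in
#'   generations, strictly increasing from 0) and `ne` (diploid effective
#'   population size during the epoch, > 0). The last epoch extends to
#'   infinity.
#' @param mutation_rate Per-site per-generation mutation rate, in \[0, 1).
#' @param recombination_rate Per-site per-generation recombination rate,
#'   in \[0, 1) (0 gives a single non-recombining sequence).
#' @param sequence_length_bp Sequence length in bp.
#' @param seed Integer seed.
#' @return A `demography_scenario` object.
#' @examples
#' demography_scenario(data.frame(start_gen = 0, ne = 1e4), 1e-8, 1e-8, 1e6, 1)
#' @export
demography_scenario <- function(epochs, mutation_rate, recombination_rate,
                                sequence_length_bp, seed = 1L) {
  stopifnot(is.data.frame(epochs), all(c("start_gen", "ne") %in% names(epochs)),
            nrow(epochs) >= 1L)
  if (epochs$start_gen[1L] != 0) stop("first epoch must start at 0")
  if (is.unsorted(epochs$start_gen, strictly = TRUE))
    stop("epoch start times must be strictly increasing")
  if (any(epochs$ne <= 0)) stop("all Ne must be positive")
  if (mutation_rate < 0 || mutation_rate >= 1)
    stop("mutation_rate must be in [0, 1)")
  if (recombination_rate < 0 || recombination_rate >= 1)
    stop("recombination_rate must be in [0, 1)")
  stopifnot(sequence_length_bp >= 1)
  structure(list(epochs = epochs, mutation_rate = mutation_rate,
                 recombination_rate = recombination_rate,
                 sequence_length_bp = as.numeric(sequence_length_bp),
                 seed = as.integer(seed)),
            class = "demography_scenario")
}

## Ne(tau) at time tau (generations ago) for a piecewise scenario
ne_at <- function(epochs, tau) {
  idx <- findInterval(tau, epochs$start_gen)
  epochs$ne[pmax(idx, 1L)]
}

## Draw the stationary pairwise TMRCA (generations) under piecewise Ne by
## inverting the cumulative coalescent hazard H(tau) = int 1/(2 Ne).
draw_tmrca_stationary <- function(epochs) {
  e <- rexp(1)
  lo <- c(epochs$start_gen, Inf)
  acc <- 0
  for (i in seq_len(nrow(epochs))) {
    rate <- 1 / (2 * epochs$ne[i])
    width <- lo[i + 1L] - lo[i]
    seg <- rate * width
    if (acc + seg >= e || i == nrow(epochs)) {
      return(lo[i] + (e - acc) / rate)
    }
    acc <- acc + seg
  }
}

## Race a single floating lineage upward from time `from`, with `k` partner
## lineages up to `cap` and piecewise rates k/(2 Ne); returns coalescence time
## or Inf if it survives past `cap`.
race_coalesce <- function(epochs, from, cap, k) {
  bounds <- c(epochs$start_gen, Inf)
  i <- findInterval(from, epochs$start_gen)
  cur <- from
  repeat {
    rate <- k / (2 * epochs$ne[i])
    hi <- min(bounds[i + 1L], cap)
    cand <- cur + rexp(1, rate)
    if (cand <= hi) return(cand)
    if (hi >= cap) return(Inf)
    cur <- hi
    i <- i + 1L
  }
}

## One SMC'/SMC transition: resample the TMRCA after a recombination event.
resample_tmrca <- function(epochs, tmrca, variant = c("smc_prime", "smc")) {
  variant <- match.arg(variant)
  u <- runif(1, 0, tmrca)
  if (variant == "smc_prime") {
    v <- race_coalesce(epochs, u, tmrca, k = 2L)
    if (is.finite(v)) {
      # two equally likely partners: rejoining its own stub keeps the TMRCA
      if (runif(1) < 0.5) return(tmrca) else return(v)
    }
  }
  # above the old TMRCA (or plain SMC from u): single ancestral partner
  from <- if (variant == "smc_prime") tmrca else u
  race_coalesce(epochs, from, Inf, k = 1L)
}

#' Simulate a binned heterozygosity track under the sequential coalescent
#'
#' Simulates the hidden pairwise TMRCA along a diploid sequence as a
#' piecewise-constant process: segment lengths are exponential with per-bp
#' rate `2 * r * TMRCA` (recombination anywhere on the two branches), and at
#' each recombination the TMRCA is resampled with the SMC' kernel (the
#' floating lineage may re-coalesce with its own stub, leaving the TMRCA
#' unchanged) or, optionally, the plain SMC kernel. Heterozygous sites are
#' then placed as a Poisson process at per-site rate `2 * mu * TMRCA`.
#'
#' @param scenario A [demography_scenario()].
#' @param bin_size_bp Bin width for the observation track (default 100).
#' @param variant `"smc_prime"` (default) or `"smc"` transition kernel.
#' @param scaffold Name of the single simulated scaffold.
#' @return A list with `track` (a [het_bin_track()]), `segments` (data frame
#'   `start`, `end`, `tmrca_gen`: the true hidden TMRCA series), `het_pos`
#'   (1-based heterozygous positions) and `scenario`.
#' @examples
#' sc <- demography_scenario(data.frame(start_gen = 0, ne = 5000),
#'                           1e-8, 1e-8, 2e5, seed = 7)
#' sim <- simulate_het_track(sc)
#' table(sim$track$bins[[1]])
#' @export
simulate_het_track <- function(scenario, bin_size_bp = 100L,
                               variant = c("smc_prime", "smc"),
                               scaffold = "scaffold_1") {
  stopifnot(inherits(scenario, "demography_scenario"))
  variant <- match.arg(variant)
  L <- scenario$sequence_length_bp
  if (L < bin_size_bp) stop("sequence shorter than one bin")
  set.seed(scenario$seed)
  ep <- scenario$epochs
  r <- scenario$recombination_rate
  mu <- scenario$mutation_rate

  starts <- numeric(0); ends <- numeric(0); tvals <- numeric(0)
  pos <- 0
  tm <- draw_tmrca_stationary(ep)
  while (pos < L) {
    len <- if (r > 0) rexp(1, rate = 2 * r * tm) else Inf
    end <- min(pos + len, L)
    starts <- c(starts, pos + 1); ends <- c(ends, end); tvals <- c(tvals, tm)
    pos <- end
    if (pos < L) tm <- resample_tmrca(ep, tm, variant)
  }
  segs <- data.frame(start = floor(starts), end = floor(ends),
                     tmrca_gen = tvals)
  # collapse zero-length bp segments created by sub-bp recombination distances
  segs <- segs[segs$end >= segs$start, , drop = FALSE]

  het_pos <- integer(0)
  n_mut <- rpois(nrow(segs), 2 * mu * segs$tmrca_gen *
                   (segs$end - segs$start + 1))
  for (i in which(n_mut > 0)) {
    het_pos <- c(het_pos,
                 unique(floor(runif(n_mut[i], segs$start[i], segs$end[i] + 1))))
  }
  het_pos <- sort(unique(pmin(het_pos, L)))

  n_bins <- ceiling(L / bin_size_bp)
  states <- integer(n_bins)  # 0 = HOM
  if (length(het_pos))
    states[unique((het_pos - 1L) %/% bin_size_bp) + 1L] <- 1L
  track <- het_bin_track(setNames(list(states), scaffold),
                         bin_size_bp = bin_size_bp,
                         genome_size_bp = L)
  list(track = track, segments = segs, het_pos = het_pos, scenario = scenario)
}

#' True TMRCA per bin from a simulated segment series
#'
#' Evaluates the hidden TMRCA series at bin midpoints, for parameter-recovery
#' oracles against the discretized HMM states.
#'
#' @param sim Result of [simulate_het_track()].
#' @return Numeric vector, generations, one value per bin.
#' @export
true_tmrca_per_bin <- function(sim) {
  bs <- sim$track$bin_size_bp
  n_bins <- length(sim$track$bins[[1L]])
  mids <- (seq_len(n_bins) - 0.5) * bs
  idx <- findInterval(mids, sim$segments$start)
  sim$segments$tmrca_gen[pmax(idx, 1L)]
}

# ---------------------------------------------------------------------------
# Niche-model world: climate rasters + occurrences with known suitability

#' Define a synthetic niche scenario
#'
#' Climate layers are smooth planar gradients plus noise; the true suitability
#' is a logistic transform of a linear predictor in the (standardized) layers,
#' with optional quadratic and pairwise-product terms; occurrences are sampled
#' with probability proportional to suitability. Per-period additive climate
#' shifts move the true suitable area in a known direction.
#'
#' @param grid_shape `c(rows, cols)`.
#' @param cell_size_km Cell edge length in km (planar grid).
#' @param coef List with elements `intercept` (scalar), `linear` (named by
#'   layer), optional `quadratic` (named by layer) and `product` (named
#'   `"layerA:layerB"`).
#' @param n_occurrences Number of occurrence records to draw.
#' @param n_layers Number of climate layers (>= 2).
#' @param per_period_shift Named list: period -> additive offset per layer
#'   (recycled), applied to the raw layers. Periods default to the five
#'   analysis periods (present, EarlyHolocene, LGM, LIG, MIS19).
#' @param seed Integer seed.
#' @param allow_few Allow `n_occurrences < 15` (mirrors the minimum-occurrence
#'   exclusion rule; default FALSE).
#' @return A `niche_scenario` object.
#' @export
niche_scenario <- function(grid_shape = c(60L, 60L), cell_size_km = 4.5,
                           coef = list(intercept = -4,
                                       linear = c(clim1 = 4, clim2 = -2)),
                           n_occurrences = 200L, n_layers = 4L,
                           per_period_shift = NULL, seed = 1L,
                           allow_few = FALSE) {
  stopifnot(length(grid_shape) == 2L, all(grid_shape >= 4L),
            cell_size_km > 0, n_layers >= 2L)
  if (n_occurrences < 15L && !allow_few)
    stop("fewer than 15 occurrences requires allow_few = TRUE ",
         "(species below this count are excluded from niche modelling)")
  if (is.null(per_period_shift)) {
    per_period_shift <- list(present = 0, EarlyHolocene = -0.3, LGM = -1.5,
                             LIG = 0.5, MIS19 = -0.5)
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 cell_size_km = cell_size_km, coef = coef,
                 n_occurrences = as.integer(n_occurrences),
                 n_layers = as.integer(n_layers),
                 per_period_shift = per_period_shift,
                 seed = as.integer(seed)),
            class = "niche_scenario")
}

## linear predictor of the true niche on (standardized) layer values
niche_linear_predictor <- function(coef, layer_values) {
  eta <- rep(if (is.null(coef$intercept)) 0 else coef$intercept,
             nrow(layer_values))
  for (nm in names(coef$linear))
    eta <- eta + coef$linear[[nm]] * layer_values[, nm]
  for (nm in names(coef$quadratic))
    eta <- eta + coef$quadratic[[nm]] * layer_values[, nm]^2
  for (nm in names(coef$product)) {
    ab <- strsplit(nm, ":", fixed = TRUE)[[1]]
    eta <- eta + coef$product[[nm]] * layer_values[, ab[1]] * layer_values[, ab[2]]
  }
  eta
}

#' Simulate per-period climate rasters and an occurrence set
#'
#' @param scenario A [niche_scenario()].
#' @param species Species label written into the occurrence table.
#' @return List with `stacks` (named list of [raster_stack()] per period),
#'   `occurrences` (data frame `species`, `lon`, `lat` in planar km),
#'   `true_suitability` (named list of matrices), `true_area_km2` (named
#'   vector, cells with true suitability >= 0.36 times cell area) and
#'   `scenario`.
#' @export
simulate_rasters_and_occurrences <- function(scenario, species = "sp1") {
  stopifnot(inherits(scenario, "niche_scenario"))
  set.seed(scenario$seed)
  nr <- scenario$grid_shape[1L]; nc <- scenario$grid_shape[2L]
  cs <- scenario$cell_size_km
  xy <- expand.grid(col = seq_len(nc), row = seq_len(nr))
  # cell centres in the raster convention (matrix row 1 = northern-most)
  x <- (xy$col - 0.5) * cs; y <- (nr - xy$row + 0.5) * cs
  xs <- (x - mean(x)) / sd(x); ys <- (y - mean(y)) / sd(y)

  layer_names <- paste0("clim", seq_len(scenario$n_layers))
  base <- sapply(seq_len(scenario$n_layers), function(l) {
    a <- rnorm(1); b <- rnorm(1); ph <- runif(1, 0, 2 * pi)
    a * xs + b * ys + 0.6 * sin(2 * pi * (xs + ys) / 4 + ph) +
      rnorm(nr * nc, sd = 0.15)
  })
  colnames(base) <- layer_names

  periods <- names(scenario$per_period_shift)
  stacks <- list(); suits <- list(); areas <- numeric(0)
  for (p in periods) {
    shift <- rep(scenario$per_period_shift[[p]],
                 length.out = scenario$n_layers)
    vals <- sweep(base, 2L, shift, `+`)
    std <- scale(vals, center = colMeans(base), scale = apply(base, 2, sd))
    eta <- niche_linear_predictor(scenario$coef, std)
    suit <- plogis(eta)
    layers <- lapply(seq_len(ncol(vals)), function(j)
      matrix(vals[, j], nrow = nr, ncol = nc, byrow = TRUE))
    names(layers) <- layer_names
    stacks[[p]] <- raster_stack(layers, cell_size = cs, crs = "planar_km",
                                period = p)
    suits[[p]] <- matrix(suit, nrow = nr, ncol = nc, byrow = TRUE)
    areas[p] <- sum(suit >= 0.36) * cs^2
  }

  suit_now <- as.vector(t(suits[["present"]]))
  cells <- sample.int(nr * nc, scenario$n_occurrences, replace = TRUE,
                      prob = suit_now)
  occ <- data.frame(species = species,
                    lon = x[cells] + runif(length(cells), -cs / 2, cs / 2),
                    lat = y[cells] + runif(length(cells), -cs / 2, cs / 2))
  list(stacks = stacks, occurrences = occ, true_suitability = suits,
       true_area_km2 = areas, scenario = scenario)
}

# ---------------------------------------------------------------------------
# Comparative world: tree + Brownian traits + status labels

#' Define a synthetic comparative scenario
#'
#' @param n_species Number of tips (>= 3).
#' @param tree_depth Root-to-tip depth of the (ultrametric, pure-birth) tree.
#' @param brownian_sigma2 Brownian rate for the continuous traits.
#' @param status_effect Named numeric: additive shift of each trait for
#'   "At risk" species (e.g. `c(H = -0.5)`); default all zero.
#' @param status_rule `"liability"` (threshold a Brownian liability at its
#'   median: phylogenetically clustered labels) or `"random"`.
#' @param seed Integer seed.
#' @export
comparative_scenario <- function(n_species = 16L, tree_depth = 1,
                                 brownian_sigma2 = 1, status_effect = NULL,
                                 status_rule = c("liability", "random"),
                                 seed = 1L) {
  stopifnot(n_species >= 3L, tree_depth > 0, brownian_sigma2 >= 0)
  structure(list(n_species = as.integer(n_species), tree_depth = tree_depth,
                 brownian_sigma2 = brownian_sigma2,
                 status_effect = status_effect,
                 status_rule = match.arg(status_rule),
                 seed = as.integer(seed)),
            class = "comparative_scenario")
}

## one Brownian draw on tree covariance C (root value 0)
rbrownian <- function(C, sigma2) {
  if (sigma2 == 0) return(rep(0, nrow(C)))
  ch <- chol(sigma2 * C + diag(1e-12, nrow(C)))
  as.vector(t(ch) %*% rnorm(nrow(C)))
}

#' Simulate an ultrametric tree with Brownian traits and status labels
#'
#' Traits (`H`, `mean_Ne`, `current_area_km2`, `mean_past_area_km2`) evolve by
#' Brownian motion on a pure-birth ultrametric tree; "At risk" labels are
#' drawn either from a thresholded Brownian liability or at random, and an
#' optional fixed status effect shifts named traits.
#'
#' @param scenario A [comparative_scenario()].
#' @return List with `tree` (an [ape::phylo] object), `table` (data frame of
#'   per-species traits and labels) and `scenario`.
#' @export
simulate_comparative <- function(scenario) {
  stopifnot(inherits(scenario, "comparative_scenario"))
  set.seed(scenario$seed)
  tr <- ape::rphylo(scenario$n_species, birth = 1, death = 0)
  tr$edge.length <- tr$edge.length *
    (scenario$tree_depth / max(ape::node.depth.edgelength(tr)))
  tr$tip.label <- sprintf("sp%02d", seq_len(scenario$n_species))
  C <- ape::vcv.phylo(tr)

  status <- switch(scenario$status_rule,
    liability = {
      liab <- rbrownian(C, 1)
      ifelse(liab > stats::median(liab), "At risk", "Not at risk")
    },
    random = sample(c("At risk", "Not at risk"), scenario$n_species,
                    replace = TRUE))
  tab <- data.frame(
    species = tr$tip.label,
    H = rbrownian(C, scenario$brownian_sigma2),
    mean_Ne = rbrownian(C, scenario$brownian_sigma2),
    current_area_km2 = rbrownian(C, scenario$brownian_sigma2),
    mean_past_area_km2 = rbrownian(C, scenario$brownian_sigma2),
    status = status,
    habitat = sample(c("aquatic", "terrestrial"), scenario$n_species,
                     replace = TRUE),
    climate = sample(c("tropical", "temperate"), scenario$n_species,
                     replace = TRUE))
  for (nm in names(scenario$status_effect)) {
    tab[[nm]] <- tab[[nm]] +
      scenario$status_effect[[nm]] * (tab$status == "At risk")
  }
  list(tree = tr, table = tab, scenario = scenario)
}

# ---------------------------------------------------------------------------
# Chromosome micro-dissection read positions

#' Simulate mapped read positions for micro-dissected chromosomes
#'
#' Each chromosome sample places mapped positions on scaffolds with
#' probability proportional to scaffold length, except that its true scaffold
#' (from `enrichment_map`) is up-weighted by `enrichment_factor`. With
#' `background = 0` all positions fall on the true scaffold.
#'
#' @param scaffold_lengths Named numeric vector of scaffold lengths (bp).
#' @param enrichment_map Named character: chromosome -> true scaffold.
#' @param enrichment_factor Multiplicative weight on the true scaffold
#'   (1 = no enrichment).
#' @param n_positions Mapped positions per chromosome sample.
#' @param background Fraction in \[0, 1\] of weight spread over non-target
#'   scaffolds, as a convenience override; `NULL` (default) uses the
#'   length-proportional model described above.
#' @param seed Integer seed.
#' @return Data frame `chromosome`, `scaffold`, `position`, `reads`.
#' @export
simulate_chromosome_reads <- function(scaffold_lengths, enrichment_map,
                                      enrichment_factor = 10,
                                      n_positions = 500L, background = NULL,
                                      seed = 1L) {
  stopifnot(length(scaffold_lengths) >= 1L, !is.null(names(scaffold_lengths)),
            all(enrichment_map %in% names(scaffold_lengths)))
  set.seed(seed)
  out <- list()
  for (chrom in names(enrichment_map)) {
    target <- enrichment_map[[chrom]]
    w <- scaffold_lengths
    w[target] <- w[target] * enrichment_factor
    if (!is.null(background)) {
      w[] <- background * scaffold_lengths / sum(scaffold_lengths)
      w[target] <- w[target] + (1 - background)
    }
    scaf <- sample(names(w), n_positions, replace = TRUE, prob = w)
    pos <- floor(runif(n_positions, 1, scaffold_lengths[scaf] + 1))
    out[[chrom]] <- data.frame(chromosome = chrom, scaffold = scaf,
                               position = pos,
                               reads = 1L + rpois(n_positions, 2))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Synthetic global mean-surface-temperature series
#'
#' A toy reconstruction of global mean surface temperature over the last
#' 10 Myr: a slow cooling trend plus glacial cycles, evaluated at the ages
#' (years before present) requested. Used to drive temperature trend coding
#' in demonstrations; real analyses should supply a published reconstruction
#' as a CSV (`age_years`, `temp_c`).
#'
#' @param ages_years Ages (years BP) at which to evaluate.
#' @return Data frame `age_years`, `temp_c`.
#' @export
synthetic_temperature_series <- function(ages_years =
                                           10^seq(4, 7, length.out = 200)) {
  t_myr <- ages_years / 1e6
  temp_c <- 14 + 0.45 * t_myr +                              # warmer deep past
    1.5 * cos(2 * pi * ages_years / 1e5) * exp(-t_myr / 3)   # ~100 kyr cycles
  data.frame(age_years = ages_years, temp_c = temp_c)
}
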