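## Occurrence preprocessing, raster PCA, Maxent-style niche model fitting,
## selection, paleo-projection and the spatial-autocorrelation check.

## pairwise distances in km between (lon, lat) rows, honouring the CRS
pair_dist_km <- function(pts, crs = "lonlat") {
  if (crs == "lonlat") {
    geosphere::distm(as.matrix(pts[, c("lon", "lat")]),
                     fun = geosphere::distHaversine) / 1000
  } else {
    as.matrix(dist(pts[, c("lon", "lat")]))
  }
}

## exact maximum independent set by branch and bound on the conflict graph
## (adjacency list `nbr`), used on small connected components
mis_exact <- function(nbr, verts) {
  if (!length(verts)) return(integer(0))
  deg <- vapply(verts, function(v) length(intersect(nbr[[v]], verts)),
                integer(1))
  if (all(deg == 0)) return(verts)
  v <- verts[which.max(deg)]
  # branch 1: keep v, drop its neighbours; branch 2: drop v
  with_v <- c(v, mis_exact(nbr, setdiff(verts, c(v, nbr[[v]]))))
  without_v <- mis_exact(nbr, setdiff(verts, v))
  if (length(with_v) >= length(without_v)) with_v else without_v
}

#' Spatially thin an occurrence set
#'
#' Removes records until no retained pair is closer than `min_distance_km`,
#' keeping as many records as possible: this is a maximum-independent-set
#' problem on the graph of too-close pairs. Connected conflict components
#' with up to `exact_limit` records are solved exactly by branch and bound;
#' larger components fall back to `n_tries` randomized greedy passes
#' (iteratively deleting the record with most close neighbours, random
#' tie-breaks) keeping the best pass. Deterministic given `seed`.
#'
#' @param occ Data frame with `lon`, `lat` (degrees for `crs = "lonlat"`,
#'   km for `"planar_km"`).
#' @param min_distance_km Minimum allowed pairwise distance (default 4.5 km).
#' @param seed Integer seed.
#' @param crs Coordinate system of the coordinates.
#' @param n_tries Randomized repeats for large components (default 25).
#' @param exact_limit Largest component size solved exactly (default 20).
#' @return The thinned subset of `occ` (row order preserved).
#' @export
thin_occurrences <- function(occ, min_distance_km = 4.5, seed = 1L,
                             crs = c("lonlat", "planar_km"), n_tries = 25L,
                             exact_limit = 20L) {
  crs <- match.arg(crs)
  if (!nrow(occ)) stop("empty occurrence set")
  if (nrow(occ) == 1L) return(occ)
  d <- pair_dist_km(occ, crs)
  close <- d < min_distance_km
  diag(close) <- FALSE
  n <- nrow(occ)
  nbr <- lapply(seq_len(n), function(i) which(close[i, ]))
  # connected components of the conflict graph
  comp <- integer(n); cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i]) next
    cid <- cid + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (comp[v]) next
      comp[v] <- cid
      queue <- c(queue, nbr[[v]][comp[nbr[[v]]] == 0L])
    }
  }
  set.seed(seed)
  keep <- logical(n)
  for (cc in seq_len(cid)) {
    verts <- which(comp == cc)
    if (length(verts) == 1L) { keep[verts] <- TRUE; next }
    if (length(verts) <= exact_limit) {
      keep[mis_exact(nbr, verts)] <- TRUE
      next
    }
    best <- integer(0)
    for (try in seq_len(n_tries)) {
      alive <- verts
      deg <- vapply(alive, function(v) sum(close[v, alive]), integer(1))
      while (any(deg > 0)) {
        cand <- which(deg == max(deg))
        pick <- if (length(cand) > 1L) sample(cand, 1L) else cand
        v <- alive[pick]
        alive <- alive[-pick]
        deg <- vapply(alive, function(u) sum(close[u, alive]), integer(1))
      }
      if (length(alive) > length(best)) best <- alive
    }
    keep[best] <- TRUE
  }
  occ[keep, , drop = FALSE]
}

#' Principal component analysis of raster layers
#'
#' PCA on the standardized cell values across layers (constant layers are
#' dropped with a warning); retains the first components that cumulatively
#' explain more than `var_target` of the variance, capped at `max_comp`
#' (default 6).
#'
#' @param stack A [raster_stack()] of climate layers.
#' @param var_target Cumulative explained-variance target (default 0.9).
#' @param max_comp Cap on retained components (default 6).
#' @return List with `transform` (a `raster_pca_transform`: loadings,
#'   centers, scales, explained-variance fractions, `n_components`) and
#'   `scores` (a [raster_stack()] of retained PC-score layers).
#' @export
raster_pca <- function(stack, var_target = 0.9, max_comp = 6L) {
  vals <- cell_values(stack)
  if (ncol(vals) < 2L) stop("need at least two layers")
  ok_cells <- complete.cases(vals)
  if (sum(ok_cells) < 2L) stop("need at least two non-missing cells")
  sds <- apply(vals[ok_cells, , drop = FALSE], 2L, sd)
  if (any(sds == 0)) {
    warning("dropping constant layer(s): ",
            paste(colnames(vals)[sds == 0], collapse = ", "))
    vals <- vals[, sds > 0, drop = FALSE]
  }
  pc <- prcomp(vals[ok_cells, , drop = FALSE], center = TRUE, scale. = TRUE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  n_comp <- which(cumsum(expl) > var_target)[1L]
  if (is.na(n_comp)) n_comp <- length(expl)
  n_comp <- min(n_comp, max_comp, length(expl))
  transform <- structure(list(loadings = pc$rotation[, seq_len(n_comp),
                                                     drop = FALSE],
                              center = pc$center, scale = pc$scale,
                              explained = expl, n_components = n_comp),
                         class = "raster_pca_transform")
  list(transform = transform, scores = apply_pca(transform, stack))
}

#' Apply fitted PCA loadings to a (possibly different-period) raster stack
#'
#' @param transform A `raster_pca_transform` from [raster_pca()].
#' @param stack A [raster_stack()] holding at least the layers the transform
#'   was fitted on.
#' @return A [raster_stack()] of PC-score layers.
#' @export
apply_pca <- function(transform, stack) {
  need <- rownames(transform$loadings)
  missing_layers <- setdiff(need, names(stack$layers))
  if (length(missing_layers))
    stop("stack lacks layer(s) required by the PCA: ",
         paste(missing_layers, collapse = ", "))
  vals <- cell_values(stack)[, need, drop = FALSE]
  std <- scale(vals, center = transform$center[need],
               scale = transform$scale[need])
  sc <- std %*% transform$loadings
  layers <- lapply(seq_len(ncol(sc)), function(j)
    matrix(sc[, j], nrow = stack$nrow, ncol = stack$ncol, byrow = TRUE))
  names(layers) <- colnames(sc)
  raster_stack(layers, cell_size = stack$cell_size, xll = stack$xll,
               yll = stack$yll, crs = stack$crs, period = stack$period)
}

## Maxent feature expansion: linear (L), quadratic (Q), pairwise product (P)
## terms of the PC scores.
maxent_features <- function(x, classes) {
  stopifnot(grepl("^[LQP]+$", classes))
  out <- list()
  nms <- colnames(x)
  if (grepl("L", classes)) out <- c(out, setNames(lapply(seq_len(ncol(x)),
    function(j) x[, j]), nms))
  if (grepl("Q", classes)) out <- c(out, setNames(lapply(seq_len(ncol(x)),
    function(j) x[, j]^2), paste0(nms, "^2")))
  if (grepl("P", classes) && ncol(x) >= 2L) {
    for (i in seq_len(ncol(x) - 1L)) for (j in (i + 1L):ncol(x))
      out[[paste0(nms[i], ":", nms[j])]] <- x[, i] * x[, j]
  }
  do.call(cbind, out)
}

#' Fit a Maxent-style presence-background niche model
#'
#' The Gibbs/maximum-entropy suitability model in its penalized-logistic
#' form: an L1-penalized binomial regression of presence cells against
#' background cells on the requested feature expansion (linear, quadratic
#' and/or pairwise-product terms of the PC scores), solved with glmnet at a
#' fixed penalty `lambda = multiplier * sqrt(log(p) / n)` (p features, n
#' observations). Features are standardized internally; the background is
#' drawn uniformly from non-missing cells (without replacement when
#' possible).
#'
#' @param occ Occurrence data frame (`lon`, `lat` in the stack's units).
#' @param pc_stack PC-score [raster_stack()] from [raster_pca()].
#' @param features Feature classes, a string over \{L, Q, P\} (e.g. `"LQ"`).
#' @param multiplier Regularization multiplier (the study grid uses 1, 2, 5).
#' @param n_background Number of background cells (default 10000, capped at
#'   the number of non-missing cells).
#' @param seed Integer seed for the background draw.
#' @param min_occurrences Minimum occurrences required (default 15; species
#'   below this are excluded from niche modelling).
#' @return A `maxent_model`: coefficients, feature metadata, `entropy` of the
#'   fitted raw distribution over the background, and a `flagged` indicator
#'   for non-converged/separated fits.
#' @export
fit_maxent <- function(occ, pc_stack, features = "LQP", multiplier = 1,
                       n_background = 10000L, seed = 1L,
                       min_occurrences = 15L) {
  if (nrow(occ) < min_occurrences)
    stop("need at least ", min_occurrences, " occurrences (got ", nrow(occ),
         "); species with fewer are excluded")
  vals <- cell_values(pc_stack)
  ok <- which(complete.cases(vals))
  set.seed(seed)
  bg_cells <- if (length(ok) > n_background)
    sample(ok, n_background) else ok
  pres_cells <- cell_index(pc_stack, occ$lon, occ$lat)
  if (anyNA(pres_cells)) stop("occurrences outside the raster extent")

  xraw <- rbind(vals[pres_cells, , drop = FALSE],
                vals[bg_cells, , drop = FALSE])
  feat <- maxent_features(xraw, features)
  ctr <- colMeans(feat); scl <- apply(feat, 2L, sd)
  scl[scl == 0] <- 1
  fx <- scale(feat, ctr, scl)
  y <- rep(c(1L, 0L), c(nrow(occ), length(bg_cells)))
  lam <- multiplier * sqrt(log(ncol(fx)) / length(y))
  fit <- glmnet::glmnet(fx, y, family = "binomial",
                        lambda = lam * c(8, 4, 2, 1), standardize = FALSE,
                        thresh = 1e-10)
  beta <- as.numeric(coef(fit, s = lam))
  names(beta) <- c("(Intercept)", colnames(fx))
  flagged <- !all(is.finite(beta)) || any(abs(beta[-1L]) > 50)
  model <- structure(list(coef = beta, features = features,
                          multiplier = multiplier, lambda = lam,
                          center = ctr, scale = scl,
                          n_presence = nrow(occ),
                          n_background = length(bg_cells),
                          flagged = flagged, entropy = NA_real_,
                          log_z = NA_real_),
                     class = "maxent_model")
  # normalizer and entropy of the raw distribution over the training
  # background, used by the cloglog/logistic output transforms
  eta_bg <- maxent_eta(model, vals[bg_cells, , drop = FALSE])
  mx <- max(eta_bg)
  model$log_z <- mx + log(sum(exp(eta_bg - mx)))
  raw <- exp(eta_bg - model$log_z)
  model$entropy <- -sum(ifelse(raw > 0, raw * log(raw), 0))
  model
}

## linear predictor on raw PC-score rows
maxent_eta <- function(model, pc_rows) {
  feat <- maxent_features(pc_rows, model$features)
  fx <- scale(feat, model$center[colnames(feat)],
              model$scale[colnames(feat)])
  drop(model$coef[1L] + fx %*% model$coef[colnames(feat)])
}

#' Predict suitability from a Maxent-style model
#'
#' `"cloglog"` (default) and `"logistic"` outputs are in \[0, 1\]; `"raw"`
#' is the probability distribution over the non-missing cells of `stack`
#' (sums to 1).
#'
#' @param object A `maxent_model`.
#' @param stack A PC-score [raster_stack()] (same layers the model was fit
#'   on).
#' @param type Output transform.
#' @param ... Unused.
#' @return Numeric vector of predictions, one per cell (NA for missing
#'   cells), in [cell_coords()] order.
#' @export
predict.maxent_model <- function(object, stack, type = c("cloglog",
                                                         "logistic", "raw"),
                                 ...) {
  type <- match.arg(type)
  vals <- cell_values(stack)
  ok <- complete.cases(vals)
  eta <- rep(NA_real_, nrow(vals))
  eta[ok] <- maxent_eta(object, vals[ok, , drop = FALSE])
  if (type == "raw") {
    # density over the non-missing cells of this grid (sums to 1)
    w <- exp(eta - max(eta, na.rm = TRUE))
    return(w / sum(w, na.rm = TRUE))
  }
  # density relative to the training background, scaled by its entropy
  dens <- exp(object$entropy + eta - object$log_z)
  if (type == "cloglog") 1 - exp(-dens) else dens / (1 + dens)
}

#' ROC AUC by the rank (Mann-Whitney) statistic
#'
#' Probability that a presence score exceeds a background score, ties counted
#' half.
#'
#' @param pos Scores at presences.
#' @param neg Scores at background points.
#' @return AUC in \[0, 1\].
#' @export
rank_auc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Evaluate a candidate-model grid and select the best niche model
#'
#' For every feature-class/multiplier combination: random k-fold
#' cross-validation of the presences (the model is refit on k-1 folds and
#' test presences are scored against the background; AUC by rank statistic),
#' and AICc of the full-data fit with K = number of non-zero coefficients
#' and likelihood the product of normalized raw suitabilities at the
#' presences. The selected model has the lowest AICc among those with mean
#' test AUC above `auc_min`; ties prefer fewer non-zero coefficients, then a
#' lower multiplier. With no qualifying model the selection is the explicit
#' "no valid model" result (`selected = NULL`), mirroring species exclusion.
#'
#' @param occ Occurrences (data frame `lon`, `lat`).
#' @param pc_stack PC-score [raster_stack()].
#' @param feature_grid Character vector of feature-class strings (default
#'   the 7 non-empty subsets of \{L, Q, P\}).
#' @param multipliers Regularization multipliers (default `c(1, 2, 5)`).
#' @param k Folds (default 4).
#' @param n_background,seed Passed to [fit_maxent()].
#' @param auc_min AUC gate (default 0.7).
#' @return List with `evaluation` (one row per candidate: features,
#'   multiplier, mean/per-fold AUC, AICc, non-zero count, selected flag) and
#'   `selected` (`maxent_model` or NULL).
#' @export
evaluate_and_select <- function(occ, pc_stack,
                                feature_grid = c("L", "Q", "P", "LQ", "LP",
                                                 "QP", "LQP"),
                                multipliers = c(1, 2, 5), k = 4L,
                                n_background = 10000L, seed = 1L,
                                auc_min = 0.7) {
  stopifnot(nrow(occ) >= k)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), nrow(occ)))
  grid <- expand.grid(features = feature_grid, multiplier = multipliers,
                      stringsAsFactors = FALSE)
  rows <- list(); models <- list()
  for (i in seq_len(nrow(grid))) {
    fc <- grid$features[i]; mult <- grid$multiplier[i]
    full <- tryCatch(fit_maxent(occ, pc_stack, fc, mult,
                                n_background = n_background, seed = seed),
                     error = function(e) NULL)
    if (is.null(full)) next
    aucs <- rep(NA_real_, k)
    for (f in seq_len(k)) {
      train <- occ[fold != f, , drop = FALSE]
      test <- occ[fold == f, , drop = FALSE]
      if (nrow(test) == 0L || nrow(train) < 2L) next
      mf <- tryCatch(fit_maxent(train, pc_stack, fc, mult,
                                n_background = n_background, seed = seed,
                                min_occurrences = 2L),
                     error = function(e) NULL)
      if (is.null(mf) || mf$flagged) next
      pred <- predict(mf, pc_stack, type = "raw")
      test_cells <- cell_index(pc_stack, test$lon, test$lat)
      bg <- pred[!is.na(pred)]
      aucs[f] <- rank_auc(pred[test_cells], bg)
    }
    raw <- predict(full, pc_stack, type = "raw")
    pres_cells <- cell_index(pc_stack, occ$lon, occ$lat)
    ll <- sum(log(pmax(raw[pres_cells], 1e-300)))
    kk <- sum(full$coef[-1L] != 0)
    n <- nrow(occ)
    aicc <- if (n - kk - 1 > 0)
      2 * kk - 2 * ll + 2 * kk * (kk + 1) / (n - kk - 1) else Inf
    models <- c(models, list(full))
    rows <- c(rows, list(data.frame(features = fc, multiplier = mult,
                                    mean_auc = mean(aucs, na.rm = TRUE),
                                    aicc = aicc, n_nonzero = kk,
                                    flagged = full$flagged)))
  }
  ev <- do.call(rbind, rows)
  ev$selected <- FALSE
  pass <- which(!ev$flagged & is.finite(ev$aicc) & ev$mean_auc > auc_min)
  selected <- NULL
  if (length(pass)) {
    best <- pass[order(ev$aicc[pass], ev$n_nonzero[pass],
                       ev$multiplier[pass])][1L]
    ev$selected[best] <- TRUE
    selected <- models[[best]]
  } else {
    message("no model passed the AUC gate: no valid niche model")
  }
  list(evaluation = ev, selected = selected)
}

#' Project a niche model across climate periods and compute suitable area
#'
#' Applies the present-day PCA loadings to each period stack, predicts
#' suitability, and sums the area of cells at or above the suitability
#' threshold (ice-masked cells excluded). The normalized series divides each
#' period's area by the maximum across periods.
#'
#' @param model A `maxent_model` (fit on present-day PC scores).
#' @param per_period_stacks Named list of climate [raster_stack()]s (raw
#'   layers; the PCA is applied here).
#' @param pca_transform The `raster_pca_transform` fitted on the present-day
#'   stack.
#' @param threshold Suitability threshold, inclusive (default 0.36, the
#'   medium-to-high probability rule 0.36-1.00).
#' @param ice_mask Optional named list: period -> logical matrix (TRUE =
#'   ice-covered, excluded).
#' @param type Suitability transform passed to the predictor.
#' @return An `area_series` data frame: `period`, `area_km2`, `normalized`,
#'   with the per-period suitability grids in `attr(, "suitability")`.
#' @export
project_and_area <- function(model, per_period_stacks, pca_transform,
                             threshold = 0.36, ice_mask = NULL,
                             type = "cloglog") {
  stopifnot(length(per_period_stacks) >= 1L)
  areas <- numeric(0); suits <- list()
  for (p in names(per_period_stacks)) {
    stack <- per_period_stacks[[p]]
    pcs <- apply_pca(pca_transform, stack)
    suit <- predict(model, pcs, type = type)
    if (!is.null(ice_mask[[p]]))
      suit[as.vector(t(ice_mask[[p]]))] <- NA
    areas[p] <- sum(cell_areas_km2(stack)[!is.na(suit) & suit >= threshold])
    suits[[p]] <- matrix(suit, stack$nrow, stack$ncol, byrow = TRUE)
  }
  out <- data.frame(period = names(areas), area_km2 = unname(areas),
                    normalized = unname(areas) / max(areas))
  attr(out, "suitability") <- suits
  class(out) <- c("area_series", class(out))
  out
}

#' Moran's I across distance bands
#'
#' Residual spatial autocorrelation check: Moran's I with binary
#' distance-band weights at `n_distance_bins` bands between 0 and
#' `max_distance_km`, with permutation p-values. Bands with fewer than two
#' point pairs are reported as missing.
#'
#' @param points Data frame with `lon`, `lat` and a `resid` column.
#' @param n_distance_bins Number of distance bands (default 21).
#' @param max_distance_km Largest band edge (default 10 km).
#' @param crs Coordinate system of `lon`/`lat`.
#' @param n_perm Permutations for the p-value (default 999).
#' @param seed Integer seed.
#' @return Data frame `dist_lo`, `dist_hi`, `moran_i`, `p_value`, `n_pairs`.
#' @export
morans_i <- function(points, n_distance_bins = 21L, max_distance_km = 10,
                     crs = c("lonlat", "planar_km"), n_perm = 999L,
                     seed = 1L) {
  crs <- match.arg(crs)
  stopifnot(nrow(points) >= 10L, "resid" %in% names(points))
  d <- pair_dist_km(points, crs)
  z <- points$resid - mean(points$resid)
  n <- length(z)
  brk <- seq(0, max_distance_km, length.out = n_distance_bins + 1L)
  set.seed(seed)
  perms <- replicate(n_perm, sample(z))
  out <- data.frame(dist_lo = brk[-length(brk)], dist_hi = brk[-1L],
                    moran_i = NA_real_, p_value = NA_real_, n_pairs = 0L)
  denom <- sum(z^2)
  for (b in seq_len(n_distance_bins)) {
    W <- d > brk[b] & d <= brk[b + 1L]
    diag(W) <- FALSE
    s0 <- sum(W)
    out$n_pairs[b] <- s0 / 2
    if (s0 < 4 || denom == 0) next  # fewer than 2 pairs: undefined
    iobs <- (n / s0) * sum(W * outer(z, z)) / denom
    inull <- apply(perms, 2L, function(zp)
      (n / s0) * sum(W * outer(zp, zp)) / sum(zp^2))
    out$moran_i[b] <- iobs
    out$p_value[b] <- (1 + sum(abs(inull) >= abs(iobs))) / (n_perm + 1)
  }
  out
}
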