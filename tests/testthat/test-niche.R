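make_world <- function(seed = 3, n_occ = 200) {
  ns <- niche_scenario(n_occurrences = n_occ, seed = seed)
  simulate_rasters_and_occurrences(ns)
}

test_that("thinning removes close pairs and keeps dispersed points", {
  two <- data.frame(lon = c(0, 0.005), lat = c(0, 0.005))  # ~0.8 km apart
  th <- thin_occurrences(two, 4.5, seed = 1, crs = "lonlat")
  expect_equal(nrow(th), 1L)
  far <- data.frame(lon = c(0, 1, 2), lat = c(0, 1, 2))  # > 100 km apart
  expect_equal(nrow(thin_occurrences(far, 4.5, seed = 1)), 3L)
  expect_error(thin_occurrences(far[0, ]), "empty")
})

test_that("thinned set size matches the brute-force optimum on small inputs", {
  set.seed(44)
  for (rep in 1:5) {
    pts <- data.frame(lon = runif(12, 0, 12), lat = runif(12, 0, 12))
    d <- as.matrix(dist(pts))
    th <- thin_occurrences(pts, 5, seed = rep, crs = "planar_km")
    expect_equal(nrow(th), brute_max_thinned(d, 5))
    dd <- d[rownames(th) |> as.integer(), rownames(th) |> as.integer()]
    expect_true(all(dd[upper.tri(dd)] >= 5))
  }
})

test_that("cropping expands the occurrence box by the buffer and clips", {
  m <- matrix(rnorm(40 * 40), 40, 40)
  st <- raster_stack(list(l1 = m), cell_size = 1, xll = -20, yll = -20,
                     crs = "lonlat")
  occ <- data.frame(lon = c(0, 5), lat = c(0, 5))
  cr <- crop_with_buffer(st, occ, buffer = 10)
  expect_equal(cr$xll, -10)
  expect_equal(cr$yll, -10)
  expect_equal(cr$ncol, 25)  # -10..15 clipped within -20..20
  expect_equal(cr$nrow, 25)
  bb <- crop_with_buffer(st, occ, buffer = 0)
  expect_equal(c(bb$nrow, bb$ncol), c(5, 5))
  full <- crop_with_buffer(st, data.frame(lon = c(-20, 19.9),
                                          lat = c(-20, 19.9)), 10)
  expect_equal(c(full$nrow, full$ncol), c(40, 40))
})

test_that("ASCII-grid I/O round-trips a layer with missing cells", {
  m <- matrix(rnorm(30), 5, 6)
  m[2, 3] <- NA
  st <- raster_stack(list(z = m), cell_size = 4.5, xll = 1, yll = 2)
  path <- tempfile(fileext = ".asc")
  write_ascii_grid(st, "z", path)
  back <- read_ascii_grid(path, "z")
  expect_equal(back$layers$z, m, tolerance = 1e-12)
  expect_equal(back$cell_size, 4.5)
  expect_equal(c(back$xll, back$yll), c(1, 2))
  file.remove(path)
})

test_that("PCA on duplicated layers concentrates variance in one component", {
  m <- matrix(rnorm(400), 20, 20)
  st <- raster_stack(list(a = m, b = 2 * m + 3), cell_size = 1)
  p <- raster_pca(st)
  expect_equal(p$transform$n_components, 1L)
  expect_equal(p$transform$explained[1], 1, tolerance = 1e-12)
})

test_that("explained variances match a direct eigendecomposition", {
  w <- make_world(5)
  p <- raster_pca(w$stacks$present, max_comp = 4)
  vals <- scale(cell_values(w$stacks$present))
  ev <- eigen(cov(vals), symmetric = TRUE)$values
  expect_equal(p$transform$explained, ev / sum(ev), tolerance = 1e-10)
  # inverse transform reconstructs standardized layers within retained rank
  if (p$transform$n_components == ncol(vals)) {
    rec <- cell_values(p$scores) %*% t(p$transform$loadings)
    expect_equal(rec, unclass(vals), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  cst <- raster_stack(list(a = matrix(1, 5, 5),
                           b = matrix(rnorm(25), 5, 5),
                           c = matrix(rnorm(25), 5, 5)), cell_size = 1)
  expect_warning(raster_pca(cst), "constant layer")
})

test_that("projection applied to the fitting stack reproduces the scores", {
  w <- make_world(7)
  p <- raster_pca(w$stacks$present)
  again <- apply_pca(p$transform, w$stacks$present)
  expect_equal(again$layers, p$scores$layers, tolerance = 1e-12)
  dropped <- w$stacks$present
  dropped$layers <- dropped$layers[-1]
  expect_error(apply_pca(p$transform, dropped), "lacks layer")
})

test_that("an extreme regularization multiplier shrinks the model flat", {
  w <- make_world(9)
  p <- raster_pca(w$stacks$present)
  m <- fit_maxent(w$occurrences, p$scores, "LQ", multiplier = 1e6,
                  n_background = 1000, seed = 1)
  expect_true(all(m$coef[-1] == 0))
  pred <- predict(m, p$scores, type = "cloglog")
  expect_lt(diff(range(pred)), 1e-12)
})

test_that("a presence gradient yields a positive linear coefficient", {
  grad <- matrix(rep(seq(-2, 2, length.out = 30), each = 30), 30, 30,
                 byrow = FALSE)
  st <- raster_stack(list(PC1 = grad, PC2 = matrix(rnorm(900, sd = .1),
                                                   30, 30)),
                     cell_size = 1)
  set.seed(2)
  occ <- data.frame(lon = runif(60, 25, 30), lat = runif(60, 0, 30))
  m <- fit_maxent(occ, st, "L", 1, n_background = 500, seed = 3)
  # columns further right carry larger PC1 values
  expect_gt(m$coef[["PC1"]], 0)
})

test_that("glmnet fit matches an independent penalized-logistic solver", {
  set.seed(6)
  grad <- matrix(rnorm(900), 30, 30)
  st <- raster_stack(list(PC1 = grad,
                          PC2 = matrix(rnorm(900), 30, 30)), cell_size = 1)
  cells <- order(-as.vector(t(grad)))[1:40]
  cc <- cell_coords(st)
  occ <- cc[cells[1:20], ]; names(occ) <- c("lon", "lat")
  m <- fit_maxent(occ, st, "L", multiplier = 0.5, n_background = 200,
                  seed = 8, min_occurrences = 15)
  # oracle: minimize the identical objective by quasi-Newton with a smoothed
  # absolute value; glmnet objective is (1/N) sum nll + lambda * |beta|_1
  vals <- cell_values(st)
  set.seed(8)
  ok <- which(complete.cases(vals))
  bg <- if (length(ok) > 200) sample(ok, 200) else ok
  ci <- paleoterrapin:::cell_index(st, occ$lon, occ$lat)
  feat <- rbind(vals[ci, ], vals[bg, ])
  fx <- scale(feat, m$center[colnames(feat)], m$scale[colnames(feat)])
  y <- rep(c(1, 0), c(nrow(occ), length(bg)))
  objective <- function(par) {
    eta <- par[1] + fx %*% par[-1]
    mean(log(1 + exp(eta)) - y * eta) +
      m$lambda * sum(sqrt(par[-1]^2 + 1e-16))
  }
  o <- optim(c(0, 0, 0), objective, method = "BFGS",
             control = list(maxit = 2000, reltol = 1e-14))
  expect_equal(unname(m$coef), o$par, tolerance = 1e-4)
})

test_that("rank AUC equals trapezoidal ROC integration and flags separation", {
  expect_equal(rank_auc(c(5, 6, 7), c(1, 2, 3)), 1)
  set.seed(13)
  pos <- rnorm(300, 0.5); neg <- rnorm(400)
  trap_auc <- function(pos, neg) {
    th <- sort(unique(c(pos, neg, -Inf, Inf)), decreasing = TRUE)
    tpr <- vapply(th, function(t) mean(pos >= t), numeric(1))
    fpr <- vapply(th, function(t) mean(neg >= t), numeric(1))
    sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  }
  expect_equal(rank_auc(pos, neg), trap_auc(pos, neg), tolerance = 1e-12)
  # random scores give AUC near 1/2 (Mann-Whitney null)
  set.seed(14)
  a <- rnorm(1000); b <- rnorm(1000)
  expect_equal(rank_auc(a, b), 0.5, tolerance = 0.04)
})

test_that("model selection gates on AUC and breaks ties as documented", {
  w <- make_world(15)
  occ <- thin_occurrences(w$occurrences, 4.5, seed = 2, crs = "planar_km")
  p <- raster_pca(w$stacks$present)
  sel <- evaluate_and_select(occ, p$scores, feature_grid = c("L", "LQ"),
                             multipliers = c(1, 2), n_background = 1000,
                             seed = 4)
  ev <- sel$evaluation
  expect_s3_class(ev, "data.frame")
  expect_true(all(ev$mean_auc >= 0 & ev$mean_auc <= 1, na.rm = TRUE))
  if (!is.null(sel$selected)) {
    chosen <- ev[ev$selected, ]
    passing <- ev[ev$mean_auc > 0.7 & !ev$flagged & is.finite(ev$aicc), ]
    expect_equal(chosen$aicc, min(passing$aicc))
  }
  # deterministic given seed
  sel2 <- evaluate_and_select(occ, p$scores, feature_grid = c("L", "LQ"),
                              multipliers = c(1, 2), n_background = 1000,
                              seed = 4)
  expect_identical(sel$evaluation, sel2$evaluation)
})

test_that("suitable area is monotone in the threshold and matches arithmetic", {
  w <- make_world(17)
  occ <- thin_occurrences(w$occurrences, 4.5, seed = 2, crs = "planar_km")
  p <- raster_pca(w$stacks$present)
  sel <- evaluate_and_select(occ, p$scores, feature_grid = "L",
                             multipliers = 1, n_background = 1000, seed = 5)
  skip_if(is.null(sel$selected))  # never expected; guards a degenerate draw
  thr <- c(0.1, 0.36, 0.6, 0.9)
  areas <- vapply(thr, function(t)
    project_and_area(sel$selected, w$stacks["present"], p$transform,
                     threshold = t)$area_km2, numeric(1))
  expect_true(all(diff(areas) <= 0))
  ar <- project_and_area(sel$selected, w$stacks, p$transform)
  suit <- attr(ar, "suitability")$present
  expect_equal(ar$area_km2[ar$period == "present"],
               sum(suit >= 0.36, na.rm = TRUE) * 4.5^2)
  expect_equal(max(ar$normalized), 1)
  # an ice mask removes its cells from the area
  mask <- matrix(TRUE, nrow(suit), ncol(suit))
  ar0 <- project_and_area(sel$selected, w$stacks["present"], p$transform,
                          ice_mask = list(present = mask))
  expect_equal(ar0$area_km2, 0)
})

test_that("the fitted area series tracks the generator's true direction", {
  w <- make_world(19)
  occ <- thin_occurrences(w$occurrences, 4.5, seed = 2, crs = "planar_km")
  p <- raster_pca(w$stacks$present)
  sel <- evaluate_and_select(occ, p$scores, feature_grid = c("L", "LQ"),
                             n_background = 1500, seed = 6)
  skip_if(is.null(sel$selected))
  ar <- project_and_area(sel$selected, w$stacks, p$transform)
  est <- setNames(ar$area_km2, ar$period)
  truth <- w$true_area_km2
  # LGM is the strong contraction in the default scenario
  expect_lt(est[["LGM"]], est[["present"]])
  expect_equal(names(sort(truth))[1], names(sort(est))[1])
})

test_that("Moran's I handles iid, clustered and empty-band cases", {
  set.seed(21)
  pts <- data.frame(lon = runif(40, 0, 8), lat = runif(40, 0, 8),
                    resid = rnorm(40))
  mi <- morans_i(pts, n_distance_bins = 7, max_distance_km = 10,
                 crs = "planar_km", n_perm = 199, seed = 1)
  expect_equal(nrow(mi), 7L)
  done <- !is.na(mi$moran_i)
  expect_true(any(done))
  expect_true(all(abs(mi$moran_i[done]) < 1))
  # two tight clusters with equal values inside each: strong positive I
  cl <- data.frame(lon = c(rnorm(10, 0, .05), rnorm(10, 50, .05)),
                   lat = 0, resid = rep(c(1, -1), each = 10))
  mic <- morans_i(cl, n_distance_bins = 2, max_distance_km = 1,
                  crs = "planar_km", n_perm = 199, seed = 2)
  expect_gt(mic$moran_i[1], 0.9)
  expect_lt(mic$p_value[1], 0.05)
  # a band with no pairs is reported missing
  expect_true(is.na(mic$moran_i[2]) || mic$n_pairs[2] >= 2)
})
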