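test_that("pattern parsing expands the free-interval grouping", {
  d <- parse_pattern("2+2+25*2+4+6", 64)
  expect_equal(d$atomic_counts, c(2, 2, rep(2, 25), 4, 6))
  expect_equal(sum(d$atomic_counts), 64)
  expect_equal(d$n_free, 29)
  expect_equal(length(d$boundaries), 65)
  expect_true(all(diff(d$boundaries) > 0))
  expect_equal(d$boundaries[1], 0)
  expect_equal(d$boundaries[65], 15, tolerance = 1e-12)

  # "m*a" = m free intervals of a atomic intervals each
  d2 <- parse_pattern("64*1", 64)
  expect_equal(d2$n_free, 64)
  expect_true(all(d2$atomic_counts == 1))
  d3 <- parse_pattern("1*64", 64)
  expect_equal(d3$n_free, 1)
  expect_equal(d3$atomic_counts, 64)

  expect_error(parse_pattern("2+2", 64), "sum to 4")
  expect_error(parse_pattern("2+*3", 64), "bad pattern token")
})

test_that("transition rows and equilibrium distribution are proper", {
  m <- tiny_model()
  parts <- paleoterrapin:::smc_hmm_parts(m)
  expect_equal(rowSums(parts$A), rep(1, 4), tolerance = 1e-12)
  expect_equal(sum(parts$pi), 1, tolerance = 1e-12)
  expect_true(all(parts$A >= 0))
})

test_that("forward likelihood equals exhaustive path enumeration", {
  set.seed(10)
  for (rep in 1:4) {
    lam <- exp(rnorm(4, 0, 0.5))
    m <- tiny_model(lambda = lam, theta = runif(1, 0.05, 0.5),
                    rho = runif(1, 0.02, 0.3))
    parts <- paleoterrapin:::smc_hmm_parts(m)
    obs <- sample(c(0L, 1L, 2L), 9, replace = TRUE)
    fb <- paleoterrapin:::forward_backward_cpp(obs, parts$A, parts$ehet,
                                               parts$pi)
    oracle <- enumerate_loglik(obs, parts$A, parts$ehet, parts$pi)
    expect_equal(fb$loglik, oracle, tolerance = 1e-10)
  }
})

test_that("forward-backward posteriors sum to one at every bin", {
  m <- tiny_model()
  parts <- paleoterrapin:::smc_hmm_parts(m)
  set.seed(12)
  obs <- sample(c(0L, 1L, 2L), 500, replace = TRUE, prob = c(.8, .1, .1))
  fb <- paleoterrapin:::forward_backward_cpp(obs, parts$A, parts$ehet,
                                             parts$pi, TRUE)
  expect_true(all(abs(fb$posterior_sums - 1) < 1e-10))
})

test_that("EM log-likelihood is non-decreasing", {
  sc <- demography_scenario(data.frame(start_gen = 0, ne = 1e4),
                            1e-8, 1e-8, 3e5, seed = 17)
  sim <- simulate_het_track(sc)
  fit <- fit_smc(sim$track, n_em_iters = 8)
  expect_gte(length(fit$loglik_trace), 2L)
  expect_true(all(diff(fit$loglik_trace) >=
                    -1e-8 * abs(fit$loglik_trace[-1])))
})

test_that("an all-homozygous track is flagged degenerate without crashing", {
  track <- het_bin_track(list(s = rep(0L, 500)), 100)
  expect_warning(fit <- fit_smc(track, n_em_iters = 3), "degenerate")
  expect_true(fit$degenerate)
  expect_error(fit_smc(het_bin_track(list(s = rep(2L, 50)), 100)),
               "entirely missing")
})

test_that("bottleneck direction is recovered qualitatively", {
  # recent Ne = ancestral / 4 up to 5000 generations ago: the fitted
  # relative sizes should sit lower in the recent window than the ancient
  sc <- demography_scenario(data.frame(start_gen = c(0, 5000),
                                       ne = c(2500, 1e4)),
                            1e-8, 1e-8, 2e6, seed = 23)
  sim <- simulate_het_track(sc)
  fit <- fit_smc(sim$track, n_em_iters = 12)
  ne_rel <- fit$trajectory$steps$ne
  tt <- fit$trajectory$steps$time
  recent <- mean(ne_rel[tt > 0.02 & tt < 0.25])
  ancient <- mean(ne_rel[tt > 1 & tt < 4])
  expect_lt(recent, ancient)
})

test_that("bootstrap is deterministic, sized, and empty at zero replicates", {
  sc <- demography_scenario(data.frame(start_gen = 0, ne = 1e4),
                            1e-8, 1e-8, 2e5, seed = 19)
  sim <- simulate_het_track(sc)
  expect_identical(bootstrap_smc(sim$track, n_reps = 0), list())
  b1 <- bootstrap_smc(sim$track, n_reps = 2, segment_size_bp = 5e4,
                      seed = 7, n_em_iters = 2)
  b2 <- bootstrap_smc(sim$track, n_reps = 2, segment_size_bp = 5e4,
                      seed = 7, n_em_iters = 2)
  expect_equal(length(b1), 2L)
  expect_identical(lapply(b1, `[[`, "steps"), lapply(b2, `[[`, "steps"))
})

test_that("calibration arithmetic follows the generation-time formula", {
  cal <- calibrate(d = 0.012, T_years = 3e7, alpha = 12, L = 30)
  expect_equal(cal$g, 27)
  expect_equal(cal$mu_per_gen, 5.4e-9)
  expect_equal(cal$mu_per_year, 2e-10)
  expect_equal(cal$mu_per_year, cal$mu_per_gen / cal$g)
  expect_error(calibrate(-1, 1, 1, 1), "positive")
})

test_that("year scaling is linear in g and leaves relative shape intact", {
  traj <- structure(list(steps = data.frame(time = c(0, 0.5, 1, 2),
                                            ne = c(1, 2, 0.5, 1)),
                         units = "coalescent", theta = 0.04, rho = 0.008,
                         species = "x", bootstrap = NULL),
                    class = "demographic_trajectory")
  cal1 <- calibrate(d = 0.01, T_years = 1e7, alpha = 10, L = 20)   # g = 20
  cal2 <- calibrate(d = 0.005, T_years = 1e7, alpha = 20, L = 40)  # g = 40
  expect_equal(cal1$mu_per_gen, cal2$mu_per_gen)  # same per-generation rate
  s1 <- scale_to_years(traj, cal1, 100)
  s2 <- scale_to_years(traj, cal2, 100)
  n0 <- 0.04 / (4 * cal1$mu_per_gen * 100)
  expect_equal(s1$steps$time, traj$steps$time * 2 * n0 * 20)
  expect_equal(s1$steps$ne, traj$steps$ne * n0)
  # doubling g at fixed per-generation mu doubles year-times, leaves Ne as is
  expect_equal(s2$steps$time[-1] / s1$steps$time[-1], rep(2, 3))
  expect_equal(s2$steps$ne, s1$steps$ne)
  expect_error(scale_to_years(s1, cal1), "already in years")
})

test_that("year scaling commutes with the bootstrap envelope", {
  sc <- demography_scenario(data.frame(start_gen = 0, ne = 1e4),
                            1e-8, 1e-8, 2e5, seed = 29)
  sim <- simulate_het_track(sc)
  fit <- fit_smc(sim$track, n_em_iters = 3)
  boots <- bootstrap_smc(sim$track, n_reps = 2, segment_size_bp = 5e4,
                         seed = 3, n_em_iters = 3)
  cal <- calibrate(0.01, 2e7, 12, 30)
  fit$trajectory$bootstrap <- boots
  scaled_together <- scale_to_years(fit$trajectory, cal)
  scaled_alone <- lapply(boots, scale_to_years, calib = cal)
  expect_equal(lapply(scaled_together$bootstrap, `[[`, "steps"),
               lapply(scaled_alone, `[[`, "steps"))
})

test_that("mean Ne excludes exactly the four most recent points", {
  traj <- structure(list(steps = data.frame(time = c(10, 20, 30, 40, 50,
                                                     60, 70),
                                            ne = c(1, 2, 3, 4, 5, 6, 7)),
                         units = "years", theta = 0.04),
                    class = "demographic_trajectory")
  expect_equal(mean_ne(traj), mean(c(5, 6, 7)))
  expect_equal(mean_ne(traj, exclude_recent = 0), 4)
  expect_error(mean_ne(traj, exclude_recent = 7), "too few")
})

test_that("min-max normalization and group averaging behave as stated", {
  mk <- function(ne) structure(
    list(steps = data.frame(time = c(1e4, 1e5, 1e6), ne = ne),
         units = "years", theta = 0.04), class = "demographic_trajectory")
  out <- normalize_and_average(list(a = mk(c(2, 4, 6))), grid_n = 16)
  expect_equal(min(out$mean_norm_ne), 0)
  expect_equal(max(out$mean_norm_ne), 1)
  expect_true(all(out$mean_norm_ne >= 0 & out$mean_norm_ne <= 1))
  # single-species group mean equals that species' own normalized curve
  two <- normalize_and_average(list(a = mk(c(2, 4, 6)), b = mk(c(9, 1, 5))),
                               grouping = c("g1", "g2"), grid_n = 16)
  expect_equal(two$mean_norm_ne[two$group == "g1"], out$mean_norm_ne)
  expect_warning(normalize_and_average(list(a = mk(c(3, 3, 3)))),
                 "constant trajectory")
  # per-period display normalization divides by the maximum only
  mx <- normalize_and_average(list(a = mk(c(2, 4, 6))), grid_n = 16,
                              mode = "max")
  expect_equal(max(mx$mean_norm_ne), 1)
  expect_gt(min(mx$mean_norm_ne), 0)
})

test_that("the plain-text fit report carries the fitted parameters", {
  sc <- demography_scenario(data.frame(start_gen = 0, ne = 1e4),
                            1e-8, 1e-8, 2e5, seed = 37)
  fit <- fit_smc(simulate_het_track(sc)$track, n_em_iters = 2)
  path <- tempfile(fileext = ".txt")
  write_smc_report(fit, path)
  lines <- readLines(path)
  expect_true(any(grepl("^TR ", lines)))
  expect_equal(sum(grepl("^RS\t", lines)), nrow(fit$trajectory$steps))
  tr <- as.numeric(strsplit(grep("^TR ", lines, value = TRUE), " ")[[1]][2])
  expect_equal(tr, fit$model$theta, tolerance = 1e-8)
  file.remove(path)
})

test_that("trajectory TSV writer emits point estimate plus replicates", {
  traj <- structure(list(steps = data.frame(time = c(1, 2), ne = c(3, 4)),
                         units = "years", theta = 0.1,
                         bootstrap = list(structure(
                           list(steps = data.frame(time = c(1, 2),
                                                   ne = c(5, 6)),
                                units = "years"),
                           class = "demographic_trajectory"))),
                    class = "demographic_trajectory")
  path <- tempfile(fileext = ".tsv")
  write_trajectory_tsv(traj, path)
  tab <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(names(tab), c("time_years", "ne", "replicate_id"))
  expect_equal(sort(unique(tab$replicate_id)), c(0, 1))
  file.remove(path)
})
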