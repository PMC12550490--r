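## Pairwise sequentially-Markovian-coalescent HMM: EM fitting of the
## per-interval coalescence intensities, bootstrap, and trajectory handling.
## Time inside the model is in units of 2 * N0 generations; the observation
## is the binned het/hom/missing track.

#' Construct an SMC model parameter set
#'
#' @param theta Scaled mutation rate per bin (`4 * N0 * mu * bin_size`).
#' @param rho Scaled recombination rate per bin; defaults to `theta / 5`
#'   (the `-r 5` convention: theta/rho ratio 5 at initialization).
#' @param lambda_free Relative coalescence intensity per free interval
#'   (inverse relative Ne); recycled to the number of free intervals.
#' @param disc A [parse_pattern()] time discretization.
#' @return An `smc_model` object.
#' @export
smc_model <- function(theta, rho = theta / 5, lambda_free = 1,
                      disc = parse_pattern("2+2+25*2+4+6", 64L)) {
  stopifnot(theta > 0, rho > 0)
  lambda_free <- rep(lambda_free, length.out = disc$n_free)
  if (any(lambda_free <= 0)) stop("lambda must be positive")
  structure(list(theta = theta, rho = rho, lambda_free = lambda_free,
                 disc = disc), class = "smc_model")
}

## model -> HMM ingredients on the atomic grid
smc_hmm_parts <- function(model) {
  disc <- model$disc
  lam <- expand_free(disc, model$lambda_free)
  list(A = smcp_transition_cpp(disc$tmid, disc$boundaries, lam, model$rho),
       pi = tmrca_equilibrium_cpp(disc$boundaries, lam),
       ehet = 1 - exp(-model$theta * disc$tmid))
}

#' Forward log-likelihood of a binned track under an SMC model
#'
#' Exposed mainly for oracle testing of the forward recursion; [fit_smc()]
#' computes it internally.
#'
#' @param track A [het_bin_track()].
#' @param model An [smc_model()].
#' @return Log-likelihood (sum over scaffolds).
#' @export
smc_loglik <- function(track, model) {
  parts <- smc_hmm_parts(model)
  sum(vapply(track$bins, function(obs)
    forward_backward_cpp(obs, parts$A, parts$ehet, parts$pi)$loglik,
    numeric(1)))
}

## aggregated E-step over scaffolds
smc_estep <- function(track, model, want_posterior = FALSE) {
  parts <- smc_hmm_parts(model)
  K <- length(parts$ehet)
  xi <- matrix(0, K, K); het <- hom <- g1 <- numeric(K); ll <- 0
  post <- list()
  for (sc in names(track$bins)) {
    fb <- forward_backward_cpp(track$bins[[sc]], parts$A, parts$ehet,
                               parts$pi, want_posterior)
    ll <- ll + fb$loglik
    xi <- xi + fb$xi; het <- het + fb$het; hom <- hom + fb$hom
    g1 <- g1 + fb$gamma1
    if (want_posterior) post[[sc]] <- fb$posterior_sums
  }
  list(loglik = ll, xi = xi, het = het, hom = hom, gamma1 = g1,
       posterior_sums = post)
}

## expected complete-data log-likelihood for given counts (the EM Q function)
smc_q <- function(par, disc, counts) {
  smc_q_cpp(disc$tmid, disc$boundaries,
            expand_free(disc, exp(par[-(1:2)])), exp(par[2L]), exp(par[1L]),
            counts$xi, counts$het, counts$hom, counts$gamma1)
}

#' Fit the SMC demographic model by expectation-maximization
#'
#' Runs EM over the hidden discretized-TMRCA chain: the E-step is a scaled
#' forward-backward pass per scaffold (emission `P(HET | state k) =
#' 1 - exp(-theta * t_k)`, SMC' transitions parameterized by `rho` and the
#' per-interval intensities `lambda`); the M-step maximizes the expected
#' complete-data log-likelihood over `(theta, rho, lambda)` by L-BFGS-B on
#' the log scale (a generalized EM step, so the observed log-likelihood is
#' non-decreasing).
#'
#' @param track A [het_bin_track()].
#' @param disc A [parse_pattern()] discretization (defaults to the
#'   64-atomic / `"2+2+25*2+4+6"` pattern with `t_max = 15`).
#' @param init Optional [smc_model()] initial values; by default `theta` is
#'   set from the observed het-bin fraction and `rho = theta / 5`.
#' @param n_em_iters Maximum EM iterations (default 25).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @param m_step_maxit L-BFGS-B iteration cap per M-step (default 30).
#' @return An `smc_fit` list: `model`, `trajectory` (coalescent units),
#'   `loglik_trace`, `n_iters`, `degenerate`.
#' @export
fit_smc <- function(track, disc = parse_pattern("2+2+25*2+4+6", 64L),
                    init = NULL, n_em_iters = 25L, tol = 1e-6,
                    m_step_maxit = 30L) {
  stopifnot(inherits(track, "het_bin_track"))
  obs_all <- unlist(track$bins, use.names = FALSE)
  if (!length(obs_all)) stop("empty track")
  if (all(obs_all == MISS_STATE)) stop("track is entirely missing")
  informative <- obs_all != MISS_STATE
  hf <- mean(obs_all[informative] == HET_STATE)
  degenerate <- hf == 0
  if (is.null(init)) {
    theta0 <- if (degenerate) 1e-6 else hf / (1 - hf)
    init <- smc_model(theta0, theta0 / 5, 1, disc)
  }
  model <- init
  model$disc <- disc
  ll_trace <- numeric(0)
  if (degenerate) {
    warning("no heterozygous bins: returning initial model, fit flagged ",
            "degenerate")
    es <- smc_estep(track, model)
    ll_trace <- es$loglik
  } else {
    par <- log(c(model$theta, model$rho, model$lambda_free))
    lb <- rep(log(1e-8), length(par)); ub <- rep(log(1e4), length(par))
    for (it in seq_len(n_em_iters)) {
      counts <- smc_estep(track, model)
      ll_trace <- c(ll_trace, counts$loglik)
      if (it > 1L &&
          abs(ll_trace[it] - ll_trace[it - 1L]) <
            tol * abs(ll_trace[it - 1L])) break
      q0 <- smc_q(par, disc, counts)
      opt <- optim(par, function(p) -smc_q(p, disc, counts),
                   method = "L-BFGS-B", lower = lb, upper = ub,
                   control = list(maxit = m_step_maxit))
      if (-opt$value > q0) par <- opt$par  # generalized EM: accept only gains
      model$theta <- exp(par[1L]); model$rho <- exp(par[2L])
      model$lambda_free <- exp(par[-(1:2)])
    }
  }
  traj <- trajectory_from_model(model)
  structure(list(model = model, trajectory = traj, loglik_trace = ll_trace,
                 n_iters = length(ll_trace), degenerate = degenerate),
            class = "smc_fit")
}

#' Stepwise Ne trajectory implied by an SMC model (coalescent units)
#'
#' Times are left edges of the free intervals in `2 * N0` units; `ne` is the
#' relative size `1 / lambda` (multiplied by `N0` when scaled to years).
#'
#' @param model An [smc_model()].
#' @return A `demographic_trajectory` object.
#' @export
trajectory_from_model <- function(model) {
  disc <- model$disc
  first_atomic <- match(seq_len(disc$n_free), disc$group)
  steps <- data.frame(time = disc$boundaries[first_atomic],
                      ne = 1 / model$lambda_free)
  structure(list(steps = steps, units = "coalescent", theta = model$theta,
                 rho = model$rho, species = NA_character_,
                 bootstrap = NULL), class = "demographic_trajectory")
}

#' @export
print.demographic_trajectory <- function(x, ...) {
  cat("demographic_trajectory (", x$units, " units): ", nrow(x$steps),
      " steps", if (!is.null(x$bootstrap))
        paste0(", ", length(x$bootstrap), " bootstrap replicates"),
      "\n", sep = "")
  invisible(x)
}

#' Write a plain-text SMC fit report
#'
#' A compact fit summary mirroring the common pairwise-SMC text layout:
#' one header line per scalar (log-likelihood, theta, rho), then one `RS`
#' line per free interval with its start time (coalescent units) and
#' relative size.
#'
#' @param fit An `smc_fit` from [fit_smc()].
#' @param path Output path.
#' @export
write_smc_report <- function(fit, path) {
  stopifnot(inherits(fit, "smc_fit"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("LK", format(utils::tail(fit$loglik_trace, 1), digits = 12)),
    paste("IT", fit$n_iters),
    paste("TR", format(fit$model$theta, digits = 10),
          format(fit$model$rho, digits = 10)),
    paste("PA", fit$model$disc$pattern)), con)
  st <- fit$trajectory$steps
  writeLines(sprintf("RS\t%d\t%.6f\t%.6f", seq_len(nrow(st)) - 1L,
                     st$time, st$ne), con)
  invisible(path)
}

#' Block bootstrap of the SMC fit
#'
#' Splits the scaffolds into fixed-size segments, resamples segments with
#' replacement up to the original total length, refits, and returns one
#' trajectory per replicate.
#'
#' @param track A [het_bin_track()].
#' @param disc Time discretization.
#' @param n_reps Number of replicates (default 30).
#' @param segment_size_bp Segment size in bp (default 5e6).
#' @param seed Integer seed.
#' @param ... Passed to [fit_smc()].
#' @return List of `demographic_trajectory` objects (coalescent units).
#' @export
bootstrap_smc <- function(track, disc = parse_pattern("2+2+25*2+4+6", 64L),
                          n_reps = 30L, segment_size_bp = 5e6, seed = 1L,
                          ...) {
  stopifnot(inherits(track, "het_bin_track"))
  if (n_reps == 0L) return(list())
  seg_bins <- max(1L, as.integer(segment_size_bp / track$bin_size_bp))
  segments <- list()
  for (sc in names(track$bins)) {
    b <- track$bins[[sc]]
    starts <- seq(1L, length(b), by = seg_bins)
    for (s in starts) segments <- c(segments,
                                    list(b[s:min(s + seg_bins - 1L,
                                                 length(b))]))
  }
  total <- sum(lengths(track$bins))
  set.seed(seed)
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    picked <- list(); n <- 0L
    while (n < total) {
      seg <- segments[[sample.int(length(segments), 1L)]]
      picked <- c(picked, list(seg)); n <- n + length(seg)
    }
    names(picked) <- sprintf("bootseg_%04d", seq_along(picked))
    bt <- het_bin_track(picked, bin_size_bp = track$bin_size_bp)
    fit <- fit_smc(bt, disc = disc, ...)
    out[[r]] <- fit$trajectory
  }
  out
}
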