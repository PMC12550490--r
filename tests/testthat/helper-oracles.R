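# Shared independent oracles and small fixture builders.

# Exhaustive hidden-path likelihood of an HMM: brute-force sum over all K^n
# state paths. Independent of the forward recursion it checks.
enumerate_loglik <- function(obs, A, ehet, pi) {
  K <- length(ehet)
  n <- length(obs)
  emit <- function(o, k) if (o == 1L) ehet[k] else if (o == 0L) 1 - ehet[k]
    else 1
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    p <- paths[r, ]
    pr <- pi[p[1]] * emit(obs[1], p[1])
    for (i in seq_len(n)[-1]) pr <- pr * A[p[i - 1], p[i]] * emit(obs[i], p[i])
    tot <- tot + pr
  }
  log(tot)
}

# Exhaustive maximum independent set size under a minimum-distance
# constraint (brute force over all subsets; n <= 15).
brute_max_thinned <- function(d, min_dist) {
  n <- nrow(d)
  best <- 0L
  for (mask in seq_len(2^n) - 1L) {
    keep <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(keep) <= best) next
    if (length(keep) < 2L ||
        all(d[keep, keep][upper.tri(d[keep, keep])] >= min_dist))
      best <- length(keep)
  }
  best
}

# small genotype track fixture: explicit sites on one scaffold
make_track <- function(pos, genotype, depth = 30L, len = max(pos),
                       scaffold = "s1", baseq = 30, mapq = 60) {
  genotype_track(data.frame(scaffold = scaffold, pos = pos,
                            genotype = genotype, depth = depth,
                            baseq = baseq, mapq = mapq),
                 scaffold_lengths = setNames(len, scaffold))
}

# tiny SMC model on a 4-atomic discretization
tiny_model <- function(lambda = c(1.2, 0.7, 1.5, 0.9), theta = 0.3,
                       rho = 0.1, t_max = 4) {
  disc <- parse_pattern("1*4", 4L, t_max = t_max)
  paleoterrapin:::smc_model(theta, rho, lambda, disc)
}
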