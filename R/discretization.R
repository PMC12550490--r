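#' Parse a free-interval grouping pattern into a time discretization
#'
#' The pairwise SMC model discretizes coalescent time into `n_atomic`
#' log-spaced atomic intervals whose coalescence intensities are tied together
#' in "free" groups. The grouping is written in the upstream pattern dialect:
#' tokens separated by `+`, each either an atomic count `a` or `m*a`
#' (`m` free intervals of `a` atomic intervals each). For example
#' `"2+2+25*2+4+6"` expands to free-interval sizes `c(2, 2, rep(2, 25), 4, 6)`
#' covering 64 atomic intervals.
#'
#' Atomic boundaries follow the standard log spacing
#' `t_k = 0.1 * (exp((k/n) * log(1 + 10 * t_max)) - 1)` for `k = 0..n`,
#' in units of `2 * N0` generations, with the last interval absorbing all
#' deeper coalescent mass.
#'
#' @param pattern Grouping pattern string, e.g. `"2+2+25*2+4+6"`.
#' @param n_atomic Number of atomic intervals (default 64).
#' @param t_max Upper limit of the discretization in coalescent (2N0) units
#'   (the `-t` parameter; default 15).
#' @return An object of class `time_discretization` with elements
#'   `boundaries` (length `n_atomic + 1`), `tmid` (representative times),
#'   `group` (free-interval index of each atomic interval), `n_free`,
#'   `atomic_counts`, `pattern`, `t_max`.
#' @examples
#' d <- parse_pattern("2+2+25*2+4+6", 64)
#' d$n_free
#' @export
parse_pattern <- function(pattern, n_atomic = 64L, t_max = 15) {
  stopifnot(is.character(pattern), length(pattern) == 1L, n_atomic >= 1L,
            t_max > 0)
  tokens <- strsplit(gsub("[[:space:]]", "", pattern), "+", fixed = TRUE)[[1]]
  if (!length(tokens) || any(!nzchar(tokens)))
    stop("empty token in pattern '", pattern, "'")
  counts <- integer(0)
  for (tok in tokens) {
    if (grepl("^[0-9]+\\*[0-9]+$", tok)) {
      ma <- as.integer(strsplit(tok, "*", fixed = TRUE)[[1]])
      counts <- c(counts, rep.int(ma[2L], ma[1L]))
    } else if (grepl("^[0-9]+$", tok)) {
      counts <- c(counts, as.integer(tok))
    } else {
      stop("bad pattern token '", tok, "': expected 'a' or 'm*a'")
    }
  }
  if (sum(counts) != n_atomic)
    stop("pattern atomic intervals sum to ", sum(counts),
         ", expected ", n_atomic)
  k <- seq_len(n_atomic + 1L) - 1L
  bnd <- 0.1 * (exp((k / n_atomic) * log(1 + 10 * t_max)) - 1)
  tmid <- (bnd[-length(bnd)] + bnd[-1L]) / 2
  structure(list(
    boundaries = bnd,
    tmid = tmid,
    group = rep.int(seq_along(counts), counts),
    n_free = length(counts),
    atomic_counts = counts,
    pattern = pattern,
    n_atomic = n_atomic,
    t_max = t_max
  ), class = "time_discretization")
}

#' @export
print.time_discretization <- function(x, ...) {
  cat("Time discretization: ", x$n_atomic, " atomic intervals in ",
      x$n_free, " free groups (pattern '", x$pattern, "', t_max = ",
      x$t_max, ")\n", sep = "")
  invisible(x)
}

#' Expand per-free-interval values to the atomic grid
#' @noRd
expand_free <- function(disc, values_free) {
  stopifnot(length(values_free) == disc$n_free)
  values_free[disc$group]
}
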