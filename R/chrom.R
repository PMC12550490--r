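## ChromSeq scaffold-to-chromosome assignment: the position representation
## ratio (PRR) statistic, its binomial p-value, and per-scaffold summaries.

#' Position representation ratio
#'
#' `PRR = (n_pos_scaffold / n_pos_genome) / (scaffold_len / genome_len)`;
#' values above 1 indicate enrichment of mapped chromosome-read positions on
#' the scaffold, below 1 depletion. Because PRR is distributed lognormally,
#' its natural log is used for thresholding (`logPRR > 0` = enriched).
#'
#' @param n_pos_scaffold Positions mapped on the scaffold.
#' @param n_pos_genome Positions mapped genome-wide (> 0).
#' @param scaffold_len,genome_len Lengths in bp (> 0).
#' @return List with `prr` and `log_prr`.
#' @export
prr <- function(n_pos_scaffold, n_pos_genome, scaffold_len, genome_len) {
  if (n_pos_genome <= 0) stop("no genome-wide positions")
  if (scaffold_len <= 0 || genome_len <= 0) stop("lengths must be positive")
  val <- (n_pos_scaffold / n_pos_genome) / (scaffold_len / genome_len)
  list(prr = val, log_prr = log(val))
}

#' Binomial p-value of a PRR
#'
#' One-sided (enrichment) binomial test: the probability of observing at
#' least `n_pos_scaffold` of `n_pos_genome` positions on a scaffold whose
#' length fraction of the genome is the success probability.
#'
#' @inheritParams prr
#' @return p-value.
#' @export
prr_pvalue <- function(n_pos_scaffold, n_pos_genome, scaffold_len,
                       genome_len) {
  p0 <- scaffold_len / genome_len
  if (p0 <= 0 || p0 >= 1) stop("scaffold length fraction outside (0, 1)")
  pbinom(n_pos_scaffold - 1, n_pos_genome, p0, lower.tail = FALSE)
}

#' Per-scaffold position statistics for one chromosome sample
#'
#' @param table Read-position data frame (`chromosome`, `scaffold`,
#'   `position`, optional `reads`).
#' @param chromosome,scaffold Labels selecting the records.
#' @return List with `n_positions`, `mean_pairwise_distance` (NA for a
#'   single position) and `mean_reads_per_position`.
#' @export
scaffold_stats <- function(table, chromosome, scaffold) {
  rec <- table[table$chromosome == chromosome & table$scaffold == scaffold, ,
               drop = FALSE]
  if (!nrow(rec)) stop("no positions for ", chromosome, " / ", scaffold)
  pos <- sort(rec$position)
  mpd <- if (length(pos) >= 2L) mean(dist(pos)) else NA_real_
  reads <- if (is.null(rec$reads)) rep(1, nrow(rec)) else rec$reads
  list(n_positions = nrow(rec), mean_pairwise_distance = mpd,
       mean_reads_per_position = mean(reads))
}

#' Assign scaffolds to micro-dissected chromosomes by PRR enrichment
#'
#' For every (chromosome sample, scaffold) pair computes the PRR, its
#' one-sided binomial p-value and the per-scaffold summaries; a scaffold is
#' called enriched for a chromosome when `logPRR > 0`, `p <= p_max` and it
#' carries at least `min_positions` mapped positions. An optional minimum
#' mean pairwise distance filters clustered amplification artefacts.
#'
#' @param table Read-position data frame (`chromosome`, `scaffold`,
#'   `position`, optional `reads`).
#' @param scaffold_lengths Named numeric vector of scaffold lengths; the
#'   genome length is their sum.
#' @param min_positions Minimum positions on the scaffold (default 2, the
#'   smallest count with a defined pairwise distance).
#' @param p_max Significance threshold (default 0.01).
#' @param min_mean_distance Optional minimum mean pairwise distance (bp);
#'   NULL (default) disables the filter.
#' @return Data frame with one row per (chromosome, scaffold) pair observed:
#'   counts, summaries, `prr`, `log_prr`, `p`, `enriched`.
#' @export
assign_chromosomes <- function(table, scaffold_lengths, min_positions = 2L,
                               p_max = 0.01, min_mean_distance = NULL) {
  stopifnot(!is.null(names(scaffold_lengths)))
  genome_len <- sum(scaffold_lengths)
  out <- list()
  for (chrom in unique(table$chromosome)) {
    sub <- table[table$chromosome == chrom, , drop = FALSE]
    n_gen <- nrow(sub)
    for (sc in unique(sub$scaffold)) {
      st <- scaffold_stats(table, chrom, sc)
      pr <- prr(st$n_positions, n_gen, scaffold_lengths[[sc]], genome_len)
      p <- prr_pvalue(st$n_positions, n_gen, scaffold_lengths[[sc]],
                      genome_len)
      enr <- pr$log_prr > 0 && p <= p_max && st$n_positions >= min_positions
      if (!is.null(min_mean_distance))
        enr <- enr && !is.na(st$mean_pairwise_distance) &&
          st$mean_pairwise_distance >= min_mean_distance
      out[[length(out) + 1L]] <- data.frame(
        chromosome = chrom, scaffold = sc, n_positions = st$n_positions,
        mean_pairwise_distance = st$mean_pairwise_distance,
        mean_reads_per_position = st$mean_reads_per_position,
        prr = pr$prr, log_prr = pr$log_prr, p = p, enriched = enr)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
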