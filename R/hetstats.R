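## Depth filtering, genome-wide heterozygosity, and binning of genotype
## tracks into the psmcfa-style observation sequence.

HOM_STATE <- 0L
HET_STATE <- 1L
MISS_STATE <- 2L

#' Construct a per-site genotype track
#'
#' A light container for VCF-like per-site diploid genotype calls. Positions
#' are 1-based inclusive and must be strictly increasing within a scaffold.
#' Sites absent from the table are treated as homozygous-reference and
#' filter-passing; explicitly listed sites may carry any genotype, depth and
#' quality. `genome_size_bp` defaults to the sum of scaffold lengths, which
#' default to each scaffold's maximum listed position.
#'
#' @param sites Data frame with columns `scaffold`, `pos`, `genotype`
#'   (one of `"hom_ref"`, `"het"`, `"hom_alt"`, `"missing"`); optional
#'   `depth`, `baseq`, `mapq` (defaults 30, 30, 60).
#' @param scaffold_lengths Named numeric vector of scaffold lengths (bp).
#' @param genome_size_bp Total genome size used as the heterozygosity
#'   denominator.
#' @return A `genotype_track` object.
#' @export
genotype_track <- function(sites, scaffold_lengths = NULL,
                           genome_size_bp = NULL) {
  stopifnot(is.data.frame(sites),
            all(c("scaffold", "pos", "genotype") %in% names(sites)))
  ok <- c("hom_ref", "het", "hom_alt", "missing")
  if (!all(sites$genotype %in% ok))
    stop("genotype must be one of: ", paste(ok, collapse = ", "))
  if (is.null(sites$depth)) sites$depth <- 30L
  if (is.null(sites$baseq)) sites$baseq <- 30
  if (is.null(sites$mapq)) sites$mapq <- 60
  if (any(sites$depth < 0)) stop("depth must be non-negative")
  sites <- sites[order(sites$scaffold, sites$pos), , drop = FALSE]
  for (sc in unique(sites$scaffold)) {
    p <- sites$pos[sites$scaffold == sc]
    if (anyDuplicated(p)) stop("duplicated position on scaffold ", sc)
  }
  if (is.null(scaffold_lengths)) {
    scaffold_lengths <- tapply(sites$pos, sites$scaffold, max)
    scaffold_lengths <- setNames(as.numeric(scaffold_lengths),
                                 names(scaffold_lengths))
  }
  if (is.null(genome_size_bp)) genome_size_bp <- sum(scaffold_lengths)
  structure(list(sites = sites, scaffold_lengths = scaffold_lengths,
                 genome_size_bp = genome_size_bp),
            class = "genotype_track")
}

#' Construct a binned heterozygosity track
#'
#' The observation sequence of the SMC demographic model: fixed-width bins
#' (default 100 bp) coded 0 = homozygous, 1 = at least one heterozygous site,
#' 2 = missing.
#'
#' @param bins Named list (one element per scaffold) of integer vectors over
#'   \{0, 1, 2\}.
#' @param bin_size_bp Bin width in bp.
#' @param genome_size_bp Total genome size in bp.
#' @return A `het_bin_track` object.
#' @export
het_bin_track <- function(bins, bin_size_bp = 100L, genome_size_bp = NULL) {
  stopifnot(is.list(bins), length(bins) >= 1L, !is.null(names(bins)),
            bin_size_bp >= 1)
  bins <- lapply(bins, function(b) {
    b <- as.integer(b)
    if (any(!b %in% c(0L, 1L, 2L))) stop("bin states must be 0, 1 or 2")
    b
  })
  if (is.null(genome_size_bp))
    genome_size_bp <- sum(lengths(bins)) * bin_size_bp
  structure(list(bins = bins, bin_size_bp = as.integer(bin_size_bp),
                 genome_size_bp = genome_size_bp),
            class = "het_bin_track")
}

#' @export
print.het_bin_track <- function(x, ...) {
  n <- sum(lengths(x$bins))
  cat("het_bin_track: ", length(x$bins), " scaffold(s), ", n, " bins of ",
      x$bin_size_bp, " bp (", round(100 * mean(unlist(x$bins) == 1L), 3),
      "% HET, ", round(100 * mean(unlist(x$bins) == 2L), 3), "% missing)\n",
      sep = "")
  invisible(x)
}

#' Mean depth of coverage
#'
#' Arithmetic mean of per-site depth over called (non-missing) sites.
#'
#' @param track A [genotype_track()].
#' @return Positive scalar.
#' @export
mean_doc <- function(track) {
  stopifnot(inherits(track, "genotype_track"))
  called <- track$sites$genotype != "missing"
  if (!any(called)) stop("no called sites")
  mean(track$sites$depth[called])
}

#' Filter sites by depth of coverage
#'
#' Retains sites whose depth `d` satisfies `mean_doc / 3 <= d <= 2 * mean_doc`
#' (sites with *less than* one-third or *more than* double the mean depth are
#' removed, so equality is kept); removed sites become `"missing"`.
#'
#' @param track A [genotype_track()].
#' @param doc Mean depth of coverage (default computed with [mean_doc()]).
#' @return A filtered [genotype_track()].
#' @export
filter_by_doc <- function(track, doc = mean_doc(track)) {
  stopifnot(inherits(track, "genotype_track"), doc > 0)
  s <- track$sites
  bad <- s$genotype != "missing" & (s$depth < doc / 3 | s$depth > 2 * doc)
  s$genotype[bad] <- "missing"
  track$sites <- s
  track
}

#' Genome-wide heterozygosity
#'
#' Counts heterozygous genotypes passing the base-quality and mapping-quality
#' filters and divides by the genome size (the total assembly length, not the
#' number of passing sites); `denominator = "callable"` divides by the number
#' of filter-passing called sites instead.
#'
#' @param track A [genotype_track()] (depth-filtered upstream if desired).
#' @param min_baseq Minimum base quality (default 20).
#' @param min_mapq Minimum mapping quality (default 30).
#' @param denominator `"genome"` (default) or `"callable"`.
#' @return List with `H`, `n_het_sites`, `genome_size_bp`,
#'   `n_sites_passing_filters`.
#' @export
heterozygosity <- function(track, min_baseq = 20, min_mapq = 30,
                           denominator = c("genome", "callable")) {
  stopifnot(inherits(track, "genotype_track"))
  denominator <- match.arg(denominator)
  if (track$genome_size_bp <= 0) stop("genome size must be positive")
  s <- track$sites
  pass <- s$genotype != "missing" & s$baseq >= min_baseq & s$mapq >= min_mapq
  n_het <- sum(pass & s$genotype == "het")
  denom <- if (denominator == "genome") track$genome_size_bp else sum(pass)
  list(H = n_het / denom, n_het_sites = n_het,
       genome_size_bp = track$genome_size_bp,
       n_sites_passing_filters = sum(pass))
}

#' Bin a genotype track into a psmcfa-style observation sequence
#'
#' A bin is HET if it contains at least one filter-passing heterozygous site,
#' MISSING if more than `missing_threshold` of its positions are explicitly
#' missing, otherwise HOM. Bins are 0-based half-open internally; listed
#' 1-based site positions map to bin `(pos - 1) %/% bin_size`.
#'
#' @param track A [genotype_track()].
#' @param bin_size_bp Bin width (default 100).
#' @param missing_threshold Fraction of missing positions above which a bin is
#'   coded MISSING (default 0.9).
#' @param min_baseq,min_mapq Quality filters applied to het calls.
#' @return A [het_bin_track()].
#' @export
bin_to_psmcfa <- function(track, bin_size_bp = 100L, missing_threshold = 0.9,
                          min_baseq = 20, min_mapq = 30) {
  stopifnot(inherits(track, "genotype_track"))
  if (bin_size_bp <= 0) stop("bin_size_bp must be positive")
  s <- track$sites
  bins <- list()
  for (sc in names(track$scaffold_lengths)) {
    len <- track$scaffold_lengths[[sc]]
    n_bins <- as.integer(ceiling(len / bin_size_bp))
    states <- rep.int(HOM_STATE, n_bins)
    ss <- s[s$scaffold == sc, , drop = FALSE]
    if (nrow(ss)) {
      bin_of <- (ss$pos - 1L) %/% bin_size_bp + 1L
      miss <- tabulate(bin_of[ss$genotype == "missing"], nbins = n_bins)
      states[miss / bin_size_bp > missing_threshold] <- MISS_STATE
      hetrows <- ss$genotype == "het" & ss$baseq >= min_baseq &
        ss$mapq >= min_mapq
      states[unique(bin_of[hetrows])] <- HET_STATE
    }
    bins[[sc]] <- states
  }
  het_bin_track(bins, bin_size_bp = bin_size_bp,
                genome_size_bp = track$genome_size_bp)
}

# ---------------------------------------------------------------------------
# psmcfa text I/O: FASTA-like records, alphabet T (hom) / K (het) / N
# (missing), 60 characters per line, one record per scaffold.

#' Write a binned het track as psmcfa-style text
#'
#' @param track A [het_bin_track()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_psmcfa <- function(track, path) {
  stopifnot(inherits(track, "het_bin_track"))
  con <- file(path, "w")
  on.exit(close(con))
  code <- c("T", "K", "N")
  for (sc in names(track$bins)) {
    chars <- code[track$bins[[sc]] + 1L]
    writeLines(paste0(">", sc), con)
    n <- length(chars)
    starts <- seq(1L, n, by = 60L)
    writeLines(vapply(starts, function(i)
      paste(chars[i:min(i + 59L, n)], collapse = ""), character(1)), con)
  }
  invisible(path)
}

#' Read a psmcfa-style text file
#'
#' @param path File path.
#' @param bin_size_bp Bin width the file was produced with (default 100).
#' @return A [het_bin_track()].
#' @export
read_psmcfa <- function(path, bin_size_bp = 100L) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no records in ", path)
  ends <- c(hdr[-1L] - 1L, length(lines))
  bins <- list()
  for (i in seq_along(hdr)) {
    nm <- sub("^>\\s*", "", lines[hdr[i]])
    body <- paste(lines[(hdr[i] + 1L):ends[i]], collapse = "")
    chars <- strsplit(body, "")[[1]]
    st <- match(chars, c("T", "K", "N")) - 1L
    if (anyNA(st)) stop("unexpected character in record ", nm)
    bins[[nm]] <- st
  }
  het_bin_track(bins, bin_size_bp = bin_size_bp)
}

#' Read a genotype track from a VCF file
#'
#' Thin wrapper over [vcfR::read.vcfR()]: extracts the first sample's
#' genotype, `DP` depth and (if present) `GQ`, and classifies genotypes as
#' hom-ref / het / hom-alt / missing.
#'
#' @param path VCF path (plain or gzipped).
#' @param scaffold_lengths Optional named scaffold lengths; defaults to
#'   contig lengths in the VCF header when available.
#' @return A [genotype_track()].
#' @export
read_genotype_vcf <- function(path, scaffold_lengths = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_genotype_vcf requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")[, 1L]
  dp <- suppressWarnings(as.integer(vcfR::extract.gt(v, element = "DP")[, 1L]))
  dp[is.na(dp)] <- 0L
  alleles <- strsplit(gsub("\\|", "/", gt), "/", fixed = FALSE)
  cls <- vapply(alleles, function(a) {
    if (length(a) < 2L || any(a == ".")) return("missing")
    if (a[1] == a[2]) { if (a[1] == "0") "hom_ref" else "hom_alt" } else "het"
  }, character(1))
  cls[is.na(gt)] <- "missing"
  if (is.null(scaffold_lengths)) {
    meta <- grep("^##contig", v@meta, value = TRUE)
    if (length(meta)) {
      ids <- sub(".*ID=([^,>]+).*", "\\1", meta)
      lens <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1",
                                              meta)))
      if (!anyNA(lens)) scaffold_lengths <- setNames(lens, ids)
    }
  }
  genotype_track(data.frame(scaffold = as.character(v@fix[, "CHROM"]),
                            pos = as.numeric(v@fix[, "POS"]),
                            genotype = unname(cls), depth = unname(dp)),
                 scaffold_lengths = scaffold_lengths)
}

#' Read a genotype track from a simple TSV dialect
#'
#' Tab-separated columns `scaffold`, `pos`, `genotype` (hom_ref / het /
#' hom_alt / missing) and optionally `depth`, `baseq`, `mapq`, with a
#' header line.
#'
#' @param path TSV path.
#' @param scaffold_lengths Optional named scaffold lengths.
#' @return A [genotype_track()].
#' @export
read_genotype_tsv <- function(path, scaffold_lengths = NULL) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  genotype_track(tab, scaffold_lengths = scaffold_lengths)
}

#' Write a heterozygosity report as JSON
#' @param het Result of [heterozygosity()].
#' @param path Output path.
#' @export
write_het_report <- function(het, path) {
  jsonlite::write_json(het, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
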