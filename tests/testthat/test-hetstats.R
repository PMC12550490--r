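test_that("mean depth of coverage is the mean over called sites", {
  tr <- make_track(c(10, 20, 30), rep("hom_ref", 3), depth = c(10, 10, 10))
  expect_equal(mean_doc(tr), 10)
  tr2 <- make_track(c(10, 20), c("hom_ref", "het"), depth = c(0, 30))
  expect_equal(mean_doc(tr2), 15)
  tr3 <- make_track(c(10, 20), c("missing", "het"), depth = c(500, 30))
  expect_equal(mean_doc(tr3), 30)  # missing sites do not count
  expect_error(mean_doc(make_track(1, "missing")), "no called sites")
})

test_that("mean DOC over many Poisson sites concentrates (law of large numbers)", {
  set.seed(1)
  tr <- make_track(seq_len(1e5), rep("hom_ref", 1e5),
                   depth = rpois(1e5, 30))
  expect_gt(mean_doc(tr), 29.8)
  expect_lt(mean_doc(tr), 30.2)
})

test_that("DOC filter keeps the inclusive boundaries and is idempotent", {
  tr <- make_track(c(10, 20, 30, 40), rep("het", 4),
                   depth = c(9, 10, 60, 61))
  f <- filter_by_doc(tr, doc = 30)
  # less than one-third (9 < 10) and more than double (61 > 60) are removed;
  # the boundary depths 10 and 60 are kept
  expect_equal(f$sites$genotype, c("missing", "het", "het", "missing"))
  same <- make_track(c(1, 2), c("het", "het"), depth = c(30, 30))
  expect_equal(filter_by_doc(same, 30)$sites$genotype, c("het", "het"))
  expect_identical(filter_by_doc(f, doc = 30), f)
})

test_that("fraction removed by the DOC filter matches the exact Poisson tails", {
  set.seed(2)
  n <- 10000
  tr <- make_track(seq_len(n), rep("hom_ref", n), depth = rpois(n, 30))
  f <- filter_by_doc(tr, doc = 30)
  frac <- mean(f$sites$genotype == "missing")
  expected <- ppois(9, 30) + ppois(60, 30, lower.tail = FALSE)
  expect_equal(frac, expected, tolerance = 3 * sqrt(expected / n) / expected)
})

test_that("heterozygosity uses the genome-size denominator and quality filters", {
  tr <- make_track(c(5, 10), c("hom_ref", "hom_alt"), len = 1e6)
  expect_equal(heterozygosity(tr)$H, 0)
  sites <- data.frame(scaffold = "s1", pos = seq_len(1000), genotype = "het")
  tr2 <- genotype_track(sites, scaffold_lengths = c(s1 = 1e6))
  h <- heterozygosity(tr2)
  expect_equal(h$H, 1e-3)
  expect_equal(h$n_het_sites, 1000L)
  # low base quality excludes a het call
  tr3 <- make_track(c(1, 2), c("het", "het"), baseq = c(10, 30), len = 100)
  expect_equal(heterozygosity(tr3)$n_het_sites, 1L)
  # low mapping quality likewise
  tr4 <- make_track(c(1, 2), c("het", "het"), mapq = c(10, 60), len = 100)
  expect_equal(heterozygosity(tr4)$n_het_sites, 1L)
  # callable-sites denominator alternative
  expect_equal(heterozygosity(tr4, denominator = "callable")$H, 1)
})

test_that("H is invariant to scaffold order and to splitting a scaffold", {
  sites <- data.frame(scaffold = "s1", pos = c(50, 150, 250),
                      genotype = "het")
  one <- genotype_track(sites, scaffold_lengths = c(s1 = 300))
  two <- genotype_track(data.frame(scaffold = c("a", "b", "b"),
                                   pos = c(50, 50, 150),
                                   genotype = "het"),
                        scaffold_lengths = c(a = 100, b = 200))
  expect_equal(heterozygosity(one)$H, heterozygosity(two)$H)
  swapped <- genotype_track(data.frame(scaffold = c("b", "b", "a"),
                                       pos = c(50, 150, 50),
                                       genotype = "het"),
                            scaffold_lengths = c(b = 200, a = 100))
  expect_equal(heterozygosity(two)$H, heterozygosity(swapped)$H)
})

test_that("binning codes HET, MISSING and HOM per the stated rules", {
  tr <- make_track(150, "het", len = 300)
  bt <- bin_to_psmcfa(tr, 100)
  expect_equal(bt$bins$s1, c(0L, 1L, 0L))  # position 150 -> second bin
  # two het sites in one bin still give one HET bin
  tr2 <- make_track(c(110, 190), c("het", "het"), len = 300)
  expect_equal(bin_to_psmcfa(tr2, 100)$bins$s1, c(0L, 1L, 0L))
  # fully missing bins
  tr3 <- make_track(seq_len(300), rep("missing", 300), len = 300)
  expect_true(all(bin_to_psmcfa(tr3, 100)$bins$s1 == 2L))
  # 90% missing threshold: 91 missing positions flip the bin, 90 do not
  tr4 <- make_track(seq_len(91), rep("missing", 91), len = 100)
  expect_equal(bin_to_psmcfa(tr4, 100)$bins$s1, 2L)
  tr5 <- make_track(seq_len(90), rep("missing", 90), len = 100)
  expect_equal(bin_to_psmcfa(tr5, 100)$bins$s1, 0L)
  expect_error(bin_to_psmcfa(tr, 0), "positive")
})

test_that("psmcfa text round-trips bit-exactly", {
  set.seed(3)
  bins <- list(sc1 = sample(0:2, 137, replace = TRUE, prob = c(.8, .15, .05)),
               sc2 = sample(0:2, 60, replace = TRUE))
  track <- het_bin_track(bins, bin_size_bp = 100)
  path <- tempfile(fileext = ".psmcfa")
  write_psmcfa(track, path)
  lines <- readLines(path)
  expect_true(all(nchar(lines[!grepl("^>", lines)]) <= 60))
  back <- read_psmcfa(path, 100)
  expect_identical(back$bins, track$bins)
  file.remove(path)
})

test_that("the VCF reader classifies genotypes and reads depth", {
  vcf <- c("##fileformat=VCFv4.2",
           "##contig=<ID=s1,length=1000>",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tind1",
           "s1\t10\t.\tA\tG\t50\tPASS\t.\tGT:DP\t0/1:22",
           "s1\t20\t.\tC\tT\t50\tPASS\t.\tGT:DP\t1/1:30",
           "s1\t30\t.\tG\tA\t50\tPASS\t.\tGT:DP\t0/0:28",
           "s1\t40\t.\tT\tC\t50\tPASS\t.\tGT:DP\t./.:0")
  path <- tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  tr <- read_genotype_vcf(path)
  expect_equal(tr$sites$genotype, c("het", "hom_alt", "hom_ref", "missing"))
  expect_equal(tr$sites$depth, c(22L, 30L, 28L, 0L))
  expect_equal(tr$scaffold_lengths, c(s1 = 1000))
  expect_equal(heterozygosity(tr)$H, 1 / 1000)
  file.remove(path)
})

test_that("the TSV genotype dialect round-trips through the reader", {
  tab <- data.frame(scaffold = "s1", pos = c(10, 20, 30),
                    genotype = c("het", "hom_ref", "missing"),
                    depth = c(12L, 30L, 5L))
  path <- tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- read_genotype_tsv(path, scaffold_lengths = c(s1 = 100))
  expect_equal(tr$sites$genotype, tab$genotype)
  expect_equal(tr$sites$depth, tab$depth)
  expect_equal(heterozygosity(tr)$H, 1 / 100)
  file.remove(path)
})

test_that("simulated constant-Ne genome heterozygosity matches 4*Ne*mu", {
  sc <- demography_scenario(data.frame(start_gen = 0, ne = 1e4),
                            1e-8, 1e-8, 2e6, seed = 31)
  sim <- simulate_het_track(sc)
  sites <- data.frame(scaffold = "scaffold_1", pos = sim$het_pos,
                      genotype = "het")
  tr <- genotype_track(sites, scaffold_lengths = c(scaffold_1 = 2e6))
  h <- heterozygosity(tr)
  expect_equal(h$H, 4e-4, tolerance = 0.25)
})
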