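toy_gene <- function(s0 = 1000, e0 = 2000, strand = "+", chrom = "chr1",
                     id = "g1") {
  g <- GRanges(chrom, IRanges(s0 + 1, e0), strand = strand)
  mcols(g)$gene_id <- id
  g
}

test_that("intragenic coverage is the covered fraction of the span", {
  g <- toy_gene()
  expect_equal(unname(intragenic_coverage(g, GRanges())), 0)
  expect_equal(unname(intragenic_coverage(
    g, GRanges("chr1", IRanges(901, 2100)))), 1)
  peaks <- GRanges("chr1", IRanges(c(901, 1501), c(1100, 1600)))
  expect_equal(unname(intragenic_coverage(g, peaks)), 0.20)
  # oracle check on random instances
  set.seed(12)
  for (i in 1:10) {
    p <- random_intervals(sample(1:40, 1), chrom = "chr1")
    expected <- sum(oracle_cover(p, 10000)[1001:2000])
    expect_equal(unname(intragenic_coverage(g, p)), expected / 1000)
  }
})

test_that("coverage is invariant to splitting peaks into abutting pieces", {
  g <- toy_gene()
  set.seed(8)
  peaks <- merge_intervals(random_intervals(30, chrom = "chr1"))
  halves <- unlist(GenomicRanges::GRangesList(lapply(seq_along(peaks),
    function(i) {
      w <- width(peaks)[i]
      if (w < 2) return(peaks[i])
      cut <- start(peaks)[i] + sample.int(w - 1, 1) - 1L
      GRanges("chr1", IRanges(c(start(peaks)[i], cut + 1),
                              c(cut, end(peaks)[i])))
    })))
  expect_equal(intragenic_coverage(g, halves),
               intragenic_coverage(g, peaks))
})

test_that("coverage classes use lower-inclusive boundaries", {
  f <- c(0, 0.0001, 0.19, 0.20, 0.49, 0.50, 0.79, 0.80, 1)
  expect_equal(as.character(coverage_class(f)),
               c("none", "low", "low", "intermediary", "intermediary",
                 "high", "high", "very_high", "very_high"))
  expect_error(coverage_class(1.2))
})

test_that("metagene profiles cover flanks and scaled body bins", {
  sizes <- chrom_sizes(c(chr1 = 100000))
  g <- toy_gene(20000, 28000)
  mg <- metagene(g, GRanges(), sizes)
  expect_equal(nrow(mg), 90)
  expect_true(all(mg$value == 0))

  full <- GRanges("chr1", IRanges(20001, 28000))
  mg <- metagene(g, full, sizes)
  expect_true(all(mg$value[mg$region == "body"] == 1))
  expect_true(all(mg$value[mg$region != "body"] == 0))
})

test_that("minus-strand genes mirror their strand-flipped twins exactly", {
  sizes <- chrom_sizes(c(chr1 = 100000))
  set.seed(14)
  # a plus-strand gene with random peaks around it
  gp <- toy_gene(40000, 52000, strand = "+")
  s0 <- sample(35000:55000, 40)
  w <- sample(100:900, 40, replace = TRUE)
  peaks_p <- GRanges("chr1", IRanges(s0 + 1, s0 + w))
  # mirror the whole configuration through the chromosome midpoint
  L <- 100000
  gm <- toy_gene(L - 52000, L - 40000, strand = "-")
  peaks_m <- GRanges("chr1", IRanges(L - (s0 + w) + 1, L - s0))
  prof_p <- metagene(gp, peaks_p, sizes)
  prof_m <- metagene(gm, peaks_m, sizes)
  expect_equal(prof_m$value, prof_p$value)
  body_p <- gene_body_profiles(gp, peaks_p, sizes)
  body_m <- gene_body_profiles(gm, peaks_m, sizes)
  expect_equal(unname(body_m), unname(body_p))
})

test_that("flank bins truncate at chromosome boundaries", {
  sizes <- chrom_sizes(c(chr1 = 10000))
  g <- toy_gene(1000, 3000)  # upstream flank extends past the origin
  peaks <- GRanges("chr1", IRanges(1, 3000))
  mg <- metagene(g, peaks, sizes, flank_bp = 2500, flank_bins = 25)
  up <- mg$value[mg$region == "upstream"]
  # all surviving upstream bins are fully covered; clipped ones dropped
  expect_true(all(up[!is.nan(up)] == 1))
  expect_true(all(mg$n_genes[mg$region == "upstream"][1:10] %in% c(0, 1)))
})

test_that("enrichment summary decomposes the genome consistently", {
  sizes <- chrom_sizes(c(chr1 = 1000, chr2 = 2000))
  g <- toy_gene(100, 600, chrom = "chr1")
  none <- enrichment_summary(GRanges(), g, sizes)
  expect_equal(none$pct_genome, 0)
  expect_true(all(none$per_chrom$pct_intragenic == 0))

  peaks <- GRanges("chr1", IRanges(1, 100))
  one <- enrichment_summary(peaks, g, sizes)
  expect_equal(one$total_bp, 100)
  expect_equal(one$pct_genome, 100 * 100 / 3000)

  set.seed(19)
  p <- random_intervals(50, chrom = "chr1", len = 1000, max_w = 80)
  es <- enrichment_summary(p, g, sizes)
  cov <- oracle_cover(merge_intervals(p), 1000)
  genic <- oracle_cover(g, 1000)
  row1 <- es$per_chrom[es$per_chrom$chrom == "chr1", ]
  expect_equal(row1$covered_intragenic_bp, sum(cov & genic))
  expect_equal(row1$covered_intergenic_bp, sum(cov & !genic))
  # conservation: covered intragenic + intergenic = merged peak bp
  expect_equal(sum(es$per_chrom$covered_intragenic_bp +
                     es$per_chrom$covered_intergenic_bp), es$total_bp)
  expect_equal(sum(es$per_chrom$intragenic_bp +
                     es$per_chrom$intergenic_bp), sum(as.numeric(sizes)))
})

test_that("group mean coverage matches a naive loop", {
  expect_equal(unname(group_mean_coverage(
    matrix(c(0, 0.5, 1), 3, 1), c("a", "a", "a"))$mean[1, 1]), 0.5)
  set.seed(3)
  m <- matrix(runif(60), 20, 3,
              dimnames = list(paste0("g", 1:20), c("s1", "s2", "s3")))
  lab <- sample(c("x", "y", "z"), 20, replace = TRUE)
  got <- group_mean_coverage(m, lab)
  for (l in unique(lab)) {
    for (s in colnames(m)) {
      expect_equal(got$mean[l, s], mean(m[lab == l, s]))
    }
    expect_equal(unname(got$n[l]), sum(lab == l))
  }
})
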