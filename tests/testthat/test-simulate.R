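small_params <- hmc_sim_params(
  n_genes = 150,
  chrom_lengths = c(chr1 = 2e6, chr2 = 1.5e6, chr3 = 1.2e6,
                    chrX = 1e6, chrY = 4e5))

test_that("the generator is deterministic under a fixed seed", {
  a <- simulate_hmc_study(seed = 5, params = small_params)
  b <- simulate_hmc_study(seed = 5, params = small_params)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth$target, b$truth$target)
  expect_identical(lapply(a$peaks, as.data.frame),
                   lapply(b$peaks, as.data.frame))
  c_ <- simulate_hmc_study(seed = 6, params = small_params)
  expect_false(identical(a$counts, c_$counts))
})

test_that("written annotation round-trips through the GTF reader", {
  st <- simulate_hmc_study(seed = 5, params = small_params)
  dir <- withr::local_tempdir()
  write_synthetic_study(st, dir)
  back <- read_gtf_genes(file.path(dir, "genes.gtf"))
  expect_length(back, 150)
  expect_equal(mcols(back)$gene_id, mcols(st$genes)$gene_id)
  expect_equal(start(back), start(st$genes))
  expect_equal(as.character(strand(back)), as.character(strand(st$genes)))
  expect_equal(mcols(back)$biotype, mcols(st$genes)$biotype)
  # gene lengths respect the clip range
  expect_true(all(width(st$genes) >= 1000 & width(st$genes) <= 100000))
  # peak BED files round-trip
  cs <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  smp <- st$coverage_samples$sample[1]
  p <- read_bed(file.path(dir, "peaks", paste0(smp, ".bed")), cs)
  expect_equal(length(p), length(st$peaks[[smp]]))
})

test_that("realized coverage tracks the planted targets", {
  st <- simulate_hmc_study(seed = 5, params = small_params)
  cov <- gene_coverage_matrix(st$genes, st$peaks)
  tgt <- st$truth$target
  big <- width(st$genes) >= 5000
  expect_lt(max(abs(cov[big, ] - tgt[big, ])), 0.05)
  # zero-target genes (planted class 1, male X analog) get no peaks
  zero <- tgt[, 1] == 0
  expect_true(all(cov[zero, 1] == 0))
  # mean realized peak length is near the 800 bp calibration
  mpl <- mean(unlist(lapply(st$peaks, width)))
  expect_gt(mpl, 750); expect_lt(mpl, 850)
})

test_that("planted structure matches the study design", {
  st <- simulate_hmc_study(seed = 5, params = small_params)
  cm <- st$coverage_samples
  tgt <- st$truth$target
  sex_genes <- as.character(seqnames(st$genes)) %in%
    sex_chromosomes(st$sizes)
  xist <- st$truth$xist_gene
  other_sex <- setdiff(rownames(tgt)[sex_genes], xist)
  expect_true(all(tgt[other_sex, ] == 0))
  expect_true(all(tgt[xist, cm$sex == "F"] > 0))
  expect_true(all(tgt[xist, cm$sex == "M"] == 0))
  # brain coverage exceeds liver on average (planted Beta ordering)
  expect_gt(mean(tgt[, cm$organ == "brain"]),
            mean(tgt[, cm$organ == "liver"]))
})

test_that("a null link slope yields no coverage-expression correlation", {
  st <- simulate_hmc_study(seed = 5, params = modifyList(
    small_params, list(link_b = 0)))
  l2c <- log2_cpm(st$counts, tmm_factors(st$counts))
  em <- st$expression_samples
  ebc <- vapply(st$coverage_samples$sample, function(s)
    rowMeans(l2c[, em$sample[em$coverage_sample == s], drop = FALSE]),
    numeric(nrow(l2c)))
  apc <- autosomal_protein_coding(st$genes, st$sizes)
  nonhk <- setdiff(apc, st$truth$sets$housekeeping)
  rho <- cor(as.vector(st$truth$target[nonhk, ]),
             as.vector(ebc[nonhk, ]), method = "spearman")
  expect_lt(abs(rho), 0.1)
})

test_that("fragment simulation conserves counts and matches rates", {
  sizes <- chrom_sizes(c(chr1 = 1e6))
  isl <- GRanges("chr1", IRanges(100001, 102000))
  fr <- simulate_fragments(isl, sizes, n_control = 5000, fold = 1,
                           seed = 17)
  expect_length(fr$ctrl, 5000)
  expect_length(fr$treat, 5000)  # fold 1 adds nothing
  # fold 1: treatment rate inside the island matches control within 5%
  # of the total (both are a tiny uniform share of 5000)
  fr10 <- simulate_fragments(isl, sizes, n_control = 5000, fold = 10,
                             seed = 18)
  in_isl <- sum(countOverlaps(fr10$treat, isl) > 0)
  expect_gt(in_isl, 5 * sum(countOverlaps(fr10$ctrl, isl) > 0))
})

test_that("similarity block structure separates brain from liver", {
  st <- small_study()
  cov <- gene_coverage_matrix(st$genes, st$peaks)
  sim <- sample_similarity(cov)
  diag(sim) <- NA
  cm <- st$coverage_samples
  b <- cm$sample[cm$organ == "brain"]
  l <- cm$sample[cm$organ == "liver"]
  expect_gt(min(sim[b, b], na.rm = TRUE), max(sim[b, l]))
  # thalamus and hypothalamus are the closest brain pair on average
  thhy <- mean(sim[cm$sample[cm$region == "thalamus"],
                   cm$sample[cm$region == "hypothalamus"]])
  cbcx <- mean(sim[cm$sample[cm$region == "cerebellum"],
                   cm$sample[cm$region == "cortex"]])
  expect_gt(thhy, cbcx)
})
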