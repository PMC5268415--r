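params <- caller_params()

test_that("redundant fragments are capped at the redundancy threshold", {
  frag <- GRanges("chr1", IRanges(101, 300), strand = "+")
  three <- c(frag, frag, frag)
  expect_length(deduplicate_fragments(three, 1), 1)

  set.seed(3)
  distinct <- random_intervals(40)
  expect_length(deduplicate_fragments(distinct, 1), 40)

  a <- GRanges("chr1", IRanges(1, 200), strand = "+")
  b <- GRanges("chr1", IRanges(501, 700), strand = "-")
  mixed <- c(a, rep(b, 4))
  out <- deduplicate_fragments(mixed, 2)
  expect_length(out, 3)
  expect_equal(sum(start(out) == 501), 2)
})

test_that("window counting shifts reads by half the fragment size", {
  sizes <- chrom_sizes(c(chr1 = 1000))
  empty <- GRanges()
  expect_equal(count_windows(empty, params, sizes)$chr1, rep(0L, 10))

  # plus-strand read starting at 0-based 0: point 100 -> window [100,200)
  rd <- GRanges("chr1", IRanges(1, 100), strand = "+")
  cw <- count_windows(rd, params, sizes)$chr1
  expect_equal(which(cw == 1), 2L)

  # minus-strand read ending at 0-based 1000 clips into the last window
  rd <- GRanges("chr1", IRanges(901, 1000), strand = "-")
  cw <- count_windows(rd, params, sizes)$chr1
  expect_equal(which(cw == 1), 9L)  # point 999-100=899 -> window [800,900)

  set.seed(5)
  sizes <- chrom_sizes(c(chr1 = 50000, chr2 = 30000))
  ch <- sample(c("chr1", "chr2"), 1000, replace = TRUE)
  s0 <- sample.int(45000, 1000, replace = TRUE) - 1L
  fr <- GRanges(ch, IRanges(s0 + 1L, s0 + 200L),
                strand = sample(c("+", "-"), 1000, replace = TRUE))
  cw <- count_windows(fr, params, sizes)
  expect_equal(sum(unlist(cw)), 1000)
  expect_error(count_windows(GRanges("chrZ", IRanges(1, 200)), params,
                             sizes), "chrZ")
})

test_that("eligibility threshold matches Poisson tail summation", {
  expect_equal(eligible_threshold(1, 0.2), 3L)
  expect_equal(eligible_threshold(1, 0.9999), 1L)
  brute <- function(lambda, p0) {
    pmf <- dpois(0:200, lambda)
    for (l0 in 1:200) if (sum(pmf[(l0 + 1):201]) < p0) return(l0)
  }
  for (lambda in c(0.25, 0.5, 2, 5)) {
    for (p0 in c(0.2, 0.05, 0.01)) {
      expect_equal(eligible_threshold(lambda, p0), brute(lambda, p0))
    }
  }
})

test_that("island formation joins eligible windows across allowed gaps", {
  p <- caller_params(window_w = 100, gap_g = 100)
  empty <- form_islands(rep(0L, 20), "chr1", 2L, p, 0.5)
  expect_equal(nrow(empty), 0)

  counts <- rep(0L, 10)
  counts[c(1, 2, 6)] <- 5L  # eligible windows 0,1 and 5; gap 1 window
  isl <- form_islands(counts, "chr1", 2L, p, 0.5)
  expect_equal(nrow(isl), 2)
  expect_equal(isl$start_win, c(0L, 5L))
  expect_equal(isl$end_win, c(1L, 5L))

  # random track vs a brute-force scan over eligible runs
  set.seed(9)
  for (gap_w in c(1L, 2L)) {
    p <- caller_params(window_w = 100, gap_g = 100L * gap_w)
    counts <- rpois(500, 0.8)
    l0 <- 3L
    isl <- form_islands(counts, "chr1", l0, p, 0.8)
    elig <- which(counts >= l0) - 1L
    # brute force: walk eligible windows, break on gap > gap_w
    runs <- list()
    cur <- elig[1]
    lo <- elig[1]
    for (e in elig[-1]) {
      if (e - cur - 1L > gap_w) {
        runs[[length(runs) + 1L]] <- c(lo, cur)
        lo <- e
      }
      cur <- e
    }
    runs[[length(runs) + 1L]] <- c(lo, cur)
    expect_equal(isl$start_win, vapply(runs, `[`, numeric(1), 1))
    expect_equal(isl$end_win, vapply(runs, `[`, numeric(1), 2))
    # score equals the summed -log pmf over eligible windows
    expect_equal(sum(isl$score),
                 sum(-dpois(counts[elig + 1L], 0.8, log = TRUE)))
  }
})

test_that("island q-values follow the Benjamini-Hochberg rule", {
  isl <- data.frame(chrom = "chr1", start_win = c(0, 10, 20, 30),
                    end_win = c(0, 10, 20, 30), score = 1)
  counts <- list(chr1 = rep(5L, 40))
  ctrl <- list(chr1 = rep(0L, 40))
  out <- score_islands_vs_control(isl, counts, ctrl, 100, 100,
                                  params, 0.5)
  expect_equal(out$q_value, oracle_bh(out$p_value))
  # hand case: p = .01,.02,.03,.04 all adjust to .04
  expect_equal(oracle_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  empty <- score_islands_vs_control(isl[0, ], counts, ctrl, 100, 100,
                                    params, 0.5)
  expect_equal(nrow(empty), 0)
})

test_that("a planted strong island is recovered cleanly", {
  sizes <- chrom_sizes(c(chr1 = 1e6))
  planted <- GRanges("chr1", IRanges(500001, 502000))
  fr <- simulate_fragments(planted, sizes, n_control = 20000, fold = 10,
                           seed = 21)
  res <- call_islands(fr$treat, fr$ctrl, sizes)
  hits <- findOverlaps(planted, res$islands)
  expect_equal(length(unique(S4Vectors::subjectHits(hits))), 1)
  isl <- res$islands[S4Vectors::subjectHits(hits)[1]]
  expect_gte(overlap_length(isl, planted) / width(planted), 0.9)
  # null counts at background expectation are not retained
  null_cand <- res$candidates
  at_bg <- null_cand$treat_count <= res$lambda_bg *
    (null_cand$end_win - null_cand$start_win + 1)
  expect_true(all(null_cand$q_value[at_bg] >= params$fdr_q))
})

test_that("island calls behave monotonically in fdr and gap", {
  sizes <- chrom_sizes(c(chr1 = 1e6))
  planted <- GRanges("chr1", IRanges(c(200001, 700001), width = 2000))
  fr <- simulate_fragments(planted, sizes, n_control = 15000, fold = 6,
                           seed = 33)
  loose <- call_islands(fr$treat, fr$ctrl, sizes,
                        caller_params(fdr_q = 0.05))
  strict <- call_islands(fr$treat, fr$ctrl, sizes,
                         caller_params(fdr_q = 0.001))
  expect_true(all(countOverlaps(strict$islands, loose$islands,
                                type = "equal") > 0))
  g100 <- call_islands(fr$treat, fr$ctrl, sizes,
                       caller_params(gap_g = 100))
  g200 <- call_islands(fr$treat, fr$ctrl, sizes,
                       caller_params(gap_g = 200))
  expect_lte(length(g200$candidates$chrom), length(g100$candidates$chrom))
  # retained islands never overlap each other
  for (res in list(loose, strict, g100, g200)) {
    if (length(res$islands) > 1) {
      expect_true(all(countOverlaps(res$islands, res$islands) == 1))
    }
  }
})
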