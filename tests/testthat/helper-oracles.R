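suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# Per-base boolean oracle on a single toy chromosome: which 0-based
# positions of [0, len) are covered by the given intervals.
oracle_cover <- function(gr, len) {
  covered <- logical(len)
  for (i in seq_along(gr)) {
    s <- start(gr)[i] - 1L  # to 0-based
    e <- end(gr)[i]
    covered[seq.int(s + 1L, e)] <- TRUE
  }
  covered
}

# Random interval set on a toy chromosome.
random_intervals <- function(n, chrom = "toy", len = 10000L,
                             max_w = 400L) {
  s0 <- sample.int(len - max_w, n, replace = TRUE) - 1L
  w <- sample.int(max_w, n, replace = TRUE)
  GRanges(chrom, IRanges(s0 + 1L, s0 + w))
}

# Exhaustive-enumeration oracle for the two-sided rank-sum p-value
# (distinct values assumed; all choose(n1+n2, n1) group assignments).
oracle_wilcox_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  w_all <- apply(combs, 2, function(idx)
    sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_lo <- mean(w_all <= w_obs)
  p_hi <- mean(w_all >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Straightforward reference for the Benjamini-Hochberg adjustment.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Small synthetic study shared across test files (cached per session).
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_hmc_study(
        seed = 11,
        params = hmc_sim_params(
          n_genes = 250,
          chrom_lengths = c(chr1 = 3e6, chr2 = 2.5e6, chr3 = 2e6,
                            chrX = 1.5e6, chrY = 5e5)))
    }
    cache
  }
})
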