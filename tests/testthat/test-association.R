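test_that("sample similarity is Spearman correlation of coverage", {
  set.seed(20)
  cov <- matrix(runif(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  sim <- sample_similarity(cov)
  expect_equal(diag(sim), c(a = 1, b = 1, c = 1))
  expect_equal(sim, t(sim))
  # definition oracle: rank transform then Pearson
  oracle <- cor(apply(cov, 2, rank))
  expect_equal(unname(sim), unname(oracle), tolerance = 1e-12)
  # reversed ranks give -1; duplicated columns give off-diagonal 1
  rev2 <- cbind(a = 1:20, b = 20:1)
  expect_equal(sample_similarity(rev2)["a", "b"], -1)
  dup <- cbind(x = cov[, 1], y = cov[, 1], z = cov[, 2])
  expect_equal(sample_similarity(dup)["x", "y"], 1)
})

test_that("rank-sum tests match exhaustive enumeration for small n", {
  res <- marked_vs_unmarked_test(c(1, 2, 3, 4, 5, 6),
                                 c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  # one-sided exact p for complete separation of 3 vs 3 is 1/20
  expect_equal(res$p_value, 2 * 0.05)
  expect_equal(res$statistic, 0)  # marked group holds the lowest ranks

  set.seed(30)
  for (rep in 1:12) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    vals <- sample(seq_len(40), n1 + n2)  # distinct, tie-free
    marked <- c(rep(TRUE, n1), rep(FALSE, n2))
    got <- marked_vs_unmarked_test(vals, marked)$p_value
    expect_equal(got, oracle_wilcox_p(vals[marked], vals[!marked]))
  }
  # identical groups are a null case
  same <- marked_vs_unmarked_test(rep(c(1, 2, 3), 2),
                                  rep(c(TRUE, FALSE), each = 3))
  expect_gte(same$p_value, 0.99)
  # a group with <2 members is reported untestable
  tiny <- marked_vs_unmarked_test(1:4, c(TRUE, FALSE, FALSE, FALSE))
  expect_false(tiny$testable)
})

test_that("gene clustering recovers planted groups ordered by coverage", {
  # separable case: two point masses
  prof <- rbind(matrix(0.1, 5, 8), matrix(0.9, 5, 8))
  rownames(prof) <- paste0("g", 1:10)
  cl <- cluster_genes(prof, k = 2)
  expect_equal(as.character(cl$cluster),
               rep(c("C1", "C2"), each = 5))

  set.seed(41)
  means <- c(0.0, 0.2, 0.4, 0.7, 0.95)
  prof <- do.call(rbind, lapply(means, function(m)
    matrix(pmin(pmax(m + rnorm(40 * 20, 0, 0.03), 0), 1), 20, 40)))
  rownames(prof) <- paste0("g", seq_len(nrow(prof)))
  truth <- rep(paste0("C", 1:5), each = 20)
  cl <- cluster_genes(prof, k = 5)
  expect_gte(mean(as.character(cl$cluster) == truth), 0.95)
  expect_true(all(diff(cl$mean_coverage) > 0))
  # determinism
  cl2 <- cluster_genes(prof, k = 5)
  expect_identical(cl$cluster, cl2$cluster)
  expect_error(cluster_genes(prof[1:3, ], k = 5), "k exceeds")
})

test_that("cluster expression summaries expose the monotone trend", {
  cl <- factor(rep(paste0("C", 1:5), each = 10),
               levels = paste0("C", 1:5))
  names(cl) <- paste0("g", 1:50)
  flat <- matrix(1, 50, 2, dimnames = list(names(cl), c("s1", "s2")))
  expect_equal(cluster_expression_summary(cl, flat)$trend_rho, 0)
  linked <- matrix(rep(as.integer(cl), 2), 50, 2,
                   dimnames = dimnames(flat))
  res <- cluster_expression_summary(cl, linked)
  expect_equal(res$trend_rho, 1)
  expect_equal(res$summary$median[res$summary$cluster == "C3"],
               c(3, 3))
})

test_that("set membership reproduces reported percentage arithmetic", {
  cl <- factor(c(rep("C1", 150), rep("C2", 144), rep("C3", 246)),
               levels = paste0("C", 1:5))
  names(cl) <- paste0("g", seq_along(cl))
  # 294 of 540 in C1+C2
  res <- set_membership(cl, names(cl), c("C1", "C2"))
  expect_equal(res$count, 294)
  expect_equal(res$percentage, 54)
  empty <- set_membership(cl, character(0), c("C1", "C2"))
  expect_equal(empty$count, 0)
  expect_equal(empty$percentage, 0)
  # percentages over a partition sum to 100 up to rounding
  p <- vapply(paste0("C", 1:5), function(k)
    set_membership(cl, names(cl), k)$percentage, numeric(1))
  expect_lte(abs(sum(p) - 100), length(p) / 2)
})

test_that("one- and two-way ANOVA follow the standard decomposition", {
  x <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- group_anova(x, g)
  expect_equal(res$F, 3.0)
  # two groups: F equals the squared pooled-variance t statistic
  x2 <- c(1.2, 2.1, 0.7, 3.3, 2.8, 4.1)
  g2 <- rep(c("a", "b"), each = 3)
  tt <- t.test(x2[g2 == "a"], x2[g2 == "b"], var.equal = TRUE)
  expect_equal(group_anova(x2, g2)$F, unname(tt$statistic)^2)

  # balanced two-way toy: cell means recovered, Tukey flags match CIs
  set.seed(55)
  d <- expand.grid(f1 = c("lo", "hi"), f2 = c("p", "q"),
                   rep = 1:4)
  d$y <- 2 + (d$f1 == "hi") * 1.5 + (d$f2 == "q") * 0.5 + rnorm(16, 0, 0.2)
  res2 <- group_anova2(d$y, d$f1, d$f2)
  expect_equal(res2$tukey$significant,
               res2$tukey$lwr > 0 | res2$tukey$upr < 0)
  f1_effect <- mean(d$y[d$f1 == "hi"]) - mean(d$y[d$f1 == "lo"])
  ss_f1 <- 8 * 2 * (f1_effect / 2)^2
  expect_equal(res2$anova[["Sum Sq"]][1], ss_f1, tolerance = 1e-8)
})

test_that("Welch t-test matches the textbook formula and guards zeros", {
  same <- group_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  degen <- group_ttest(c(0, 0, 0, 0), c(1, 1, 1, 1))
  expect_true(degen$degenerate)
  expect_lt(degen$p_value, 1e-12)

  set.seed(60)
  for (rep in 1:8) {
    x <- rnorm(sample(3:9, 1)); y <- rnorm(sample(3:9, 1), 0.5, 2)
    got <- group_ttest(x, y)
    se <- sqrt(var(x) / length(x) + var(y) / length(y))
    tstat <- (mean(x) - mean(y)) / se
    df <- se^4 / ((var(x) / length(x))^2 / (length(x) - 1) +
                    (var(y) / length(y))^2 / (length(y) - 1))
    expect_equal(got$t, tstat, tolerance = 1e-10)
    expect_equal(got$df, df, tolerance = 1e-10)
    expect_equal(got$p_value, 2 * pt(-abs(tstat), df), tolerance = 1e-10)
  }
})
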