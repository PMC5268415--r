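#' Sample-by-sample Spearman similarity of intragenic coverage
#'
#' Pairwise Spearman rank correlation (mid-rank ties) of the per-gene
#' coverage vectors, the study's measure of epigenetic similarity between
#' samples.
#'
#' @param coverage genes x samples coverage matrix
#' @return symmetric samples x samples correlation matrix, unit diagonal
#' @export
sample_similarity <- function(coverage) {
  stopifnot(ncol(coverage) >= 2, nrow(coverage) >= 3)
  stats::cor(coverage, method = "spearman")
}

#' Wilcoxon rank-sum comparison of marked vs unmarked genes
#'
#' Two-sided rank-sum test of expression between genes with and without
#' intragenic 5hmC enrichment, run separately per stratum (gene biotype
#' or molecule type). Exact p when the combined sample is small
#' (n1 + n2 <= `exact_max`) and tie-free; otherwise the normal
#' approximation with continuity and tie correction. Strata in which
#' either group has fewer than 2 members are reported untestable.
#'
#' @param values numeric expression values (e.g. log2 CPM), one per gene
#' @param marked logical, gene has intragenic enrichment
#' @param strata character/factor stratum per gene (a single stratum is
#'   fine)
#' @param exact_max largest n1 + n2 for the exact null distribution
#' @return data.frame: stratum, n_marked, n_unmarked, statistic (rank-sum
#'   W of the marked group), p_value, testable
#' @export
marked_vs_unmarked_test <- function(values, marked,
                                    strata = rep("all", length(values)),
                                    exact_max = 12L) {
  stopifnot(length(marked) == length(values),
            length(strata) == length(values))
  out <- lapply(split(seq_along(values), strata), function(idx) {
    x <- values[idx][marked[idx]]
    y <- values[idx][!marked[idx]]
    if (length(x) < 2 || length(y) < 2) {
      return(data.frame(n_marked = length(x), n_unmarked = length(y),
                        statistic = NA_real_, p_value = NA_real_,
                        testable = FALSE))
    }
    ties <- anyDuplicated(c(x, y)) > 0
    wt <- suppressWarnings(stats::wilcox.test(
      x, y, alternative = "two.sided",
      exact = (length(x) + length(y)) <= exact_max && !ties,
      correct = TRUE))
    data.frame(n_marked = length(x), n_unmarked = length(y),
               statistic = unname(wt$statistic), p_value = wt$p.value,
               testable = TRUE)
  })
  res <- do.call(rbind, out)
  res$stratum <- names(out)
  rownames(res) <- NULL
  res[, c("stratum", "n_marked", "n_unmarked", "statistic", "p_value",
          "testable")]
}

#' Cluster genes by gene-body enrichment pattern
#'
#' Agglomerative hierarchical clustering (Euclidean distance, Ward
#' linkage, `ward.D2`) of per-gene body-bin coverage profiles, cut at `k`
#' clusters. Clusters are relabelled C1..Ck by strictly increasing mean
#' coverage, matching the convention that C1 is least and Ck most
#' enriched. Deterministic for a fixed input.
#'
#' @param profiles genes x bins numeric matrix (see
#'   [gene_body_profiles()]); rownames are gene ids
#' @param k number of clusters
#' @param linkage hclust method: "ward.D2", "complete" or "average"
#' @return list with `cluster` (factor C1..Ck per gene, named by gene),
#'   `sizes`, `mean_coverage` (per cluster), `mean_profile` (k x bins),
#'   `hclust` (the tree)
#' @export
cluster_genes <- function(profiles, k = 5L,
                          linkage = c("ward.D2", "complete", "average")) {
  linkage <- match.arg(linkage)
  profiles <- as.matrix(profiles)
  if (k > nrow(profiles)) stop("k exceeds the number of genes")
  hc <- stats::hclust(stats::dist(profiles, method = "euclidean"),
                      method = linkage)
  raw <- stats::cutree(hc, k = k)
  mean_cov <- tapply(rowMeans(profiles), raw, mean)
  ord <- order(mean_cov)  # ascending coverage -> C1..Ck
  relabel <- stats::setNames(seq_len(k), names(mean_cov)[ord])
  lab <- factor(paste0("C", relabel[as.character(raw)]),
                levels = paste0("C", seq_len(k)))
  names(lab) <- rownames(profiles)
  mean_profile <- do.call(rbind, lapply(levels(lab), function(cl)
    colMeans(profiles[lab == cl, , drop = FALSE])))
  rownames(mean_profile) <- levels(lab)
  list(cluster = lab,
       sizes = table(lab),
       mean_coverage = tapply(rowMeans(profiles), lab, mean),
       mean_profile = mean_profile,
       hclust = hc)
}

#' Expression summaries per enrichment cluster
#'
#' Median and IQR of expression per cluster and sample, plus the Spearman
#' correlation between cluster index (1..k) and per-gene expression as a
#' monotone-trend statistic.
#'
#' @param cluster factor of cluster labels per gene (names = gene ids)
#' @param log2cpm genes x samples expression matrix containing every
#'   clustered gene
#' @return list with `summary` (data.frame cluster x sample: median, q25,
#'   q75, n) and `trend_rho` (Spearman of cluster index vs mean log2 CPM
#'   per gene)
#' @export
cluster_expression_summary <- function(cluster, log2cpm) {
  genes <- names(cluster)
  stopifnot(!is.null(genes), all(genes %in% rownames(log2cpm)))
  expr <- log2cpm[genes, , drop = FALSE]
  rows <- list()
  for (cl in levels(cluster)) {
    e <- expr[cluster == cl, , drop = FALSE]
    for (s in colnames(expr)) {
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, sample = s,
        median = stats::median(e[, s]),
        q25 = stats::quantile(e[, s], 0.25, names = FALSE),
        q75 = stats::quantile(e[, s], 0.75, names = FALSE),
        n = nrow(e))
    }
  }
  gene_means <- rowMeans(expr)
  trend <- if (stats::sd(gene_means) == 0) 0 else
    stats::cor(as.integer(cluster), gene_means, method = "spearman")
  list(summary = do.call(rbind, rows), trend_rho = trend)
}

#' Gene-set membership in a cluster subset
#'
#' How many members of a named gene set fall in the given clusters, with
#' the percentage rounded half away from zero to the nearest integer (the
#' reporting convention for e.g. "294 of 540 (54%)").
#'
#' @param cluster factor of cluster labels, named by gene id
#' @param gene_set character vector of gene ids
#' @param clusters cluster labels of interest, e.g. `c("C1", "C2")`
#' @return list with `count`, `size`, `percentage`
#' @export
set_membership <- function(cluster, gene_set, clusters) {
  inset <- gene_set[gene_set %in% names(cluster)]
  count <- sum(cluster[inset] %in% clusters)
  size <- length(gene_set)
  pct <- if (size == 0) 0 else floor(100 * count / size + 0.5)
  list(count = count, size = size, percentage = pct)
}

#' One-way ANOVA across groups
#'
#' @param values numeric observations
#' @param group factor of group labels
#' @return list with `F`, `p_value`, `df`, and the `aov` fit
#' @export
group_anova <- function(values, group) {
  group <- factor(group)
  stopifnot(nlevels(group) >= 2, all(table(group) >= 2))
  fit <- stats::aov(values ~ group)
  tab <- summary(fit)[[1]]
  list(F = tab$`F value`[1], p_value = tab$`Pr(>F)`[1],
       df = tab$Df, fit = fit)
}

#' Two-way ANOVA with Tukey HSD post hoc
#'
#' Crossed two-factor ANOVA with interaction, followed by Tukey honest
#' significant difference intervals on the interaction cells; pairs whose
#' interval excludes zero are flagged significant.
#'
#' @param values numeric observations
#' @param f1,f2 the two factors
#' @return list with `anova` (the summary table as data.frame) and
#'   `tukey` (data.frame: pair, diff, lwr, upr, p_adj, significant)
#' @export
group_anova2 <- function(values, f1, f2) {
  f1 <- factor(f1); f2 <- factor(f2)
  fit <- stats::aov(values ~ f1 * f2)
  tk <- stats::TukeyHSD(fit, "f1:f2")[[1]]
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"],
                      significant = tk[, "lwr"] > 0 | tk[, "upr"] < 0,
                      row.names = NULL)
  list(anova = as.data.frame(summary(fit)[[1]]), tukey = tukey, fit = fit)
}

#' Welch two-sample t-test with a degenerate-variance guard
#'
#' Two-sided Welch test. When both groups have (numerically) zero
#' variance the statistic is undefined: equal means report t = 0, p = 1;
#' unequal means report p < 1e-12 with the `degenerate` flag set.
#'
#' @param x,y numeric groups, each of length >= 2
#' @param eps variance below which a group is treated as constant
#' @return list with `t`, `p_value`, `df`, `degenerate`
#' @export
group_ttest <- function(x, y, eps = 1e-12) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::var(x) < eps && stats::var(y) < eps) {
    if (abs(mean(x) - mean(y)) < eps) {
      return(list(t = 0, p_value = 1, df = NA_real_, degenerate = TRUE))
    }
    return(list(t = sign(mean(x) - mean(y)) * Inf, p_value = 1e-13,
                df = NA_real_, degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), degenerate = FALSE)
}
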