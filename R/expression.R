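#' Trimmed mean of M-values normalisation factors
#'
#' Between-sample scaling factors for count libraries. The reference is
#' the sample whose 75th-percentile count fraction is closest to the mean
#' of those fractions. For each sample, per-gene log2 ratios (M) and
#' average log2 abundances (A) against the reference are computed over
#' genes nonzero in both; the 30% most extreme M and 5% most extreme A are
#' trimmed; the factor is 2 to the precision-weighted mean of the retained
#' M values. Factors are rescaled to geometric mean 1.
#'
#' @param counts non-negative integer matrix, genes x samples
#' @param logratio_trim,abundance_trim two-sided trim fractions for M and A
#' @return numeric vector of per-sample factors, geometric mean 1
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, abundance_trim = 0.05) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) >= 2, all(counts >= 0))
  lib <- colSums(counts)
  stopifnot(all(lib > 0))
  f75 <- vapply(seq_len(ncol(counts)), function(j)
    stats::quantile(counts[, j], 0.75, names = FALSE) / lib[j], numeric(1))
  ref <- which.min(abs(f75 - mean(f75)))
  factors <- vapply(seq_len(ncol(counts)), function(j) {
    .tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref],
              logratio_trim, abundance_trim,
              sample_name = colnames(counts)[j])
  }, numeric(1))
  factors <- factors / exp(mean(log(factors)))
  stats::setNames(factors, colnames(counts))
}

.tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim,
                      abundance_trim, sample_name = NULL) {
  logR <- log2((obs / n_obs) / (ref / n_ref))
  absE <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  # asymptotic binomial variance of M, the precision weight denominator
  v <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
  fin <- is.finite(logR) & is.finite(absE)
  if (!any(fin)) {
    stop("sample ", if (is.null(sample_name)) "?" else sample_name,
         " shares no nonzero genes with the TMM reference")
  }
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1
  hiL <- n + 1 - loL
  loS <- floor(n * abundance_trim) + 1
  hiS <- n + 1 - loS
  keep <- rank(logR) >= loL & rank(logR) <= hiL &
          rank(absE) >= loS & rank(absE) <= hiS
  f <- sum(logR[keep] / v[keep]) / sum(1 / v[keep])
  if (!is.finite(f)) f <- 0
  2^f
}

#' log2 counts-per-million
#'
#' `log2((count + prior) / (libsize * factor + 2 * prior) * 1e6)`, the
#' prior keeping zero counts finite.
#'
#' @param counts genes x samples count matrix
#' @param factors per-sample normalisation factors (default all 1; use
#'   [tmm_factors()] output for TMM-normalised CPM)
#' @param prior prior count added to the numerator
#' @return matrix of log2 CPM values, same dimensions as `counts`
#' @export
log2_cpm <- function(counts, factors = NULL, prior = 0.5) {
  counts <- as.matrix(counts)
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  stopifnot(length(factors) == ncol(counts), all(factors > 0))
  eff <- colSums(counts) * factors
  log2(sweep(counts + prior, 2, eff + 2 * prior, "/") * 1e6)
}

#' Binary expression status at per-sample and per-group level
#'
#' A gene is "expressed" at `tau_on` and "moderate-high" at `tau_mod`
#' (log2 CPM of 2.5 or more, inclusive). Group-level flags follow the
#' ALL-replicates rule: set only when every sample of the group passes
#' (`rule = "any"` relaxes this to at least one).
#'
#' @param log2cpm matrix from [log2_cpm()]
#' @param groups optional factor/character of group labels per sample
#' @param tau_on log2 CPM threshold for "expressed"
#' @param tau_mod log2 CPM threshold for "moderately to highly expressed"
#' @param rule "all" (default) or "any" replicate rule for group flags
#' @return list with logical matrices `expressed`, `moderate_high`
#'   (genes x samples) and, when `groups` is given, `group_expressed`,
#'   `group_moderate_high` (genes x groups)
#' @export
expression_status <- function(log2cpm, groups = NULL, tau_on = 0,
                              tau_mod = 2.5, rule = c("all", "any")) {
  rule <- match.arg(rule)
  stopifnot(is.finite(tau_on), is.finite(tau_mod))
  expressed <- log2cpm >= tau_on
  moderate <- log2cpm >= tau_mod
  out <- list(expressed = expressed, moderate_high = moderate,
              tau_on = tau_on, tau_mod = tau_mod)
  if (!is.null(groups)) {
    stopifnot(length(groups) == ncol(log2cpm))
    agg <- function(m) {
      do.call(cbind, lapply(split(seq_along(groups), groups), function(j) {
        if (rule == "all") rowSums(!m[, j, drop = FALSE]) == 0
        else rowSums(m[, j, drop = FALSE]) > 0
      }))
    }
    out$group_expressed <- agg(expressed)
    out$group_moderate_high <- agg(moderate)
  }
  out
}
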