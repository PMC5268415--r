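#' Analysis configuration
#'
#' Thresholds and tuning knobs shared by the pipeline stages, with the
#' defaults used throughout: moderate-high expression at log2 CPM 2.5
#' (inclusive), expressed-at-all at 0, organ-specific off-threshold 0,
#' sex-specific minimum coverage 0.1, exception-class coverage threshold
#' 0 (any overlap), five clusters under Ward linkage, 2.5 kb metagene
#' flanks in 25 bins with 40 body bins.
#'
#' @param ... overrides of any default field
#' @return a named list of class `hmc_config`
#' @export
hmc_config <- function(...) {
  cfg <- list(tau_mod = 2.5, tau_on = 0, tau_off = 0, tau_cov_sex = 0.1,
              tau_cov_exception = 0, cluster_k = 5L,
              cluster_linkage = "ward.D2", metagene_flank_bp = 2500L,
              metagene_body_bins = 40L, metagene_flank_bins = 25L,
              cpm_prior = 0.5, seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    warning("unknown config key(s) ignored: ",
            paste(unknown, collapse = ", "))
    over <- over[names(over) %in% names(cfg)]
  }
  cfg[names(over)] <- over
  structure(cfg, class = "hmc_config")
}

#' Write a configuration as a flat key=value file
#' @param cfg [hmc_config()]
#' @param path output path
#' @export
write_hmc_config <- function(cfg, path) {
  writeLines(sprintf("%s = %s", names(cfg),
                     vapply(cfg, function(x) as.character(x),
                            character(1))), path)
  invisible(path)
}

#' Read a flat key=value configuration file
#'
#' Unknown keys warn; missing keys take their documented defaults.
#'
#' @param path config file path
#' @return [hmc_config()] list
#' @export
read_hmc_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- lapply(kv, function(x) {
    v <- x[2]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(vals) <- vapply(kv, `[`, character(1), 1)
  do.call(hmc_config, vals)
}

stage_tsv <- function(df, path, stage, seed) {
  con <- file(path, "w")
  writeLines(sprintf("# hmcscan stage=%s seed=%s", stage, seed), con)
  suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  close(con)
}

#' Run the full downstream analysis
#'
#' Executes coverage, enrichment summaries, metagene, expression,
#' similarity, clustering, marked-vs-unmarked tests and specificity over
#' one study (typically [simulate_hmc_study()] output or equivalently
#' loaded real inputs), optionally writing every stage table plus a run
#' manifest under `out_dir`. Deterministic for fixed inputs.
#'
#' @param genes gene `GRanges`
#' @param sizes `chrom_sizes()` vector
#' @param peaks named list of per-sample peak `GRanges`
#' @param counts genes x expression-samples count matrix
#' @param coverage_meta data.frame (sample, organ, region, sex) for the
#'   peak samples
#' @param expr_meta data.frame (sample, organ, region, sex, replicate,
#'   coverage_sample) for the count columns
#' @param config [hmc_config()]
#' @param out_dir optional output directory for stage TSVs
#' @return named list of stage results (coverage, summaries, metagene,
#'   log2cpm, similarity, clustering, cluster_expression, marked_tests,
#'   specificity, report, manifest)
#' @export
run_hmc_pipeline <- function(genes, sizes, peaks, counts, coverage_meta,
                             expr_meta, config = hmc_config(),
                             out_dir = NULL) {
  stopifnot(all(coverage_meta$sample %in% names(peaks)),
            all(expr_meta$sample %in% colnames(counts)),
            all(expr_meta$coverage_sample %in% coverage_meta$sample))
  manifest <- list()
  tick <- function(stage, nrows) {
    manifest[[length(manifest) + 1L]] <<-
      data.frame(stage = stage, rows = nrows, time = Sys.time())
  }
  res <- list()

  cov <- gene_coverage_matrix(genes, peaks[coverage_meta$sample])
  res$coverage <- cov
  tick("coverage", nrow(cov))

  res$summaries <- lapply(coverage_meta$sample, function(s)
    enrichment_summary(peaks[[s]], genes, sizes))
  names(res$summaries) <- coverage_meta$sample
  tick("summary", length(res$summaries))

  stranded <- genes[as.character(strand(genes)) %in% c("+", "-")]
  res$metagene <- lapply(coverage_meta$sample, function(s)
    metagene(stranded, peaks[[s]], sizes,
             flank_bp = config$metagene_flank_bp,
             body_bins = config$metagene_body_bins,
             flank_bins = config$metagene_flank_bins))
  names(res$metagene) <- coverage_meta$sample
  tick("metagene", nrow(res$metagene[[1]]))

  factors <- tmm_factors(counts)
  l2c <- log2_cpm(counts, factors, prior = config$cpm_prior)
  res$tmm_factors <- factors
  res$log2cpm <- l2c
  tick("expression", nrow(l2c))

  res$similarity <- sample_similarity(cov)
  tick("similarity", nrow(res$similarity))

  # expression per coverage sample = mean log2 CPM over its replicates
  expr_by_cov <- vapply(coverage_meta$sample, function(s) {
    cols <- expr_meta$sample[expr_meta$coverage_sample == s]
    rowMeans(l2c[, cols, drop = FALSE])
  }, numeric(nrow(l2c)))
  res$expr_by_coverage_sample <- expr_by_cov

  apc <- autosomal_protein_coding(genes, sizes)
  brain_samples <- coverage_meta$sample[coverage_meta$organ == "brain"]
  prof <- Reduce(`+`, lapply(brain_samples, function(s)
    gene_body_profiles(genes[mcols(genes)$gene_id %in% apc],
                       peaks[[s]], sizes,
                       body_bins = config$metagene_body_bins))) /
    length(brain_samples)
  clus <- cluster_genes(prof, k = config$cluster_k,
                        linkage = config$cluster_linkage)
  res$clustering <- clus
  res$cluster_expression <-
    cluster_expression_summary(clus$cluster, expr_by_cov)
  tick("cluster", length(clus$cluster))

  # marked vs unmarked expression per biotype, per coverage sample
  biotype <- mcols(genes)$biotype
  res$marked_tests <- do.call(rbind, lapply(coverage_meta$sample,
    function(s) {
      tab <- marked_vs_unmarked_test(expr_by_cov[, s], cov[, s] > 0,
                                     strata = biotype)
      tab$sample <- s
      tab
    }))
  tick("tests", nrow(res$marked_tests))

  organ_expr <- expr_meta$organ[match(colnames(l2c), expr_meta$sample)]
  ts <- tissue_specific_genes(l2c, organ_expr, tau_on = config$tau_mod,
                              tau_off = config$tau_off)
  sx <- sex_specific_enrichment(cov, coverage_meta$sex,
                                coverage_meta$organ,
                                tau_cov = config$tau_cov_sex)
  ex <- expression_5hmc_exceptions(l2c, cov, apc,
                                   tau_mod = config$tau_mod,
                                   tau_on = config$tau_on,
                                   tau_cov = config$tau_cov_exception)
  res$specificity <- list(tissue = ts, sex = sx, exceptions = ex)
  tick("specificity", length(ts$brain_specific) +
         length(ts$liver_specific))

  res$report <- data.frame(
    quantity = c("n_genes", "n_coverage_samples", "n_expression_samples",
                 "mean_pct_genome_enriched", "n_clusters",
                 "cluster_trend_rho", "n_brain_specific",
                 "n_liver_specific", "n_sex_specific_genes",
                 "n_exception_class1", "n_exception_class2"),
    value = c(length(genes), nrow(coverage_meta), nrow(expr_meta),
              mean(vapply(res$summaries, function(s) s$pct_genome,
                          numeric(1))),
              config$cluster_k,
              res$cluster_expression$trend_rho,
              length(ts$brain_specific), length(ts$liver_specific),
              length(unique(sx$gene)),
              length(ex$class1), length(ex$class2)))
  res$manifest <- do.call(rbind, manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    sd <- config$seed
    stage_tsv(data.frame(gene_id = rownames(cov), cov,
                         check.names = FALSE),
              file.path(out_dir, "coverage.tsv"), "coverage", sd)
    cls <- data.frame(gene_id = rownames(cov),
                      t(apply(cov, 1, function(f)
                        as.character(coverage_class(f)))),
                      check.names = FALSE)
    colnames(cls)[-1] <- colnames(cov)
    stage_tsv(cls, file.path(out_dir, "coverage_class.tsv"),
              "coverage_class", sd)
    mg <- do.call(rbind, lapply(names(res$metagene), function(s) {
      x <- res$metagene[[s]]; x$sample <- s; x
    }))
    stage_tsv(mg, file.path(out_dir, "metagene.tsv"), "metagene", sd)
    stage_tsv(data.frame(gene_id = rownames(l2c), round(l2c, 4),
                         check.names = FALSE),
              file.path(out_dir, "log2cpm.tsv"), "expression", sd)
    stage_tsv(data.frame(sample = rownames(res$similarity),
                         round(res$similarity, 6), check.names = FALSE),
              file.path(out_dir, "similarity.tsv"), "similarity", sd)
    stage_tsv(data.frame(gene_id = names(clus$cluster),
                         cluster = as.character(clus$cluster)),
              file.path(out_dir, "clusters.tsv"), "cluster", sd)
    stage_tsv(res$cluster_expression$summary,
              file.path(out_dir, "cluster_expression.tsv"), "cluster",
              sd)
    stage_tsv(res$marked_tests, file.path(out_dir, "marked_tests.tsv"),
              "tests", sd)
    stage_tsv(sx, file.path(out_dir, "sex_specific.tsv"), "specificity",
              sd)
    spec_df <- rbind(
      data.frame(gene_id = ts$brain_specific, set = "brain_specific"),
      data.frame(gene_id = ts$liver_specific, set = "liver_specific"),
      data.frame(gene_id = ex$class1, set = "exception_class1"),
      data.frame(gene_id = ex$class2, set = "exception_class2"))
    stage_tsv(spec_df, file.path(out_dir, "specific_genes.tsv"),
              "specificity", sd)
    stage_tsv(res$report, file.path(out_dir, "report.tsv"), "report", sd)
    stage_tsv(res$manifest, file.path(out_dir, "manifest.tsv"),
              "manifest", sd)
  }
  res
}
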