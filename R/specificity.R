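#' Organ-specific gene calling by expression thresholds
#'
#' A gene is brain-specific when it is moderately-to-highly expressed
#' (log2 CPM >= `tau_on`) in every brain sample and below `tau_off` in
#' every liver sample; liver-specific symmetrically. A deterministic
#' threshold rule over all samples of each organ.
#'
#' @param log2cpm genes x samples matrix
#' @param organ character/factor of organ per sample ("brain"/"liver")
#' @param tau_on log2 CPM required in every on-organ sample
#' @param tau_off log2 CPM bound in every off-organ sample
#' @return list of character vectors `brain_specific`, `liver_specific`
#' @export
tissue_specific_genes <- function(log2cpm, organ, tau_on = 2.5,
                                  tau_off = 0) {
  organ <- as.character(organ)
  stopifnot(length(organ) == ncol(log2cpm),
            all(c("brain", "liver") %in% organ))
  b <- log2cpm[, organ == "brain", drop = FALSE]
  l <- log2cpm[, organ == "liver", drop = FALSE]
  on_all <- function(m, tau) rowSums(m < tau) == 0
  off_all <- function(m, tau) rowSums(m >= tau) == 0
  genes <- rownames(log2cpm)
  list(brain_specific = genes[on_all(b, tau_on) & off_all(l, tau_off)],
       liver_specific = genes[on_all(l, tau_on) & off_all(b, tau_off)])
}

#' Sex-specific intragenic enrichment scan
#'
#' Flags genes whose intragenic coverage is at least `tau_cov` in every
#' sample of one sex and exactly zero in every sample of the other — the
#' pattern the X-inactivation transcript shows in female samples. The
#' scan runs genome-wide (sex chromosomes included) and both overall and
#' within each organ.
#'
#' @param coverage genes x samples coverage matrix
#' @param sex character/factor of sex per sample ("F"/"M")
#' @param organ optional organ per sample for per-organ scans
#' @param tau_cov minimum coverage in the enriched sex
#' @return data.frame: gene, scope ("all" or an organ), enriched_sex,
#'   min_cov_enriched
#' @export
sex_specific_enrichment <- function(coverage, sex, organ = NULL,
                                    tau_cov = 0.1) {
  sex <- as.character(sex)
  stopifnot(length(sex) == ncol(coverage), all(c("F", "M") %in% sex))
  scan_one <- function(cols, scope) {
    f <- coverage[, cols & sex == "F", drop = FALSE]
    m <- coverage[, cols & sex == "M", drop = FALSE]
    if (ncol(f) == 0 || ncol(m) == 0) return(NULL)
    f_only <- rowSums(f < tau_cov) == 0 & rowSums(m > 0) == 0
    m_only <- rowSums(m < tau_cov) == 0 & rowSums(f > 0) == 0
    hits <- which(f_only | m_only)
    if (length(hits) == 0) return(NULL)
    data.frame(gene = rownames(coverage)[hits], scope = scope,
               enriched_sex = ifelse(f_only[hits], "F", "M"),
               min_cov_enriched = vapply(hits, function(i) {
                 if (f_only[i]) min(f[i, ]) else min(m[i, ])
               }, numeric(1)), row.names = NULL)
  }
  res <- list(scan_one(rep(TRUE, ncol(coverage)), "all"))
  if (!is.null(organ)) {
    organ <- as.character(organ)
    for (og in unique(organ)) {
      res[[length(res) + 1L]] <- scan_one(organ == og, og)
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(gene = character(0), scope = character(0),
                      enriched_sex = character(0),
                      min_cov_enriched = numeric(0))
  }
  out
}

#' Exception classes of the coverage-expression association
#'
#' Over a gene universe of autosomal protein-coding genes: class 1 genes
#' are moderately-to-highly expressed (log2 CPM >= `tau_mod`) in every
#' expression sample yet have zero intragenic coverage in every coverage
#' sample; class 2 genes are below `tau_on` in every expression sample
#' yet have coverage >= `tau_cov` in every coverage sample. The classes
#' are mutually exclusive by construction.
#'
#' @param log2cpm genes x expression-samples matrix
#' @param coverage genes x coverage-samples matrix
#' @param universe character vector of gene ids to consider (autosomal
#'   protein-coding genes; see [autosomal_protein_coding()])
#' @param tau_mod expressed threshold for class 1
#' @param tau_on not-expressed bound for class 2
#' @param tau_cov minimum coverage for "with enrichment" in class 2;
#'   the default 0 plus strictness means any overlap counts
#' @return list of character vectors `class1` (expressed, no 5hmC) and
#'   `class2` (not expressed, 5hmC)
#' @export
expression_5hmc_exceptions <- function(log2cpm, coverage, universe,
                                       tau_mod = 2.5, tau_on = 0,
                                       tau_cov = 0) {
  universe <- intersect(universe,
                        intersect(rownames(log2cpm), rownames(coverage)))
  e <- log2cpm[universe, , drop = FALSE]
  cv <- coverage[universe, , drop = FALSE]
  class1 <- rowSums(e < tau_mod) == 0 & rowSums(cv > 0) == 0
  cov_all <- if (tau_cov > 0) rowSums(cv >= tau_cov) == ncol(cv)
             else rowSums(cv > 0) == ncol(cv)
  class2 <- rowSums(e >= tau_on) == 0 & cov_all
  list(class1 = universe[class1], class2 = universe[class2])
}

#' Autosomal protein-coding gene universe
#'
#' Gene ids of protein-coding genes not on a sex chromosome — the
#' universe for biotype-level and exception-class analyses.
#'
#' @param genes gene `GRanges` with `biotype` metadata
#' @param sizes `chrom_sizes()` vector carrying the sex-chromosome labels
#' @return character vector of gene ids
#' @export
autosomal_protein_coding <- function(genes, sizes) {
  keep <- mcols(genes)$biotype == "protein_coding" &
    !(as.character(seqnames(genes)) %in% sex_chromosomes(sizes))
  mcols(genes)$gene_id[keep]
}
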