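# Covered width of each target interval under a merged peak set.
covered_width <- function(targets, peaks_merged) {
  out <- numeric(length(targets))
  if (length(targets) == 0L || length(peaks_merged) == 0L) return(out)
  hits <- findOverlaps(targets, peaks_merged, ignore.strand = TRUE)
  if (length(hits) == 0L) return(out)
  ov <- pmin(end(targets)[S4Vectors::queryHits(hits)],
             end(peaks_merged)[S4Vectors::subjectHits(hits)]) -
        pmax(start(targets)[S4Vectors::queryHits(hits)],
             start(peaks_merged)[S4Vectors::subjectHits(hits)]) + 1L
  agg <- rowsum(as.numeric(ov), S4Vectors::queryHits(hits))
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

#' Intragenic 5hmC coverage of gene bodies
#'
#' Fraction of each gene span (TSS to TTS, introns included) overlapped by
#' the merged peak set — the central per-gene statistic of the pipeline.
#'
#' @param genes gene `GRanges`
#' @param peaks peak `GRanges` (merged internally)
#' @return numeric vector in \[0,1\], one value per gene, named by
#'   `gene_id` when present
#' @export
intragenic_coverage <- function(genes, peaks) {
  m <- merge_intervals(peaks)
  frac <- covered_width(genes, m) / width(genes)
  if (!is.null(mcols(genes)$gene_id)) names(frac) <- mcols(genes)$gene_id
  frac
}

#' Gene-by-sample intragenic coverage matrix
#'
#' @param genes gene `GRanges`
#' @param peaks_list named list of peak `GRanges`, one per sample
#' @return numeric matrix genes x samples of coverage fractions, rownames
#'   gene ids, colnames sample ids
#' @export
gene_coverage_matrix <- function(genes, peaks_list) {
  stopifnot(length(peaks_list) > 0, !is.null(names(peaks_list)))
  mat <- vapply(peaks_list, function(p) intragenic_coverage(genes, p),
                numeric(length(genes)))
  mat <- matrix(mat, nrow = length(genes),
                dimnames = list(mcols(genes)$gene_id, names(peaks_list)))
  mat
}

#' Five-level intragenic coverage class
#'
#' Classes: none (exactly 0), low (0 < f < 0.20), intermediary
#' (0.20 <= f < 0.50), high (0.50 <= f < 0.80), very_high (f >= 0.80).
#' Boundaries are lower-inclusive so the classes partition \[0,1\].
#'
#' @param f coverage fraction(s) in \[0,1\]
#' @return factor with levels none, low, intermediary, high, very_high
#' @export
coverage_class <- function(f) {
  stopifnot(all(f >= 0 & f <= 1))
  lev <- c("none", "low", "intermediary", "high", "very_high")
  out <- ifelse(f == 0, "none",
         ifelse(f < 0.20, "low",
         ifelse(f < 0.50, "intermediary",
         ifelse(f < 0.80, "high", "very_high"))))
  factor(out, levels = lev)
}

# Bin table for metagene profiling: per gene, flank_bins fixed-width
# upstream bins, body_bins length-proportional bins, flank_bins downstream
# bins, ordered 5'->3' in the gene's own orientation. Coordinates 0-based
# half-open, clipped to [0, chrom length].
gene_bin_table <- function(genes, flank_bp, body_bins, flank_bins, sizes) {
  n <- length(genes)
  s0 <- start(genes) - 1L
  e0 <- end(genes)
  L <- e0 - s0
  minus <- as.character(strand(genes)) == "-"
  chr <- as.character(seqnames(genes))
  fw <- if (flank_bins > 0) flank_bp / flank_bins else 0

  pieces <- list()
  if (flank_bins > 0) {
    j <- seq_len(flank_bins)
    # upstream, most distal bin first
    up_start <- ifelse(rep(minus, each = flank_bins),
                       rep(e0, each = flank_bins) + flank_bp - j * fw,
                       rep(s0, each = flank_bins) - flank_bp + (j - 1) * fw)
    pieces$up <- data.frame(
      gene = rep(seq_len(n), each = flank_bins),
      region = "upstream", bin = j,
      start0 = round(up_start), end0 = round(up_start + fw))
  }
  k <- seq_len(body_bins)
  Lr <- rep(L, each = body_bins)
  s0r <- rep(s0, each = body_bins)
  mr <- rep(minus, each = body_bins)
  # integer boundary arithmetic keeps minus-strand bins the exact mirror
  # of their plus-strand twins
  bnd_lo <- (Lr * rep(k - 1, n)) %/% body_bins
  bnd_hi <- (Lr * rep(k, n)) %/% body_bins
  body_lo <- ifelse(mr, s0r + Lr - bnd_hi, s0r + bnd_lo)
  body_hi <- ifelse(mr, s0r + Lr - bnd_lo, s0r + bnd_hi)
  pieces$body <- data.frame(
    gene = rep(seq_len(n), each = body_bins),
    region = "body", bin = rep(k, n),
    start0 = body_lo, end0 = body_hi)
  if (flank_bins > 0) {
    j <- seq_len(flank_bins)
    # downstream, bin nearest the TTS first
    dn_start <- ifelse(rep(minus, each = flank_bins),
                       rep(s0, each = flank_bins) - j * fw,
                       rep(e0, each = flank_bins) + (j - 1) * fw)
    pieces$down <- data.frame(
      gene = rep(seq_len(n), each = flank_bins),
      region = "downstream", bin = j,
      start0 = round(dn_start), end0 = round(dn_start + fw))
  }
  bins <- do.call(rbind, pieces[c("up", "body", "down")])
  rownames(bins) <- NULL
  bins$chrom <- chr[bins$gene]
  lim <- as.numeric(sizes[bins$chrom])
  bins$start0 <- pmax(bins$start0, 0)
  bins$end0 <- pmin(bins$end0, lim)
  bins$width <- pmax(bins$end0 - bins$start0, 0)
  bins
}

# Covered fraction of every bin in a gene_bin_table under merged peaks;
# zero-width (fully clipped) bins come back NA.
bin_covered_fraction <- function(bins, peaks, sizes) {
  frac <- rep(NA_real_, nrow(bins))
  ok <- bins$width > 0
  if (any(ok)) {
    gr <- granges_from_bed0(bins$chrom[ok], bins$start0[ok], bins$end0[ok])
    cw <- covered_width(gr, merge_intervals(peaks))
    frac[ok] <- cw / bins$width[ok]
  }
  frac
}

#' Metagene coverage profile around gene bodies
#'
#' Average covered fraction in fixed-width flanking bins up to `flank_bp`
#' upstream of the TSS and downstream of the TTS, and in
#' `body_bins` length-scaled bins across the gene body. Minus-strand genes
#' are profiled 5' to 3' in their own orientation, i.e. their genomic
#' profile is reversed before averaging. Flank bins truncated at
#' chromosome boundaries use their remaining width as denominator; bins
#' clipped away entirely are dropped from the average.
#'
#' @param genes stranded gene `GRanges`
#' @param peaks peak `GRanges`
#' @param sizes `chrom_sizes()` vector
#' @param flank_bp flank extent, bp
#' @param body_bins number of length-scaled gene-body bins
#' @param flank_bins number of fixed-width bins per flank
#' @return data.frame with columns region (upstream/body/downstream), bin
#'   (1-based within region, 5'->3'), position (1..total bins), value
#'   (mean covered fraction), n_genes
#' @export
metagene <- function(genes, peaks, sizes, flank_bp = 2500L,
                     body_bins = 40L, flank_bins = 25L) {
  stopifnot(length(genes) > 0,
            all(as.character(strand(genes)) %in% c("+", "-")))
  bins <- gene_bin_table(genes, flank_bp, body_bins, flank_bins, sizes)
  bins$frac <- bin_covered_fraction(bins, peaks, sizes)
  key <- paste(bins$region, bins$bin)
  ord_regions <- c(if (flank_bins > 0) "upstream", "body",
                   if (flank_bins > 0) "downstream")
  out <- do.call(rbind, lapply(ord_regions, function(rg) {
    nb <- if (rg == "body") body_bins else flank_bins
    data.frame(region = rg, bin = seq_len(nb))
  }))
  okey <- paste(out$region, out$bin)
  out$value <- vapply(okey, function(k)
    mean(bins$frac[key == k], na.rm = TRUE), numeric(1))
  out$n_genes <- vapply(okey, function(k)
    sum(!is.na(bins$frac[key == k])), numeric(1))
  out$position <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("region", "bin", "position", "value", "n_genes")]
}

#' Per-gene gene-body coverage profiles
#'
#' The body-bin vectors (no flanks) used for enrichment-pattern
#' clustering: one row per gene, `body_bins` covered fractions ordered
#' 5' to 3'.
#'
#' @inheritParams metagene
#' @return numeric matrix genes x body_bins, rownames gene ids
#' @export
gene_body_profiles <- function(genes, peaks, sizes, body_bins = 40L) {
  bins <- gene_bin_table(genes, 0L, body_bins, 0L, sizes)
  bins$frac <- bin_covered_fraction(bins, peaks, sizes)
  mat <- matrix(bins$frac[order(bins$gene, bins$bin)],
                nrow = length(genes), ncol = body_bins, byrow = TRUE)
  rownames(mat) <- mcols(genes)$gene_id
  mat
}

#' Genome-wide enrichment summary for one sample
#'
#' Total enriched bp and percent of the genome, per-chromosome percent
#' coverage of intragenic space (merged union of gene spans) and
#' intergenic space (its complement), and the peak-length distribution.
#'
#' @param peaks peak `GRanges`
#' @param genes gene `GRanges`
#' @param sizes `chrom_sizes()` vector
#' @return list with `total_bp`, `pct_genome`, `per_chrom` (data.frame:
#'   chrom, intragenic_bp, intergenic_bp, covered_intragenic_bp,
#'   covered_intergenic_bp, pct_intragenic, pct_intergenic),
#'   `peak_length_mean`, `peak_length_median`, `peak_length_hist`
#' @export
enrichment_summary <- function(peaks, genes, sizes) {
  m <- merge_intervals(peaks)
  genome_bp <- sum(as.numeric(sizes))
  total_bp <- sum(as.numeric(width(m)))
  genic <- merge_intervals(granges(genes, use.mcols = FALSE))
  seqlevels(m) <- union(seqlevels(m), names(sizes))
  seqlevels(genic) <- union(seqlevels(genic), names(sizes))
  per_chrom <- do.call(rbind, lapply(names(sizes), function(ch) {
    chr_gr <- GRanges(ch, IRanges(1L, sizes[[ch]]))
    g_ch <- genic[as.character(seqnames(genic)) == ch]
    m_ch <- m[as.character(seqnames(m)) == ch]
    intra_bp <- sum(as.numeric(width(g_ch)))
    inter_bp <- sizes[[ch]] - intra_bp
    cov_intra <- overlap_length(m_ch, g_ch)
    cov_all <- sum(as.numeric(width(GenomicRanges::intersect(
      m_ch, chr_gr, ignore.strand = TRUE))))
    cov_inter <- cov_all - cov_intra
    data.frame(chrom = ch, intragenic_bp = intra_bp,
               intergenic_bp = inter_bp,
               covered_intragenic_bp = cov_intra,
               covered_intergenic_bp = cov_inter,
               pct_intragenic = if (intra_bp > 0) 100 * cov_intra / intra_bp else 0,
               pct_intergenic = if (inter_bp > 0) 100 * cov_inter / inter_bp else 0)
  }))
  rownames(per_chrom) <- NULL
  lens <- width(m)
  h <- if (length(lens) > 0) graphics::hist(lens, plot = FALSE) else NULL
  list(total_bp = total_bp,
       pct_genome = 100 * total_bp / genome_bp,
       per_chrom = per_chrom,
       peak_length_mean = if (length(lens)) mean(lens) else NA_real_,
       peak_length_median = if (length(lens)) stats::median(lens) else NA_real_,
       peak_length_hist = h)
}

#' Mean intragenic coverage by gene grouping
#'
#' Arithmetic mean coverage per (label, sample), e.g. by gene biotype or
#' molecule type.
#'
#' @param coverage genes x samples coverage matrix
#' @param labels character vector of group labels, one per gene (use
#'   "other" for unlabelled genes)
#' @return list with `mean` (labels x samples matrix) and `n` (named group
#'   sizes)
#' @export
group_mean_coverage <- function(coverage, labels) {
  stopifnot(length(labels) == nrow(coverage))
  sums <- rowsum(coverage, group = labels)
  n <- as.vector(table(labels)[rownames(sums)])
  list(mean = sums / n, n = stats::setNames(n, rownames(sums)))
}
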