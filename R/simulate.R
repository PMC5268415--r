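#' Parameters of the synthetic 5hmC study generator
#'
#' Defaults mirror the study design at toy scale: a ~30 Mb genome of three
#' autosomes plus X and Y analogs, ~1000 genes, 12 coverage samples
#' (2 sexes x 5 brain regions + liver) and 24 expression samples (2
#' replicates each). Coverage targets are drawn from organ-level Beta
#' distributions (brain Beta(2,1.2), liver Beta(1.2,2.5)) coupled through
#' a Gaussian copula that plants the relatedness hierarchy (thalamus and
#' hypothalamus most alike, cerebellum most distinct within brain, liver
#' lowest and least correlated). Peak lengths are Normal(800, 200)
#' truncated to \[100, 3000\] bp with linearly 3'-biased placement.
#' Expression follows count ~ NB(mean = 2^(a + b * coverage + e_g), phi)
#' except for the planted housekeeping (decoupled, constitutively high),
#' exception-class, organ-specific and female-only X-linked genes.
#'
#' @param n_genes number of genes
#' @param chrom_lengths named vector of chromosome lengths
#' @param ... overrides for any default listed in the function body
#' @return named list of generator parameters
#' @export
hmc_sim_params <- function(n_genes = 1000L,
                           chrom_lengths = c(chr1 = 10e6, chr2 = 8e6,
                                             chr3 = 6e6, chrX = 5e6,
                                             chrY = 1e6), ...) {
  p <- list(
    n_genes = as.integer(n_genes),
    chrom_lengths = chrom_lengths,
    chrom_weights = c(chr1 = 1, chr2 = 1, chr3 = 1, chrX = 0.6,
                      chrY = 0.2),
    gene_len_meanlog = log(8000), gene_len_sdlog = 0.9,
    gene_len_range = c(1000, 100000),
    biotype_probs = c(protein_coding = 0.55, pseudogene = 0.12,
                      lincRNA = 0.10, short_ncRNA = 0.10,
                      processed_transcript = 0.08, other = 0.05),
    molecule_probs = c(enzyme = 0.22, `transcription regulator` = 0.15,
                       transporter = 0.12, kinase = 0.10,
                       `ion channel` = 0.08, GPCR = 0.08, other = 0.25),
    beta_brain = c(2, 1.2), beta_liver = c(1.2, 2.5),
    peak_len_mean = 800, peak_len_sd = 200, peak_len_range = c(100, 3000),
    bg_peak_rate = 0.005,    # fraction of intergenic autosomal bp
    link_a = 11, link_b = 1.5, nb_phi = 0.1, gene_baseline_sd = 0.15,
    off_mean = 0.005,        # NB mean of a silenced gene
    hk_mean_log2 = 11, hk_sd_log2 = 0.3,
    n_housekeeping = as.integer(round(0.12 * n_genes)),
    n_brain_specific = as.integer(round(0.02 * n_genes)),
    n_liver_specific = as.integer(round(0.01 * n_genes)),
    n_class1 = as.integer(round(0.012 * n_genes)),
    n_class2 = as.integer(round(0.008 * n_genes)),
    xist_coverage = 0.6)
  over <- list(...)
  stopifnot(all(names(over) %in% names(p)))
  p[names(over)] <- over
  p
}

# Sample metadata tables for the fixed study design.
coverage_sample_table <- function() {
  regions <- c("cerebellum", "cortex", "hippocampus", "hypothalamus",
               "thalamus", "liver")
  abbr <- c("Cb", "Cx", "Hi", "Hy", "Th", "Lv")
  out <- expand.grid(sex = c("F", "M"), region = regions,
                     stringsAsFactors = FALSE)
  out$organ <- ifelse(out$region == "liver", "liver", "brain")
  out$sample <- paste0(abbr[match(out$region, regions)], "_", out$sex)
  out[, c("sample", "organ", "region", "sex")]
}

expression_sample_table <- function() {
  cs <- coverage_sample_table()
  out <- do.call(rbind, lapply(1:2, function(r) {
    x <- cs
    x$replicate <- r
    x$coverage_sample <- x$sample
    x$sample <- paste0(x$sample, "_r", r)
    x
  }))
  rownames(out) <- NULL
  out[order(out$coverage_sample, out$replicate),
      c("sample", "organ", "region", "sex", "replicate",
        "coverage_sample")]
}

#' Simulate the toy genome annotation
#'
#' Draws log-normal gene lengths (clipped to 1-100 kb), places genes
#' without overlap on the five chromosomes (sex chromosomes carry fewer
#' genes), assigns biotypes and molecule types from the parameterised
#' categorical distributions, and designates one X-linked gene as the
#' female-only enrichment analog.
#'
#' @param params [hmc_sim_params()]
#' @param seed optional integer seed (NULL leaves the RNG state alone)
#' @return list with `genes` (a gene `GRanges`), `sizes`
#'   (`chrom_sizes()`), `xist_gene` (gene id)
#' @export
simulate_annotation <- function(params = hmc_sim_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- params$n_genes
  stopifnot(n >= 50)
  sizes <- chrom_sizes(params$chrom_lengths)
  lens <- round(stats::rlnorm(n, params$gene_len_meanlog,
                              params$gene_len_sdlog))
  lens <- pmin(pmax(lens, params$gene_len_range[1]),
               params$gene_len_range[2])
  # assign chromosomes by weighted remaining capacity
  remaining <- params$chrom_lengths * 0.8
  wt <- params$chrom_weights[names(params$chrom_lengths)]
  chrom <- character(n)
  for (i in seq_len(n)) {
    ok <- remaining > lens[i]
    p <- wt * remaining * ok
    chrom[i] <- sample(names(remaining), 1, prob = p / sum(p))
    remaining[chrom[i]] <- remaining[chrom[i]] - lens[i]
  }
  # non-overlapping placement per chromosome via stick-breaking gaps
  start0 <- integer(n)
  for (ch in names(params$chrom_lengths)) {
    idx <- which(chrom == ch)
    if (length(idx) == 0) next
    idx <- sample(idx)  # random order along the chromosome
    free <- params$chrom_lengths[[ch]] - sum(lens[idx])
    g <- stats::rexp(length(idx) + 1)
    gaps <- floor(free * g / sum(g))
    start0[idx] <- cumsum(c(gaps[1], utils::head(lens[idx], -1) +
                                     gaps[-c(1, length(gaps))]))
  }
  strand <- sample(c("+", "-"), n, replace = TRUE)
  biotype <- sample(names(params$biotype_probs), n, replace = TRUE,
                    prob = params$biotype_probs)
  mol <- rep("other", n)
  pc <- biotype == "protein_coding"
  mol[pc] <- sample(names(params$molecule_probs), sum(pc), replace = TRUE,
                    prob = params$molecule_probs)
  mol[biotype == "short_ncRNA"] <- "microRNA"
  gene_id <- sprintf("G%04d", seq_len(n))
  # the female-only X-linked analog
  on_x <- which(chrom == "chrX")
  if (length(on_x) == 0) stop("no chrX genes drawn; increase n_genes")
  xist <- on_x[1]
  biotype[xist] <- "lincRNA"
  mol[xist] <- "other"
  gene_name <- gene_id
  gene_name[xist] <- "XistLike"
  genes <- granges_from_bed0(chrom, start0, start0 + lens, strand,
                             seqinfo_sizes = sizes)
  mcols(genes) <- S4Vectors::DataFrame(gene_id = gene_id,
                                       gene_name = gene_name,
                                       biotype = biotype,
                                       molecule_type = mol)
  ord <- order(chrom, start0)
  list(genes = genes[ord], sizes = sizes, xist_gene = gene_id[xist])
}

# Planted per-gene, per-sample coverage targets (Gaussian copula over the
# organ Beta marginals) plus the planted gene-set overrides.
simulate_targets <- function(ann, params) {
  genes <- ann$genes
  n <- length(genes)
  cs <- coverage_sample_table()
  mixz <- function(parent, a) a * parent + sqrt(1 - a^2) * stats::rnorm(n)
  z0 <- stats::rnorm(n)
  zB <- mixz(z0, 0.75)
  zL <- mixz(z0, 0.75)
  zreg <- list(cerebellum = mixz(zB, 0.90), cortex = mixz(zB, 0.95),
               hippocampus = mixz(zB, 0.95), liver = zL)
  z_thhy <- mixz(zB, 0.96)
  zreg$thalamus <- mixz(z_thhy, 0.99)
  zreg$hypothalamus <- mixz(z_thhy, 0.99)
  target <- matrix(0, n, nrow(cs), dimnames = list(mcols(genes)$gene_id,
                                                   cs$sample))
  for (j in seq_len(nrow(cs))) {
    z <- mixz(zreg[[cs$region[j]]], 0.995)
    sh <- if (cs$organ[j] == "brain") params$beta_brain
          else params$beta_liver
    target[, j] <- stats::qbeta(stats::pnorm(z), sh[1], sh[2])
  }
  # planted gene sets, all from autosomal protein-coding genes
  sex_chr <- sex_chromosomes(ann$sizes)
  apc <- mcols(genes)$gene_id[mcols(genes)$biotype == "protein_coding" &
    !(as.character(seqnames(genes)) %in% sex_chr)]
  need <- params$n_housekeeping + params$n_brain_specific +
    params$n_liver_specific + params$n_class1 + params$n_class2
  stopifnot(length(apc) >= need)
  pick <- sample(apc, need)
  sets <- list(
    housekeeping = pick[seq_len(params$n_housekeeping)],
    brain_specific = pick[params$n_housekeeping +
                            seq_len(params$n_brain_specific)],
    liver_specific = pick[params$n_housekeeping +
                            params$n_brain_specific +
                            seq_len(params$n_liver_specific)],
    class1 = pick[params$n_housekeeping + params$n_brain_specific +
                    params$n_liver_specific + seq_len(params$n_class1)],
    class2 = pick[need - params$n_class2 + seq_len(params$n_class2)])
  # overrides: sex chromosomes depleted, female-only analog, exceptions
  on_sex <- as.character(seqnames(genes)) %in% sex_chr
  target[on_sex, ] <- 0
  target[ann$xist_gene, cs$sex == "F"] <- params$xist_coverage
  target[sets$class1, ] <- 0
  target[sets$class2, ] <- 0.5
  list(target = target, sets = sets, samples = cs)
}

# Lengths of the peaks for one gene: truncated-normal draws whose total is
# stretched to the target; a single clipped peak when the target is small.
draw_peak_lengths <- function(target_bp, gene_len, params) {
  rng <- params$peak_len_range
  lens <- numeric(0); tot <- 0
  repeat {
    l <- min(max(round(stats::rnorm(1, params$peak_len_mean,
                                    params$peak_len_sd)), rng[1]), rng[2])
    if (tot + l >= target_bp) break
    lens <- c(lens, l); tot <- tot + l
  }
  d <- target_bp - tot
  if (length(lens) == 0) {
    lens <- min(max(d, rng[1]), gene_len)
  } else {
    add <- d %/% length(lens)
    lens <- lens + add
    lens[1] <- lens[1] + d %% length(lens)
    lens <- pmin(lens, gene_len)
  }
  lens
}

# Non-overlapping placement of peak lengths inside [0, L) with a 3'
# placement bias: the k+1 inter-peak gaps are drawn by stick-breaking with
# expected gap size decreasing linearly 5'->3', so covered density rises
# toward the 3' end while the realized covered length equals sum(lens)
# exactly.
place_in_gene <- function(lens, L) {
  lens <- pmin(lens, L)
  while (sum(lens) > L) lens <- lens[-length(lens)]
  k <- length(lens)
  if (k == 0) return(cbind(start = numeric(0), end = numeric(0)))
  if (k > 1) lens <- sample(lens)  # length uncorrelated with position
  free <- L - sum(lens)
  # squared-decreasing gap weights concentrate free space at the 5' end;
  # the damped terminal gap keeps coverage from dipping right at the TTS
  w <- ((k + 1):1)^2 * stats::rgamma(k + 1, shape = 2, rate = 2)
  w[k + 1] <- w[k + 1] * 0.15
  gaps <- floor(free * w / sum(w))
  gaps[1] <- gaps[1] + free - sum(gaps)
  st <- cumsum(c(gaps[1], lens[-k] + gaps[2:k][seq_len(max(k - 1, 0))]))
  cbind(start = st, end = st + lens)
}

#' Simulate per-sample 5hmC peak sets
#'
#' For each gene and coverage sample, places non-overlapping peaks inside
#' the gene body until the planted target coverage fraction is met, with
#' truncated-Normal(800, 200) lengths and a linearly 3'-biased placement
#' density. Sex-chromosome genes stay empty except the female-only
#' X-linked analog; sparse background peaks are scattered over intergenic
#' autosomal space.
#'
#' @param ann [simulate_annotation()] output
#' @param targets output of the internal target generator (a matrix of
#'   planted fractions) — supplied by [simulate_hmc_study()]
#' @param params [hmc_sim_params()]
#' @param seed optional seed
#' @return named list of 12 peak `GRanges`
#' @export
simulate_peaks <- function(ann, targets, params = hmc_sim_params(),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genes <- ann$genes
  s0 <- start(genes) - 1L
  e0 <- end(genes)
  L <- e0 - s0
  minus <- as.character(strand(genes)) == "-"
  chr <- as.character(seqnames(genes))
  sex_chr <- sex_chromosomes(ann$sizes)
  genic <- merge_intervals(granges(genes, use.mcols = FALSE))
  auto <- setdiff(names(ann$sizes), sex_chr)
  intergenic_bp <- sum(as.numeric(ann$sizes[auto])) -
    sum(as.numeric(width(genic[as.character(seqnames(genic)) %in% auto])))
  n_bg <- round(params$bg_peak_rate * intergenic_bp /
                  params$peak_len_mean)
  out <- list()
  for (smp in colnames(targets)) {
    st_all <- list(); en_all <- list(); chr_all <- list()
    k <- 0L
    for (i in seq_along(genes)) {
      tb <- round(targets[i, smp] * L[i])
      if (tb < 50) next
      lens <- draw_peak_lengths(tb, L[i], params)
      pl <- place_in_gene(lens, L[i])
      if (nrow(pl) == 0) next
      k <- k + 1L
      if (minus[i]) {
        st_all[[k]] <- e0[i] - pl[, "end"]
        en_all[[k]] <- e0[i] - pl[, "start"]
      } else {
        st_all[[k]] <- s0[i] + pl[, "start"]
        en_all[[k]] <- s0[i] + pl[, "end"]
      }
      chr_all[[k]] <- rep(chr[i], nrow(pl))
    }
    # intergenic background, autosomes only (sex chromosomes depleted)
    if (n_bg > 0) {
      bg_chr <- sample(auto, n_bg * 2, replace = TRUE,
                       prob = ann$sizes[auto])
      bg_len <- pmin(pmax(round(stats::rnorm(n_bg * 2,
                                             params$peak_len_mean,
                                             params$peak_len_sd)),
                          params$peak_len_range[1]),
                     params$peak_len_range[2])
      bg_st <- floor(stats::runif(n_bg * 2) *
                       (as.numeric(ann$sizes[bg_chr]) - bg_len))
      cand <- granges_from_bed0(bg_chr, bg_st, bg_st + bg_len)
      free <- !IRanges::overlapsAny(cand, genic, ignore.strand = TRUE)
      cand <- cand[free][seq_len(min(n_bg, sum(free)))]
      k <- k + 1L
      st_all[[k]] <- start(cand) - 1L
      en_all[[k]] <- end(cand)
      chr_all[[k]] <- as.character(seqnames(cand))
    }
    gr <- granges_from_bed0(unlist(chr_all), unlist(st_all),
                            unlist(en_all), seqinfo_sizes = ann$sizes)
    out[[smp]] <- sort(gr, ignore.strand = TRUE)
  }
  out
}

#' Simulate the expression count matrix
#'
#' Counts are negative binomial with mean `2^(a + b * coverage + e_g)`
#' (per-gene baseline `e_g ~ N(0, sd)`), evaluated at each expression
#' sample's matching coverage sample. Housekeeping genes get a fixed high
#' mean decoupled from coverage. Class-1 exception genes follow the link
#' at their planted zero coverage (so they are expressed without
#' enrichment); class-2 genes are silenced despite planted high coverage;
#' organ-specific genes follow the link in their organ and are silenced
#' in the other; the X-linked analog is silenced in males.
#'
#' @param ann annotation from [simulate_annotation()]
#' @param truth target/set list from the target generator
#' @param params [hmc_sim_params()]
#' @param seed optional seed
#' @return list with `counts` (genes x 24 integer matrix), `samples`
#'   (expression metadata), `baseline` (per-gene e_g)
#' @export
simulate_counts <- function(ann, truth, params = hmc_sim_params(),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genes <- mcols(ann$genes)$gene_id
  n <- length(genes)
  es <- expression_sample_table()
  e_g <- stats::rnorm(n, 0, params$gene_baseline_sd)
  hk_level <- 2^stats::rnorm(n, params$hk_mean_log2, params$hk_sd_log2)
  mu <- matrix(0, n, nrow(es), dimnames = list(genes, es$sample))
  sets <- truth$sets
  # depth of each library under the link alone; constitutive genes keep a
  # constant share of the library, not a constant absolute mean
  depth <- vapply(seq_len(nrow(es)), function(j)
    sum(2^(params$link_a +
             params$link_b * truth$target[, es$coverage_sample[j]] +
             e_g)), numeric(1))
  depth <- depth / mean(depth)
  for (j in seq_len(nrow(es))) {
    cov_j <- truth$target[, es$coverage_sample[j]]
    m <- 2^(params$link_a + params$link_b * cov_j + e_g)
    m[match(sets$housekeeping, genes)] <-
      depth[j] * hk_level[match(sets$housekeeping, genes)]
    m[match(sets$class2, genes)] <- params$off_mean
    off <- if (es$organ[j] == "brain") sets$liver_specific
           else sets$brain_specific
    m[match(off, genes)] <- params$off_mean
    if (es$sex[j] == "M") m[match(ann$xist_gene, genes)] <- params$off_mean
    mu[, j] <- m
  }
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / params$nb_phi),
                   nrow = n, dimnames = dimnames(mu))
  list(counts = counts, samples = es, baseline = e_g)
}

#' Simulate fragment files for the island caller
#'
#' Control fragments fall uniformly over the genome; treatment fragments
#' add `fold`-times the background rate inside the supplied true islands.
#' All fragments have the given length and a random strand.
#'
#' @param islands `GRanges` of true enriched regions
#' @param sizes `chrom_sizes()` vector
#' @param n_control number of control fragments
#' @param fold treatment enrichment inside islands (1 = null)
#' @param fragment_len fragment length, bp
#' @param seed optional seed
#' @return list with `treat` and `ctrl` fragment `GRanges`
#' @export
simulate_fragments <- function(islands, sizes, n_control = 50000L,
                               fold = 10, fragment_len = 200L,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genome_bp <- sum(as.numeric(sizes))
  draw_uniform <- function(nfr) {
    ch <- sample(names(sizes), nfr, replace = TRUE, prob = sizes)
    st <- floor(stats::runif(nfr) *
                  (as.numeric(sizes[ch]) - fragment_len))
    granges_from_bed0(ch, st, st + fragment_len,
                      strand = sample(c("+", "-"), nfr, replace = TRUE),
                      seqinfo_sizes = sizes)
  }
  ctrl <- draw_uniform(n_control)
  treat <- draw_uniform(n_control)
  if (length(islands) > 0 && fold > 1) {
    rate <- n_control / genome_bp
    n_extra <- stats::rpois(length(islands),
                            rate * (fold - 1) * width(islands))
    idx <- rep(seq_along(islands), n_extra)
    if (length(idx) > 0) {
      pos <- start(islands)[idx] - 1L +
        floor(stats::runif(length(idx)) * width(islands)[idx])
      extra <- granges_from_bed0(as.character(seqnames(islands))[idx],
                                 pmax(pos - fragment_len %/% 2L, 0),
                                 pmax(pos - fragment_len %/% 2L, 0) +
                                   fragment_len,
                                 strand = sample(c("+", "-"), length(idx),
                                                 replace = TRUE),
                                 seqinfo_sizes = sizes)
      treat <- sort(c(treat, extra), ignore.strand = TRUE)
    }
  }
  list(treat = treat, ctrl = sort(ctrl, ignore.strand = TRUE))
}

#' Simulate a complete synthetic 5hmC study
#'
#' Composes annotation, planted coverage targets, per-sample peak sets
#' and the expression count matrix under one seed; every planted quantity
#' is returned in `truth` for recovery testing.
#'
#' @param seed integer seed (full determinism: same seed, same study)
#' @param params [hmc_sim_params()]
#' @return list with `genes`, `sizes`, `peaks` (12 `GRanges`), `counts`,
#'   `coverage_samples`, `expression_samples`, `truth` (targets, gene
#'   sets, link parameters, Xist analog id, baseline)
#' @export
simulate_hmc_study <- function(seed = 1L, params = hmc_sim_params()) {
  set.seed(seed)
  ann <- simulate_annotation(params)
  truth <- simulate_targets(ann, params)
  peaks <- simulate_peaks(ann, truth$target, params)
  expr <- simulate_counts(ann, truth, params)
  list(genes = ann$genes, sizes = ann$sizes, peaks = peaks,
       counts = expr$counts,
       coverage_samples = truth$samples,
       expression_samples = expr$samples,
       truth = list(target = truth$target, sets = truth$sets,
                    xist_gene = ann$xist_gene,
                    link = list(a = params$link_a, b = params$link_b,
                                phi = params$nb_phi),
                    baseline = expr$baseline, seed = seed,
                    params = params))
}

#' Write a synthetic study to disk
#'
#' Emits genes.gtf, chrom.sizes, one BED per coverage sample under
#' `peaks/`, counts.tsv, sample_metadata.tsv, and the planted truth
#' (truth_targets.tsv, truth_gene_sets.tsv).
#'
#' @param study [simulate_hmc_study()] output
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_synthetic_study <- function(study, dir) {
  dir.create(file.path(dir, "peaks"), recursive = TRUE,
             showWarnings = FALSE)
  g <- study$genes
  md <- mcols(g)
  attrs <- sprintf(
    'gene_id "%s"; gene_type "%s"; gene_name "%s"; molecule_type "%s";',
    md$gene_id, md$biotype, md$gene_name, md$molecule_type)
  gtf <- sprintf("%s\thmcscan_sim\tgene\t%d\t%d\t.\t%s\t.\t%s",
                 as.character(seqnames(g)), start(g), end(g),
                 as.character(strand(g)), attrs)
  writeLines(gtf, file.path(dir, "genes.gtf"))
  write_chrom_sizes(study$sizes, file.path(dir, "chrom.sizes"))
  for (smp in names(study$peaks)) {
    write_bed(study$peaks[[smp]],
              file.path(dir, "peaks", paste0(smp, ".bed")))
  }
  utils::write.table(
    data.frame(gene_id = rownames(study$counts), study$counts,
               check.names = FALSE),
    file.path(dir, "counts.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(study$expression_samples,
                     file.path(dir, "sample_metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = rownames(study$truth$target),
               study$truth$target, check.names = FALSE),
    file.path(dir, "truth_targets.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  sets <- study$truth$sets
  set_df <- do.call(rbind, lapply(names(sets), function(nm)
    data.frame(gene_id = sets[[nm]], set = nm)))
  set_df <- rbind(set_df, data.frame(gene_id = study$truth$xist_gene,
                                     set = "xist_analog"))
  utils::write.table(set_df, file.path(dir, "truth_gene_sets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
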