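#' Parameters for the window-clustering island caller
#'
#' The caller tiles each chromosome with non-overlapping windows of
#' `window_w` bp, marks windows whose fragment-midpoint count exceeds a
#' Poisson background as eligible, joins eligible windows separated by at
#' most `gap_g` bp into islands, and scores islands against the input
#' control. Defaults follow the published use of this algorithm family on
#' 5hmC capture data: 100 bp windows, 200 bp fragments, 200 bp gap (100 bp
#' also supported), island FDR 0.01, redundancy threshold 1.
#'
#' @param window_w window size, bp
#' @param fragment_size assumed sequenced-fragment length, bp; reads are
#'   shifted by half this in their strand direction
#' @param gap_g maximum ineligible gap bridged inside an island, bp; must
#'   be a multiple of `window_w`
#' @param redundancy_r maximum identical fragments retained
#' @param window_p0 Poisson upper-tail probability below which a window
#'   count is eligible
#' @param fdr_q Benjamini-Hochberg q-value cutoff for retained islands
#' @param effective_genome_fraction mappable fraction of the genome used
#'   in the background rate
#' @return a list of class `caller_params`
#' @export
caller_params <- function(window_w = 100L, fragment_size = 200L,
                          gap_g = 200L, redundancy_r = 1L,
                          window_p0 = 0.2, fdr_q = 0.01,
                          effective_genome_fraction = 0.74) {
  stopifnot(window_w > 0, gap_g %% window_w == 0,
            window_p0 > 0, window_p0 < 1, fdr_q > 0, fdr_q < 1,
            redundancy_r >= 1, effective_genome_fraction > 0,
            effective_genome_fraction <= 1)
  structure(list(window_w = as.integer(window_w),
                 fragment_size = as.integer(fragment_size),
                 gap_g = as.integer(gap_g),
                 redundancy_r = as.integer(redundancy_r),
                 window_p0 = window_p0, fdr_q = fdr_q,
                 effective_genome_fraction = effective_genome_fraction),
            class = "caller_params")
}

#' Remove redundant fragments
#'
#' At most `r` fragments with identical (chromosome, start, end, strand)
#' are retained, emulating a PCR-duplicate redundancy threshold.
#'
#' @param frags fragment `GRanges`
#' @param r maximum copies retained per identical fragment
#' @return deduplicated `GRanges`
#' @export
deduplicate_fragments <- function(frags, r = 1L) {
  stopifnot(r >= 1)
  if (length(frags) == 0L) return(frags)
  key <- paste(as.character(seqnames(frags)), start(frags), end(frags),
               as.character(strand(frags)))
  ord <- order(key)
  copy_index <- sequence(rle(key[ord])$lengths)
  keep <- ord[copy_index <= r]
  sort(frags[sort(keep)], ignore.strand = TRUE)
}

#' Count fragment midpoints in fixed windows
#'
#' Each fragment contributes one point: its read start shifted by
#' `fragment_size/2` in the strand direction (the fragment midpoint when
#' full fragments are supplied unstranded). Points are assigned to the
#' non-overlapping `window_w` tiling of each chromosome; points beyond the
#' chromosome end are clipped into the last window.
#'
#' @param frags deduplicated fragment `GRanges`
#' @param params `caller_params()`
#' @param sizes `chrom_sizes()` vector
#' @return named list, one integer count vector per chromosome
#' @export
count_windows <- function(frags, params, sizes) {
  w <- params$window_w
  shift <- params$fragment_size %/% 2L
  chrom <- as.character(seqnames(frags))
  unknown <- setdiff(unique(chrom), names(sizes))
  if (length(unknown) > 0L) {
    stop("fragment(s) on unknown chromosome(s): ",
         paste(unknown, collapse = ", "))
  }
  str <- as.character(strand(frags))
  # 0-based point position per fragment
  point <- ifelse(str == "-", (end(frags) - 1L) - shift,
           ifelse(str == "+", (start(frags) - 1L) + shift,
                  (start(frags) - 1L + end(frags)) %/% 2L))
  point <- pmax(point, 0L)
  out <- lapply(names(sizes), function(ch) {
    nwin <- as.integer(ceiling(sizes[[ch]] / w))
    idx <- point[chrom == ch] %/% w
    idx <- pmin(idx, nwin - 1L)
    tabulate(idx + 1L, nbins = nwin)
  })
  names(out) <- names(sizes)
  out
}

#' Smallest eligible window count under a Poisson background
#'
#' Returns the smallest integer `l0` whose upper-tail probability
#' P(X >= l0) under Poisson(`lambda_bg`) is below `p0`; windows with at
#' least `l0` points are eligible for island formation.
#'
#' @param lambda_bg expected background points per window
#' @param p0 eligibility tail probability
#' @return integer threshold >= 1
#' @export
eligible_threshold <- function(lambda_bg, p0) {
  stopifnot(lambda_bg > 0, p0 > 0, p0 <= 1)
  l0 <- 1L
  # P(X >= l0) = 1 - P(X <= l0-1)
  while (stats::ppois(l0 - 1L, lambda_bg, lower.tail = FALSE) >= p0) {
    l0 <- l0 + 1L
  }
  l0
}

#' Join eligible windows into candidate islands
#'
#' Islands are maximal runs of eligible windows in which consecutive
#' eligible windows are separated by at most `gap_g` bp of ineligible
#' windows. The island span runs from the first to the last eligible
#' window, gaps included, and its score is the summed negative log Poisson
#' probability of the eligible window counts under the background rate.
#'
#' @param counts integer window counts for one chromosome
#' @param chrom chromosome name
#' @param l0 eligibility threshold from [eligible_threshold()]
#' @param params `caller_params()`
#' @param lambda_bg background rate per window
#' @return data.frame with columns chrom, start_win, end_win (inclusive,
#'   0-based window units), score
#' @export
form_islands <- function(counts, chrom, l0, params, lambda_bg) {
  elig <- which(counts >= l0) - 1L   # 0-based window indices
  empty <- data.frame(chrom = character(0), start_win = integer(0),
                      end_win = integer(0), score = numeric(0))
  if (length(elig) == 0L) return(empty)
  gap_windows <- params$gap_g %/% params$window_w
  # break whenever more than gap_windows ineligible windows intervene
  new_island <- c(TRUE, diff(elig) - 1L > gap_windows)
  grp <- cumsum(new_island)
  start_win <- tapply(elig, grp, min)
  end_win <- tapply(elig, grp, max)
  wscore <- -stats::dpois(counts[elig + 1L], lambda_bg, log = TRUE)
  score <- as.numeric(tapply(wscore, grp, sum))
  data.frame(chrom = chrom, start_win = as.integer(start_win),
             end_win = as.integer(end_win), score = score,
             row.names = NULL)
}

#' Score candidate islands against the input control
#'
#' Treatment and control points are summed over each island span. The
#' expected treatment count is the control count scaled by the library-size
#' ratio, floored at the background expectation for the span so that
#' zero-control islands cannot reach p = 0. p is the Poisson upper tail,
#' q the Benjamini-Hochberg adjustment over all candidate islands.
#'
#' @param islands data.frame from [form_islands()] (possibly several
#'   chromosomes row-bound)
#' @param treat_counts,ctrl_counts window-count lists from
#'   [count_windows()]
#' @param n_treat,n_ctrl total retained fragment counts
#' @param params `caller_params()`
#' @param lambda_bg background rate per window
#' @return islands with columns treat_count, ctrl_count, p_value, q_value
#'   appended; all candidates are returned (filtering is the caller's job)
#' @export
score_islands_vs_control <- function(islands, treat_counts, ctrl_counts,
                                     n_treat, n_ctrl, params, lambda_bg) {
  stopifnot(n_treat > 0, n_ctrl > 0)
  if (nrow(islands) == 0L) {
    islands$treat_count <- integer(0); islands$ctrl_count <- integer(0)
    islands$p_value <- numeric(0); islands$q_value <- numeric(0)
    return(islands)
  }
  span_sum <- function(counts_list, row) {
    sum(counts_list[[row$chrom]][(row$start_win:row$end_win) + 1L])
  }
  islands$treat_count <- vapply(seq_len(nrow(islands)), function(i)
    span_sum(treat_counts, islands[i, ]), numeric(1))
  islands$ctrl_count <- vapply(seq_len(nrow(islands)), function(i)
    span_sum(ctrl_counts, islands[i, ]), numeric(1))
  span_windows <- islands$end_win - islands$start_win + 1L
  lambda_isl <- pmax(islands$ctrl_count * n_treat / n_ctrl,
                     lambda_bg * span_windows)
  islands$p_value <- stats::ppois(islands$treat_count - 1L, lambda_isl,
                                  lower.tail = FALSE)
  islands$q_value <- stats::p.adjust(islands$p_value, method = "BH")
  islands
}

#' Call 5hmC islands from treatment and control fragments
#'
#' Full caller: deduplicate both fragment sets, count shifted points in
#' windows, form gap-joined islands from eligible treatment windows, score
#' them against the scaled control, and retain islands with q below
#' `params$fdr_q`. The background rate is
#' `n_treat * window_w / (effective_genome_fraction * genome length)`.
#'
#' @param treat,ctrl fragment `GRanges` (treatment, input control)
#' @param sizes `chrom_sizes()` vector
#' @param params `caller_params()`
#' @return list with `islands` (a `GRanges` with score, counts, p, q,
#'   sorted by chromosome and start), `candidates` (data.frame of all
#'   scored candidates), `lambda_bg`, `l0`, `n_treat`, `n_ctrl`
#' @export
call_islands <- function(treat, ctrl, sizes, params = caller_params()) {
  treat <- deduplicate_fragments(treat, params$redundancy_r)
  ctrl <- deduplicate_fragments(ctrl, params$redundancy_r)
  n_treat <- length(treat)
  n_ctrl <- length(ctrl)
  stopifnot(n_treat > 0, n_ctrl > 0)
  tc <- count_windows(treat, params, sizes)
  cc <- count_windows(ctrl, params, sizes)
  genome_bp <- sum(as.numeric(sizes))
  lambda_bg <- n_treat * params$window_w /
    (params$effective_genome_fraction * genome_bp)
  l0 <- eligible_threshold(lambda_bg, params$window_p0)
  cand <- do.call(rbind, lapply(names(sizes), function(ch)
    form_islands(tc[[ch]], ch, l0, params, lambda_bg)))
  if (is.null(cand)) {
    cand <- form_islands(integer(0), "none", l0, params, lambda_bg)
  }
  cand <- score_islands_vs_control(cand, tc, cc, n_treat, n_ctrl,
                                   params, lambda_bg)
  keep <- cand[!is.na(cand$q_value) & cand$q_value < params$fdr_q, ,
               drop = FALSE]
  w <- params$window_w
  gr <- granges_from_bed0(keep$chrom, keep$start_win * w,
                          pmin((keep$end_win + 1L) * w,
                               as.numeric(sizes[keep$chrom])),
                          seqinfo_sizes = sizes)
  ord <- order(as.character(seqnames(gr)), start(gr))
  gr <- gr[ord]
  keep <- keep[ord, , drop = FALSE]
  if (length(gr) > 0L) {
    mcols(gr) <- S4Vectors::DataFrame(
      name = sprintf("island_%d", seq_along(gr)),
      score = keep$score, treat_count = keep$treat_count,
      ctrl_count = keep$ctrl_count, p_value = keep$p_value,
      q_value = keep$q_value)
  }
  list(islands = gr, candidates = cand, lambda_bg = lambda_bg, l0 = l0,
       n_treat = n_treat, n_ctrl = n_ctrl)
}
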