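#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom GenomeInfoDb seqlevels seqlevels<- seqlengths seqlengths<- seqnames
#' @importFrom data.table fread data.table as.data.table setkey :=
NULL

#' Read a chromosome-sizes table
#'
#' Two whitespace-delimited columns: chromosome name and length in bp.
#' Sex chromosomes are flagged so downstream analyses can exclude them
#' (biotype and exception-class analyses run on autosomes only).
#'
#' @param path path to a two-column chrom.sizes file
#' @param sex_chroms character vector of chromosome names to treat as sex
#'   chromosomes; only those actually present are kept
#' @return named integer vector of lengths with attribute `sex_chroms`
#' @export
read_chrom_sizes <- function(path, sex_chroms = c("chrX", "chrY")) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "length"))
  if (any(tab$length <= 0)) stop("chromosome lengths must be positive")
  if (anyDuplicated(tab$chrom)) stop("duplicated chromosome names in ", path)
  chrom_sizes(stats::setNames(tab$length, tab$chrom), sex_chroms)
}

#' Construct a chromosome-sizes object from a named vector
#'
#' @param sizes named numeric vector, chromosome name -> length in bp
#' @param sex_chroms names to flag as sex chromosomes
#' @return named integer vector with attribute `sex_chroms`
#' @export
chrom_sizes <- function(sizes, sex_chroms = c("chrX", "chrY")) {
  stopifnot(!is.null(names(sizes)), all(sizes > 0))
  out <- stats::setNames(as.integer(sizes), names(sizes))
  attr(out, "sex_chroms") <- intersect(sex_chroms, names(out))
  out
}

#' Sex-chromosome names recorded in a chrom-sizes object
#' @param sizes a `chrom_sizes()` vector
#' @return character vector (possibly empty)
#' @export
sex_chromosomes <- function(sizes) {
  sc <- attr(sizes, "sex_chroms")
  if (is.null(sc)) character(0) else sc
}

#' Write a chrom.sizes file
#' @param sizes named vector of lengths
#' @param path output path
#' @export
write_chrom_sizes <- function(sizes, path) {
  utils::write.table(data.frame(names(sizes), as.integer(sizes)), path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# GRanges from 0-based half-open coordinates (the BED convention).
granges_from_bed0 <- function(chrom, start0, end0, strand = "*",
                              seqinfo_sizes = NULL) {
  strand <- rep(strand, length.out = length(chrom))
  gr <- GRanges(chrom, IRanges(start0 + 1L, end0), strand = strand)
  if (!is.null(seqinfo_sizes)) {
    seqlevels(gr) <- names(seqinfo_sizes)
    seqlengths(gr) <- unname(as.integer(seqinfo_sizes))
  }
  gr
}

#' Read a BED3/BED6 file of genomic intervals
#'
#' BED coordinates are 0-based half-open; the returned `GRanges` uses the
#' usual Bioconductor 1-based closed convention, so widths and overlaps are
#' identical. Column 6, when present, is parsed as strand. Lines failing
#' validation (fewer than 3 columns, non-numeric or inverted coordinates)
#' abort the read with their line numbers.
#'
#' @param path BED file path
#' @param chrom_sizes optional `chrom_sizes()` vector; when supplied, any
#'   interval on an unlisted chromosome is an error naming it
#' @return a `GRanges`, sorted by (chromosome, start)
#' @export
read_bed <- function(path, chrom_sizes = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(granges_from_bed0(character(0), integer(0), integer(0),
                             seqinfo_sizes = chrom_sizes))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  ncol <- lengths(fields)
  bad <- which(ncol < 3L)
  getf <- function(i) vapply(fields, function(f) f[i], character(1))
  chrom <- getf(1L)
  start0 <- suppressWarnings(as.numeric(getf(2L)))
  end0 <- suppressWarnings(as.numeric(getf(3L)))
  bad <- sort(unique(c(bad,
                       which(is.na(start0) | is.na(end0) |
                             start0 < 0 | start0 >= end0))))
  if (length(bad) > 0L) {
    stop(sprintf("%d malformed BED line(s) in %s (lines: %s)",
                 length(bad), path,
                 paste(utils::head(bad, 10), collapse = ", ")))
  }
  strand <- rep("*", length(lines))
  has6 <- ncol >= 6L
  if (any(has6)) {
    s6 <- vapply(fields[has6], function(f) f[6L], character(1))
    s6[!s6 %in% c("+", "-")] <- "*"
    strand[has6] <- s6
  }
  if (!is.null(chrom_sizes)) {
    unknown <- setdiff(unique(chrom), names(chrom_sizes))
    if (length(unknown) > 0L) {
      stop("BED interval(s) on chromosome(s) absent from chrom sizes: ",
           paste(unknown, collapse = ", "))
    }
  }
  sort(granges_from_bed0(chrom, start0, end0, strand,
                         seqinfo_sizes = chrom_sizes),
       ignore.strand = TRUE)
}

#' Write intervals as BED
#'
#' Emits BED6 when any strand is set or `name`/`score` metadata exist,
#' BED3 otherwise. Coordinates are converted back to 0-based half-open.
#'
#' @param gr a `GRanges`
#' @param path output path
#' @export
write_bed <- function(gr, path) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr))
  str <- as.character(strand(gr))
  want6 <- any(str != "*") || !is.null(mcols(gr)$name) ||
    !is.null(mcols(gr)$score)
  if (want6) {
    df$name <- if (is.null(mcols(gr)$name)) "." else mcols(gr)$name
    df$score <- if (is.null(mcols(gr)$score)) 0 else mcols(gr)$score
    df$strand <- ifelse(str == "*", ".", str)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Controlled biotype vocabulary used throughout the genic analyses.
.short_ncrna <- c("miRNA", "snRNA", "snoRNA", "rRNA", "misc_RNA", "scRNA",
                  "srpRNA", "tRNA", "Mt_rRNA", "Mt_tRNA")

map_biotype <- function(x) {
  out <- rep("other", length(x))
  out[x == "protein_coding"] <- "protein_coding"
  out[x %in% c("lincRNA", "lncRNA")] <- "lincRNA"
  out[x == "processed_transcript"] <- "processed_transcript"
  out[grepl("pseudogene", x)] <- "pseudogene"
  out[x %in% c(.short_ncrna, "short_ncRNA")] <- "short_ncRNA"
  out[is.na(x)] <- "other"
  out
}

#' Read gene models from a GENCODE-style GTF
#'
#' Only `gene` feature rows are used. The gene span (TSS to TTS, introns
#' included) is the unit of every intragenic analysis. Biotypes are mapped
#' onto a controlled vocabulary (protein_coding, lincRNA,
#' processed_transcript, pseudogene, short_ncRNA, other); an optional
#' `molecule_type` attribute is carried through (missing -> "other").
#'
#' @param path GTF path (1-based closed coordinates, GENCODE attributes)
#' @return a `GRanges` of gene spans with metadata columns `gene_id`,
#'   `gene_name`, `biotype`, `molecule_type`
#' @export
read_gtf_genes <- function(path) {
  raw <- readLines(path)
  body <- !grepl("^#", raw) & nzchar(trimws(raw))
  feat <- sub("^([^\t]*\t){2}([^\t]*)\t.*$", "\\2", raw)
  gene_rows <- which(body & feat == "gene")
  if (length(gene_rows) == 0L) {
    gr <- GRanges()
    mcols(gr) <- S4Vectors::DataFrame(gene_id = character(0),
                                      gene_name = character(0),
                                      biotype = character(0),
                                      molecule_type = character(0))
    return(gr)
  }
  no_id <- gene_rows[!grepl("gene_id", raw[gene_rows])]
  if (length(no_id) > 0L) {
    stop(sprintf("GTF gene record(s) missing gene_id attribute (lines: %s)",
                 paste(utils::head(no_id, 10), collapse = ", ")))
  }
  gr <- rtracklayer::import(path, format = "gtf", feature.type = "gene")
  md <- mcols(gr)
  biotype_raw <- if (!is.null(md$gene_type)) md$gene_type
    else if (!is.null(md$gene_biotype)) md$gene_biotype
    else rep(NA_character_, length(gr))
  mol <- if (!is.null(md$molecule_type)) as.character(md$molecule_type)
    else rep("other", length(gr))
  mol[is.na(mol) | !nzchar(mol)] <- "other"
  nm <- if (!is.null(md$gene_name)) as.character(md$gene_name)
    else rep("", length(gr))
  nm[is.na(nm)] <- ""
  out <- granges(gr, use.mcols = FALSE)
  mcols(out) <- S4Vectors::DataFrame(
    gene_id = as.character(md$gene_id),
    gene_name = nm,
    biotype = map_biotype(as.character(biotype_raw)),
    molecule_type = mol)
  out
}

#' Transcription start sites as 0-based offsets
#'
#' For a plus-strand gene the TSS is its first base; for a minus-strand
#' gene, its last. Returned on the 0-based scale (a gene occupying BED
#' interval \[1000, 2000) on the minus strand has its TSS at 1999).
#'
#' @param genes gene `GRanges` with strand
#' @return integer vector of 0-based TSS offsets
#' @export
tss_positions <- function(genes) {
  ifelse(as.character(strand(genes)) == "-", end(genes) - 1L,
         start(genes) - 1L)
}

#' Merge an interval set into disjoint sorted intervals
#'
#' Union of the input, ignoring strand; abutting intervals merge (the
#' half-open BED intervals \[0,10) and \[10,20) become \[0,20)). Idempotent.
#'
#' @param gr a `GRanges`
#' @return reduced, sorted `GRanges`
#' @export
merge_intervals <- function(gr) {
  GenomicRanges::reduce(sort(gr, ignore.strand = TRUE), ignore.strand = TRUE)
}

#' Total genomic length of an interval set in bp
#' @param gr a `GRanges` (merged internally)
#' @return integer bp
#' @export
interval_total_length <- function(gr) {
  sum(as.numeric(width(merge_intervals(gr))))
}

#' Length of the intersection of two interval sets
#'
#' Symmetric; both sides are merged first so duplicated or overlapping
#' input intervals are not double counted.
#'
#' @param a,b `GRanges`
#' @return intersection length in bp
#' @export
overlap_length <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(0)
  sum(as.numeric(width(GenomicRanges::intersect(
    merge_intervals(a), merge_intervals(b), ignore.strand = TRUE))))
}
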