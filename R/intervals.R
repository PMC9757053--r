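#' Read a chrom.sizes file
#'
#' Two-column, tab-separated: chromosome name and length in nucleotides.
#'
#' @param path Path to a chrom.sizes file.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "integer"))
  if (any(df$length <= 0)) stop("chromosome lengths must be positive")
  stats::setNames(df$length, df$chrom)
}

#' Write a chrom.sizes file
#'
#' @param genome Named vector of chromosome lengths.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(genome, path) {
  utils::write.table(
    data.frame(names(genome),
               format(unname(genome), scientific = FALSE, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read genomic intervals from a BED file
#'
#' BED3/BED6, 0-based half-open on disk; returned as a `GRanges`
#' (1-based closed, the Bioconductor convention). When `genome` is given its
#' chromosome lengths are attached as seqlengths and intervals are validated
#' against them.
#'
#' @param path Path to a BED file.
#' @param genome Optional named vector of chromosome lengths.
#' @return A `GRanges`.
#' @export
read_bed <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(genome)) gr <- set_genome(gr, genome)
  gr
}

#' Write genomic intervals to a BED file
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Attach a genome (chromosome lengths) to a GRanges
#'
#' @param gr A `GRanges`.
#' @param genome Named vector of chromosome lengths.
#' @return `gr` with seqlengths set; errors if any interval exceeds its
#'   chromosome bounds.
#' @export
set_genome <- function(gr, genome) {
  chroms <- unique(as.character(GenomeInfoDb::seqnames(gr)))
  missing <- setdiff(chroms, names(genome))
  if (length(missing) > 0)
    stop("chromosomes absent from genome: ", paste(missing, collapse = ", "))
  GenomeInfoDb::seqlevels(gr) <- names(genome)
  GenomeInfoDb::seqlengths(gr) <- unname(genome)
  bad <- BiocGenerics::end(gr) > genome[as.character(GenomeInfoDb::seqnames(gr))]
  if (any(bad))
    stop("interval(s) beyond chromosome end: ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  gr
}

.validate_intervals <- function(gr) {
  bad <- BiocGenerics::width(gr) < 1L
  if (any(bad))
    stop("malformed interval(s) with start >= end at index: ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  invisible(gr)
}

#' Merge (normalize) an interval set
#'
#' Sorts and collapses overlapping intervals; book-ended intervals (one ending
#' exactly where the next starts) are merged as well, matching the default of
#' the standard BED merge tool.
#'
#' @param gr A `GRanges`.
#' @return A sorted, non-overlapping `GRanges` covering the same bases.
#' @export
merge_intervals <- function(gr) {
  .validate_intervals(gr)
  GenomicRanges::reduce(gr, ignore.strand = TRUE)
}

#' Subtract one interval set from another
#'
#' @param gr A `GRanges`.
#' @param exclude A `GRanges` whose bases are removed from `gr`.
#' @return Merged `GRanges` of bases covered by `gr` but not `exclude`.
#' @export
subtract_regions <- function(gr, exclude) {
  GenomicRanges::setdiff(merge_intervals(gr), merge_intervals(exclude),
                         ignore.strand = TRUE)
}

#' Flanking regions of an interval set
#'
#' Extends each interval by `width` nucleotides on both sides (flanks only,
#' not the interval itself), truncates at chromosome bounds, merges, and
#' removes any base overlapping `exclude`. This mirrors the
#' flank-then-subtract construction used for mutation-rate comparisons of
#' binding sites and exons against their neighbourhoods.
#'
#' @param gr A `GRanges` with seqlengths set (see [set_genome()]).
#' @param width Flank width in nucleotides (typically 100, 500 or 1000).
#' @param exclude A `GRanges` of regions to remove from the flanks (commonly
#'   the binding sites and exons themselves). Defaults to `gr`.
#' @return Merged `GRanges` of flanking bases sharing no base with `exclude`.
#' @export
flank_regions <- function(gr, width, exclude = gr) {
  stopifnot(width > 0)
  if (any(is.na(GenomeInfoDb::seqlengths(gr))))
    stop("genome lengths missing; call set_genome() so flanks can be bounded")
  # flanks may momentarily exceed chromosome bounds; trim() is the intent
  fl <- suppressWarnings({
    left <- GenomicRanges::flank(gr, width, start = TRUE,
                                 ignore.strand = TRUE)
    right <- GenomicRanges::flank(gr, width, start = FALSE,
                                  ignore.strand = TRUE)
    GenomicRanges::trim(c(left, right))
  })
  fl <- fl[BiocGenerics::width(fl) > 0]
  subtract_regions(fl, exclude)
}

# GRanges of the reference span of each mutation. Insertions occupy the 1-nt
# anchor base; SNVs and deletions span nchar(ref) bases from pos.
mutation_ranges <- function(muts, genome = NULL) {
  span <- ifelse(muts$variant_class == "insertion", 1L, nchar(muts$ref))
  gr <- GenomicRanges::GRanges(muts$chrom,
                               IRanges::IRanges(muts$pos, width = span))
  if (!is.null(genome)) gr <- set_genome(gr, genome)
  gr
}

#' Intersect mutations with an interval set
#'
#' A mutation is kept when any base of its reference span (insertions: the
#' 1-nt anchor base) overlaps the set. Input order is preserved; the operation
#' is idempotent. Mutations on chromosomes with no intervals in `gr` are
#' simply dropped (reported once per chromosome).
#'
#' @param muts Mutation data frame (see [read_mutations()]).
#' @param gr A normalized `GRanges`.
#' @return The subset of `muts` overlapping `gr`.
#' @export
intersect_mutations <- function(muts, gr) {
  if (nrow(muts) == 0) return(muts)
  mr <- mutation_ranges(muts)
  absent <- setdiff(unique(muts$chrom),
                    unique(as.character(GenomeInfoDb::seqnames(gr))))
  if (length(absent) > 0)
    message("mutations on chromosome(s) absent from interval set dropped: ",
            paste(absent, collapse = ", "))
  keep <- suppressWarnings(IRanges::overlapsAny(mr, gr, ignore.strand = TRUE))
  muts[keep, , drop = FALSE]
}

#' Shuffle mutations within chromosomes
#'
#' Draws, for each mutation, a new uniform position on its own chromosome
#' while preserving the per-chromosome mutation counts, the variant classes
#' and the reference-span lengths (so indels never run off chromosome ends).
#' Used to build the random expectation for region mutation rates.
#'
#' @param muts Mutation data frame.
#' @param genome Named vector of chromosome lengths covering all chromosomes
#'   present in `muts`.
#' @param seed Integer seed; the shuffle is deterministic given the seed.
#' @return A mutation data frame with new positions.
#' @export
shuffle_mutations <- function(muts, genome, seed) {
  absent <- setdiff(unique(muts$chrom), names(genome))
  if (length(absent) > 0)
    stop("chromosome(s) absent from genome: ", paste(absent, collapse = ", "))
  out <- muts
  if (nrow(muts) == 0) return(out)
  span <- ifelse(muts$variant_class == "insertion", 1L, nchar(muts$ref))
  len <- genome[muts$chrom]
  if (any(span > len)) stop("reference span exceeds chromosome length")
  seed_rng(seed)
  out$pos <- 1L + as.integer(floor(stats::runif(nrow(muts)) * (len - span + 1)))
  out
}

seed_rng <- function(seed) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  invisible(NULL)
}

#' Closest transcription start site for each interval
#'
#' Distance is 0 when a TSS lies inside the interval, otherwise the minimum of
#' the distances to the interval's two end bases. Ties are broken
#' deterministically by lowest TSS coordinate, then lexicographic gene id.
#'
#' @param gr Query intervals (`GRanges`).
#' @param tss TSS table: data frame with columns `gene_id`, `chrom`, `pos`
#'   (1-based), and optionally `strand` and `gene_class`.
#' @return Character vector of gene ids, `NA` where the interval's chromosome
#'   has no TSS (reported, not fatal).
#' @export
closest_tss <- function(gr, tss) {
  n <- length(gr)
  res <- rep(NA_character_, n)
  qc <- as.character(GenomeInfoDb::seqnames(gr))
  qs <- BiocGenerics::start(gr)
  qe <- BiocGenerics::end(gr)
  for (chrom in unique(qc)) {
    idx <- which(qc == chrom)
    tt <- tss[tss$chrom == chrom, , drop = FALSE]
    if (nrow(tt) == 0) next
    ord <- order(tt$pos, tt$gene_id)
    tt <- tt[ord, , drop = FALSE]
    for (i in idx) {
      d <- ifelse(tt$pos >= qs[i] & tt$pos <= qe[i], 0L,
                  pmin(abs(tt$pos - qs[i]), abs(tt$pos - qe[i])))
      res[i] <- tt$gene_id[which.min(d)]  # ties: first in (pos, gene_id) order
    }
  }
  if (anyNA(res))
    message(sum(is.na(res)), " interval(s) on chromosome(s) without a TSS ",
            "left unassigned")
  res
}

#' Total length of an interval set
#'
#' @param gr A `GRanges`; merged first so overlapping bases count once.
#' @return Total number of covered bases.
#' @export
total_length <- function(gr) {
  sum(BiocGenerics::width(merge_intervals(gr)))
}
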