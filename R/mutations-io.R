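#' Read somatic mutations from a tab-separated file
#'
#' Expected header columns: `sample_id`, `chrom`, `pos_1based`, `ref`, `alt`
#' and optionally `consequence` (controlled term for exonic calls). Positions
#' are 1-based on disk and kept 1-based internally (the R/Bioconductor
#' convention). The variant class is derived from the alleles: equal-length
#' 1-nt alleles are SNVs, longer ref than alt a deletion, shorter an
#' insertion.
#'
#' @param path Path to the mutation TSV.
#' @param genome Optional named vector of chromosome lengths, used to validate
#'   positions.
#' @return Data frame with columns `sample_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `variant_class`, `consequence`.
#' @export
read_mutations <- function(path, genome = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  need <- c("sample_id", "chrom", "pos_1based", "ref", "alt")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("mutation file missing column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(sample_id = df$sample_id,
                    chrom = df$chrom,
                    pos = as.integer(df$pos_1based),
                    ref = df$ref,
                    alt = df$alt,
                    consequence = if ("consequence" %in% names(df))
                      df$consequence else NA_character_,
                    stringsAsFactors = FALSE)
  out$variant_class <- variant_class(out$ref, out$alt)
  validate_mutations(out, genome)
}

#' Classify variants from their alleles
#'
#' @param ref,alt Character vectors of reference and alternate alleles.
#' @return `"SNV"`, `"insertion"` or `"deletion"` per record.
#' @export
variant_class <- function(ref, alt) {
  nr <- nchar(ref)
  na <- nchar(alt)
  ifelse(nr == 1L & na == 1L, "SNV",
         ifelse(na > nr, "insertion", "deletion"))
}

validate_mutations <- function(muts, genome = NULL) {
  snv <- muts$variant_class == "SNV"
  if (any(snv & (nchar(muts$ref) != 1L | nchar(muts$alt) != 1L)))
    stop("SNV with multi-nucleotide alleles")
  if (any(muts$pos < 1L)) stop("mutation position < 1")
  if (!is.null(genome)) {
    absent <- setdiff(unique(muts$chrom), names(genome))
    if (length(absent) > 0)
      stop("mutation chromosome(s) absent from genome: ",
           paste(absent, collapse = ", "))
    span <- ifelse(muts$variant_class == "insertion", 1L, nchar(muts$ref))
    if (any(muts$pos + span - 1L > genome[muts$chrom]))
      stop("mutation reference span beyond chromosome end")
  }
  muts
}

#' Write mutations as TSV
#'
#' Inverse of [read_mutations()]: positions written 1-based under the
#' `pos_1based` header.
#'
#' @param muts Mutation data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutations <- function(muts, path) {
  out <- data.frame(sample_id = muts$sample_id, chrom = muts$chrom,
                    pos_1based = muts$pos, ref = muts$ref, alt = muts$alt,
                    consequence = muts$consequence)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read mutations from a minimal VCF
#'
#' Accepts single-nucleotide and small-indel records from a VCF 4.x file
#' carrying the originating sample in a `SAMPLE` INFO key. Multi-sample
#' genotype columns and symbolic alleles are out of scope.
#'
#' @param path Path to an (uncompressed) VCF.
#' @param genome Optional named vector of chromosome lengths for validation.
#' @return Mutation data frame as from [read_mutations()].
#' @export
read_mutations_vcf <- function(path, genome = NULL) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("VariantAnnotation is required to read VCF input")
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  info <- VariantAnnotation::info(vcf)
  if (is.null(info$SAMPLE))
    stop("VCF lacks the SAMPLE INFO key carrying the sample id")
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- as.character(unlist(VariantAnnotation::alt(vcf)))
  if (length(alt) != length(vcf))
    stop("multi-allelic VCF records are not supported")
  out <- data.frame(sample_id = as.character(info$SAMPLE),
                    chrom = as.character(GenomeInfoDb::seqnames(rr)),
                    pos = BiocGenerics::start(rr),
                    ref = as.character(VariantAnnotation::ref(vcf)),
                    alt = alt,
                    consequence = NA_character_,
                    stringsAsFactors = FALSE)
  out$variant_class <- variant_class(out$ref, out$alt)
  validate_mutations(out, genome)
}
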