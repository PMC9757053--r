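# Fixed whitelist of loss-of-function consequence terms: nonsense,
# frameshift, and splice-site classes.
lof_terms <- c("disruptive in-frame deletion", "disruptive in-frame insertion",
               "stop gained", "start lost", "stop lost",
               "stop retained variant",
               "frameshift variant", "initiator codon variant",
               "splice region variant", "splice donor variant",
               "splice acceptor variant")

#' Is a consequence term loss-of-function?
#'
#' Matches against the fixed 11-term whitelist of nonsense, frameshift and
#' splice-site consequences; matching is case- and underscore-insensitive.
#' Unknown terms are simply not LoF.
#'
#' @param consequence Character vector of consequence terms.
#' @return Logical vector.
#' @export
classify_lof <- function(consequence) {
  norm <- tolower(gsub("_", " ", trimws(consequence)))
  out <- norm %in% lof_terms
  out[is.na(consequence)] <- FALSE
  out
}

#' Read a TSS table
#'
#' Tab-separated with header `gene_id`, `chrom`, `pos_1based`, `strand` and
#' optionally `gene_class` (`protein_coding` or `miRNA`). Several TSSs per
#' gene are allowed.
#'
#' @param path Path to the TSV.
#' @return Data frame with columns `gene_id`, `chrom`, `pos`, `strand`,
#'   `gene_class`.
#' @export
read_tss_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  out <- data.frame(gene_id = df$gene_id, chrom = df$chrom,
                    pos = as.integer(df$pos_1based),
                    strand = if ("strand" %in% names(df)) df$strand else ".",
                    gene_class = if ("gene_class" %in% names(df))
                      df$gene_class else NA_character_,
                    stringsAsFactors = FALSE)
  if (any(is.na(out$pos))) stop("non-numeric TSS position")
  out
}

#' Read a regulatory element to gene association map
#'
#' BED-like TSV: `chrom`, `start` (0-based), `end`, and a comma-separated
#' gene-list column. An element may be linked to several genes.
#'
#' @param path Path to the file.
#' @return `GRanges` with a `genes` list-column.
#' @export
read_element_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "genes"),
                          colClasses = c("character", "integer", "integer",
                                         "character"))
  if (any(df$start >= df$end)) stop("malformed element interval (start >= end)")
  genes <- strsplit(df$genes, ",", fixed = TRUE)
  if (any(lengths(genes) == 0)) stop("element with empty gene list")
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end))
  S4Vectors::mcols(gr)$genes <- genes
  gr
}

#' Associate TFBSs with genes
#'
#' A TFBS overlapping one or more annotated cis-regulatory elements is
#' linked to all genes of those elements (element associations take
#' priority); a TFBS overlapping no element is linked to the single gene
#' with the closest TSS, pooling protein-coding and miRNA TSSs. TFBSs that
#' can be assigned to no gene are flagged with a reported count.
#'
#' @param tfbs `GRanges` of binding sites.
#' @param elements Element map from [read_element_map()] (or `NULL` to use
#'   closest-TSS assignment only).
#' @param tss TSS table from [read_tss_table()].
#' @return List of character vectors, one per TFBS (possibly empty =
#'   unassigned); attribute `via` records `"element"` or `"tss"` per TFBS.
#' @export
assign_tfbs_to_genes <- function(tfbs, elements, tss) {
  n <- length(tfbs)
  genes <- vector("list", n)
  via <- rep(NA_character_, n)
  if (!is.null(elements) && length(elements) > 0) {
    hits <- GenomicRanges::findOverlaps(tfbs, elements, ignore.strand = TRUE)
    if (length(hits) > 0) {
      qh <- S4Vectors::queryHits(hits)
      eg <- S4Vectors::mcols(elements)$genes[S4Vectors::subjectHits(hits)]
      for (i in unique(qh)) {
        genes[[i]] <- sort(unique(unlist(eg[qh == i])))
        via[i] <- "element"
      }
    }
  }
  rest <- which(is.na(via))
  if (length(rest) > 0) {
    cg <- suppressMessages(closest_tss(tfbs[rest], tss))
    for (j in seq_along(rest)) {
      if (!is.na(cg[j])) {
        genes[[rest[j]]] <- cg[j]
        via[rest[j]] <- "tss"
      }
    }
  }
  unassigned <- sum(lengths(genes) == 0)
  if (unassigned > 0)
    message(unassigned, " TFBS(s) could not be assigned to any gene")
  attr(genes, "via") <- via
  genes
}

#' Gene-sample pairs from TFBS mutations
#'
#' Intersects mutations with binding sites and propagates each hit to the
#' genes the binding site is assigned to.
#'
#' @param muts Mutation data frame.
#' @param tfbs `GRanges` of binding sites.
#' @param tfbs_genes Per-TFBS gene lists from [assign_tfbs_to_genes()].
#' @return Data frame with columns `gene`, `sample_id` (unique pairs).
#' @export
tfbs_mutation_pairs <- function(muts, tfbs, tfbs_genes) {
  if (nrow(muts) == 0)
    return(data.frame(gene = character(), sample_id = character()))
  mr <- mutation_ranges(muts)
  hits <- GenomicRanges::findOverlaps(mr, tfbs, ignore.strand = TRUE)
  if (length(hits) == 0)
    return(data.frame(gene = character(), sample_id = character()))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  reps <- lengths(tfbs_genes[sh])
  pairs <- data.frame(gene = unlist(tfbs_genes[sh]),
                      sample_id = rep(muts$sample_id[qh], reps),
                      stringsAsFactors = FALSE)
  unique(pairs)
}

#' Gene-sample pairs from loss-of-function mutations
#'
#' Keeps mutations whose consequence is in the LoF whitelist
#' ([classify_lof()]) and assigns them to genes by exon overlap.
#'
#' @param muts Mutation data frame with a `consequence` column.
#' @param exons `GRanges` of exons whose `name` metadata column carries the
#'   gene id.
#' @return Data frame with columns `gene`, `sample_id` (unique pairs).
#' @export
lof_mutation_pairs <- function(muts, exons) {
  keep <- classify_lof(muts$consequence)
  muts <- muts[keep, , drop = FALSE]
  if (nrow(muts) == 0)
    return(data.frame(gene = character(), sample_id = character()))
  mr <- mutation_ranges(muts)
  hits <- GenomicRanges::findOverlaps(mr, exons, ignore.strand = TRUE)
  if (length(hits) == 0)
    return(data.frame(gene = character(), sample_id = character()))
  pairs <- data.frame(
    gene = S4Vectors::mcols(exons)$name[S4Vectors::subjectHits(hits)],
    sample_id = muts$sample_id[S4Vectors::queryHits(hits)],
    stringsAsFactors = FALSE)
  unique(pairs)
}

#' Expand pre-miRNA gene ids to mature 5p/3p arms
#'
#' A cis mutation mapped to a pre-miRNA TSS marks both mature arms as
#' mutated; each arm is analysed separately downstream against its own
#' target network and expression.
#'
#' @param pairs Gene-sample pair data frame whose `gene` ids are pre-miRNA
#'   names.
#' @return Pair data frame with each row duplicated for the `-5p` and `-3p`
#'   arms.
#' @export
expand_mirna_arms <- function(pairs) {
  if (nrow(pairs) == 0) return(pairs)
  out <- rbind(transform(pairs, gene = paste0(gene, "-5p")),
               transform(pairs, gene = paste0(gene, "-3p")))
  rownames(out) <- NULL
  unique(out)
}

#' Build a binary gene x sample mutation matrix
#'
#' An entry is 1 iff at least one qualifying mutation links the gene to the
#' sample. For the protein-coding cis-regulatory channel
#' (`channel = "cis_protein_coding"`) an entry additionally requires the
#' gene to be potentially dysregulated in that sample (z-value strictly
#' below -1 or above 1); LoF and miRNA cis entries carry no z filter. Genes
#' or samples absent from the z matrix are dropped with a warning.
#'
#' @param pairs Gene-sample pair data frame.
#' @param samples Character vector of all cohort sample ids (matrix columns).
#' @param channel One of `"lof"`, `"cis_protein_coding"`, `"cis_mirna"`.
#' @param z z-value matrix (required for `"cis_protein_coding"`, forbidden
#'   otherwise).
#' @return Binary integer matrix, genes (with >= 1 entry) x samples.
#' @export
build_mutation_matrix <- function(pairs, samples,
                                  channel = c("lof", "cis_protein_coding",
                                              "cis_mirna"),
                                  z = NULL) {
  channel <- match.arg(channel)
  if (channel == "cis_protein_coding" && is.null(z))
    stop("channel 'cis_protein_coding' requires the z-value matrix")
  if (channel != "cis_protein_coding" && !is.null(z))
    stop("z matrix supplied for a channel that does not use it")
  pairs <- pairs[pairs$sample_id %in% samples, , drop = FALSE]
  if (channel == "cis_protein_coding") {
    known <- pairs$gene %in% rownames(z) & pairs$sample_id %in% colnames(z)
    if (any(!known))
      warning(sum(!known), " pair(s) with gene/sample absent from ",
              "expression dropped")
    pairs <- pairs[known, , drop = FALSE]
    fl <- z_flags(z)
    keep <- fl[cbind(match(pairs$gene, rownames(z)),
                     match(pairs$sample_id, colnames(z)))]
    pairs <- pairs[keep, , drop = FALSE]
  }
  genes <- sort(unique(pairs$gene))
  m <- matrix(0L, nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  if (nrow(pairs) > 0)
    m[cbind(match(pairs$gene, genes), match(pairs$sample_id, samples))] <- 1L
  m
}

#' Write a binary mutation matrix as sparse triplets
#'
#' @param m Binary matrix.
#' @param path Output path; rows are `gene`, `sample`, `1`.
#' @return `path`, invisibly.
#' @export
write_mutation_matrix <- function(m, path) {
  idx <- which(m == 1L, arr.ind = TRUE)
  out <- data.frame(gene = rownames(m)[idx[, 1]],
                    sample = colnames(m)[idx[, 2]],
                    value = 1L)
  out <- out[order(out$gene, out$sample), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
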