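#' Read a weighted edge list
#'
#' Tab-separated with header `source`, `partner`, `weight`. The source side
#' is the (potentially mutated) gene; the partner side is observed in
#' expression.
#'
#' @param path Path to the TSV.
#' @return Data frame with columns `source`, `partner`, `weight`.
#' @export
read_network <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character", "numeric"))
  validate_network(df)
}

#' Write a weighted edge list
#'
#' @param net Network data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  utils::write.table(net, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_network <- function(net) {
  stopifnot(all(c("source", "partner", "weight") %in% names(net)))
  if (any(net$weight <= 0 | net$weight > 1))
    stop("edge weights must lie in (0, 1]")
  if (anyDuplicated(net[c("source", "partner")]))
    stop("duplicate (source, partner) edges")
  net
}

#' Read a miRNA target table
#'
#' Tab-separated with header `mirna`, `target`, `n_sites`,
#' `t_score_percentile`.
#'
#' @param path Path to the TSV.
#' @return Data frame of target records.
#' @export
read_mirna_targets <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "character", "integer",
                                   "numeric"))
}

#' Build the miRNA-target network
#'
#' Targets supported by fewer than two predicted binding sites are filtered
#' out (false-positive control) and edge weights are the target-site context
#' score percentile divided by 100; zero-weight edges are dropped.
#'
#' @param records Data frame with columns `mirna`, `target`, `n_sites`,
#'   `t_score_percentile`.
#' @return Network data frame (`source` = mature miRNA, `partner` = target).
#' @export
build_mirna_network <- function(records) {
  if (any(records$t_score_percentile < 0 | records$t_score_percentile > 100))
    stop("t_score percentile outside [0, 100]")
  if (any(records$n_sites < 1)) stop("n_sites must be >= 1")
  keep <- records$n_sites >= 2 & records$t_score_percentile > 0
  net <- data.frame(source = records$mirna[keep],
                    partner = records$target[keep],
                    weight = records$t_score_percentile[keep] / 100,
                    stringsAsFactors = FALSE)
  validate_network(unique(net))
}

#' Update network weights from cohort differential expression
#'
#' For each source gene with at least two mutated and two non-mutated
#' samples, each partner's expression is compared between the two groups by
#' a two-sided Wilcoxon rank-sum test, with Benjamini-Hochberg adjustment
#' across that gene's partners (optionally across all genes). If any partner
#' is differentially expressed at the adjusted level `alpha`, those
#' partners' weights are set to 1 and the gene's other partners are dropped;
#' otherwise the original edges and weights are kept unchanged.
#'
#' @param net Network data frame.
#' @param mut_matrix Binary gene x sample mutation matrix.
#' @param expr Normalized expression matrix (partners x samples).
#' @param alpha Adjusted-p level for differential expression (default 0.05).
#' @param adjust One of `"per_gene"` (default) or `"global"`: scope of the
#'   BH adjustment.
#' @return Updated network data frame.
#' @export
update_weights <- function(net, mut_matrix, expr, alpha = 0.05,
                           adjust = c("per_gene", "global")) {
  adjust <- match.arg(adjust)
  samples <- colnames(expr)
  if (!all(colnames(mut_matrix) %in% samples))
    stop("mutation-matrix samples absent from expression")
  pvals <- rep(NA_real_, nrow(net))
  testable_src <- character(0)
  for (g in intersect(unique(net$source), rownames(mut_matrix))) {
    mut_s <- samples[samples %in%
                       colnames(mut_matrix)[mut_matrix[g, ] == 1L]]
    non_s <- setdiff(samples, mut_s)
    if (length(mut_s) < 2 || length(non_s) < 2) next
    rows <- which(net$source == g)
    for (i in rows) {
      p <- net$partner[i]
      if (!p %in% rownames(expr)) next
      pvals[i] <- suppressWarnings(
        stats::wilcox.test(expr[p, mut_s], expr[p, non_s],
                           alternative = "two.sided")$p.value)
    }
    testable_src <- c(testable_src, g)
  }
  padj <- rep(NA_real_, nrow(net))
  if (adjust == "global") {
    padj[!is.na(pvals)] <- stats::p.adjust(pvals[!is.na(pvals)], "BH")
  } else {
    for (g in testable_src) {
      rows <- which(net$source == g & !is.na(pvals))
      padj[rows] <- stats::p.adjust(pvals[rows], "BH")
    }
  }
  keep <- rep(TRUE, nrow(net))
  weight <- net$weight
  for (g in testable_src) {
    rows <- which(net$source == g)
    de <- !is.na(padj[rows]) & padj[rows] <= alpha
    if (any(de)) {
      weight[rows[de]] <- 1
      keep[rows[!de]] <- FALSE
    }
  }
  out <- net
  out$weight <- weight
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Shuffle a network for the empirical null
#'
#' Keeps the original number of edges and each source gene's degree, but
#' refills the partner slots by uniform sampling without replacement from the
#' partner universe and permutes the multiset of connection weights globally
#' over the edges. Deterministic given the seed.
#'
#' @param net Network data frame.
#' @param seed Integer seed.
#' @param partner_universe Candidate partners (default: all distinct partners
#'   in `net`).
#' @return Shuffled network data frame.
#' @export
shuffle_network <- function(net, seed, partner_universe = NULL) {
  if (is.null(partner_universe)) partner_universe <- unique(net$partner)
  deg <- table(net$source)
  if (any(deg > length(partner_universe)))
    stop("source degree exceeds partner universe size")
  seed_rng(seed)
  src_order <- unique(net$source)
  partners <- unlist(lapply(src_order, function(g) {
    partner_universe[sample.int(length(partner_universe), deg[[g]])]
  }))
  out <- data.frame(source = rep(src_order, deg[src_order]),
                    partner = partners,
                    weight = net$weight[sample.int(nrow(net))],
                    stringsAsFactors = FALSE)
  validate_network(out)
}

#' Shuffle a mutation matrix for the empirical null
#'
#' Permutes the gene labels of the rows: the per-sample mutation burden
#' structure and the total number of mutated (gene, sample) pairs are
#' preserved exactly. Deterministic given the seed.
#'
#' @param m Binary mutation matrix.
#' @param seed Integer seed.
#' @return Matrix with permuted row labels (rows re-sorted by the new
#'   labels).
#' @export
shuffle_mutation_matrix <- function(m, seed) {
  seed_rng(seed)
  perm <- sample(nrow(m))
  rownames(m) <- rownames(m)[perm]
  m[order(rownames(m)), , drop = FALSE]
}

#' Connected components induced by a gene set
#'
#' Builds the undirected subgraph of the network induced on `genes` and
#' returns its connected components; components of two or more genes
#' (subnetworks) are counted separately from isolated genes.
#'
#' @param genes Character vector of (e.g. predicted) genes.
#' @param net Network data frame.
#' @return List with `membership` (named vector), `sizes`,
#'   `n_components_ge2`, `n_isolated`.
#' @export
induced_subgraphs <- function(genes, net) {
  genes <- unique(genes)
  e <- net[net$source %in% genes & net$partner %in% genes, , drop = FALSE]
  e <- e[e$source != e$partner, , drop = FALSE]
  g <- igraph::graph_from_data_frame(e[c("source", "partner")],
                                     directed = FALSE,
                                     vertices = data.frame(name = genes))
  comp <- igraph::components(g)
  list(membership = comp$membership,
       sizes = as.integer(comp$csize),
       n_components_ge2 = sum(comp$csize >= 2),
       n_isolated = sum(comp$csize == 1))
}
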