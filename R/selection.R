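#' Selection configuration
#'
#' @param fdr_level Empirical FDR level for the DAC threshold (default 0.05).
#' @param n_controls Number of shuffled controls (default 100).
#' @param dac_floor Minimum DAC threshold; if the FDR-derived threshold is
#'   below it, the floor is used (default 0.5).
#' @param ssd_min Minimum per-sample SSD counting as support (default 0.5).
#' @param min_ssd_samples Minimum number of supporting samples (default 2).
#' @param grs_min Minimum |GRS| for a partner to appear in dysregulation
#'   tables (default 0.5).
#' @return List of class `"selection_config"`.
#' @export
selection_config <- function(fdr_level = 0.05, n_controls = 100,
                             dac_floor = 0.5, ssd_min = 0.5,
                             min_ssd_samples = 2, grs_min = 0.5) {
  stopifnot(fdr_level > 0, fdr_level < 1, n_controls >= 1,
            dac_floor > 0, dac_floor < 1, ssd_min > 0, ssd_min < 1,
            min_ssd_samples >= 1, grs_min > 0, grs_min < 1)
  structure(list(fdr_level = fdr_level, n_controls = n_controls,
                 dac_floor = dac_floor, ssd_min = ssd_min,
                 min_ssd_samples = min_ssd_samples, grs_min = grs_min),
            class = "selection_config")
}

#' Empirical FDR threshold on DAC
#'
#' For every candidate threshold t in the grid of observed DAC values, the
#' FDR estimate is the mean number of null DACs at or above t per control,
#' divided by the number of observed DACs at or above t. The threshold is
#' the smallest grid value achieving the configured FDR level, floored at
#' `dac_floor`; when no grid value achieves the level, `Inf` is returned and
#' nothing can be selected.
#'
#' @param observed_dac Numeric vector of observed DAC values.
#' @param control_dacs List of numeric vectors, one per shuffled control.
#' @param cfg A [selection_config()].
#' @return The DAC threshold t (possibly `Inf`), with attribute `fdr_curve`.
#' @export
fdr_threshold <- function(observed_dac, control_dacs,
                          cfg = selection_config()) {
  observed_dac <- observed_dac[!is.na(observed_dac)]
  if (length(observed_dac) == 0) stop("empty observed DAC list")
  nulls <- lapply(control_dacs, function(x) x[!is.na(x)])
  grid <- sort(unique(observed_dac))
  fdr <- vapply(grid, function(t) {
    null_exceed <- mean(vapply(nulls, function(x) sum(x >= t), numeric(1)))
    null_exceed / max(1, sum(observed_dac >= t))
  }, numeric(1))
  ok <- which(fdr <= cfg$fdr_level)
  t <- if (length(ok) == 0) Inf else max(grid[min(ok)], cfg$dac_floor)
  attr(t, "fdr_curve") <- data.frame(threshold = grid, fdr = fdr)
  t
}

#' Select predicted genes
#'
#' A gene is selected when its DAC is at or above the threshold and its SSD
#' is at or above `ssd_min` in at least `min_ssd_samples` samples.
#'
#' @param fit A [dysnet()] fit.
#' @param t DAC threshold from [fdr_threshold()].
#' @param cfg A [selection_config()].
#' @return Character vector of selected genes.
#' @export
select_genes <- function(fit, t, cfg = selection_config()) {
  tab <- summary(fit, ssd_min = cfg$ssd_min)
  tab$gene[!is.na(tab$dac) & tab$dac >= t &
             tab$n_ssd_samples >= cfg$min_ssd_samples]
}

#' Selection report table
#'
#' @param fit A [dysnet()] fit.
#' @param t DAC threshold.
#' @param cfg A [selection_config()].
#' @return Data frame `gene`, `dac`, `t`, `n_ssd_samples`, `selected`.
#' @export
selection_report <- function(fit, t, cfg = selection_config()) {
  tab <- summary(fit, ssd_min = cfg$ssd_min)
  tab$t <- as.numeric(t)
  tab$selected <- !is.na(tab$dac) & tab$dac >= t &
    tab$n_ssd_samples >= cfg$min_ssd_samples
  tab[c("gene", "dac", "t", "n_ssd_samples", "selected")]
}

#' Dysregulation table for one predicted gene
#'
#' Columns are the gene's mutated samples; rows are network partners whose
#' |GRS| reaches `grs_min` in at least one mutated sample whose SSD reaches
#' `ssd_min`. Cell values are GRS signed by direction (negative for
#' downregulation), the quantity shown in dysregulation heatmaps.
#'
#' @param fit A [dysnet()] fit.
#' @param gene A gene present in the fit.
#' @param cfg A [selection_config()].
#' @return Numeric matrix (possibly 0-row) with sample columns.
#' @export
dysregulation_table <- function(fit, gene, cfg = selection_config()) {
  if (!gene %in% names(fit$dac)) stop("gene not in fit: ", gene)
  s <- colnames(fit$mut_matrix)[fit$mut_matrix[gene, ] == 1L]
  p <- intersect(fit$net$partner[fit$net$source == gene], rownames(fit$grs))
  m <- fit$grs[p, s, drop = FALSE]
  ssd <- fit$ssd[fit$ssd$gene == gene, ]
  ssd_ok <- s %in% ssd$sample[ssd$ssd >= cfg$ssd_min]
  keep <- rowSums(abs(m[, ssd_ok, drop = FALSE]) >= cfg$grs_min) > 0
  m[keep, , drop = FALSE]
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' Probability of observing at least `k` category members among `n` draws
#' without replacement from a universe of size `N` containing `K` category
#' members. Computed through the stable log-space tail of the
#' hypergeometric distribution.
#'
#' @param k Observed hits.
#' @param K Category size in the universe.
#' @param n Number of draws (e.g. predicted genes).
#' @param N Universe size.
#' @return The p-value `P(X >= k)`.
#' @export
hypergeometric_enrichment <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || k > min(K, n) || K > N || n > N)
    stop("inconsistent hypergeometric counts")
  if (k == 0) return(1)
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Enrichment of predicted genes in annotated categories
#'
#' One hypergeometric upper-tail test per category (e.g. known
#' cancer-associated genes, transcription factors), BH-adjusted across
#' categories.
#'
#' @param genes Character vector of predicted genes (draws).
#' @param categories Named list of character vectors (the annotated sets).
#' @param universe Character vector of all candidate genes.
#' @return Data frame with `category`, `hits`, `category_size`, `n_genes`,
#'   `universe_size`, `p`, `p_adj`.
#' @export
enrichment_report <- function(genes, categories, universe) {
  genes <- intersect(unique(genes), universe)
  out <- do.call(rbind, lapply(names(categories), function(nm) {
    cat_set <- intersect(unique(categories[[nm]]), universe)
    data.frame(category = nm,
               hits = length(intersect(genes, cat_set)),
               category_size = length(cat_set),
               n_genes = length(genes),
               universe_size = length(universe),
               stringsAsFactors = FALSE)
  }))
  out$p <- mapply(hypergeometric_enrichment, out$hits, out$category_size,
                  out$n_genes, out$universe_size)
  out$p_adj <- bh_adjust(out$p)
  out
}

#' Benjamini-Hochberg adjustment
#'
#' @param p Numeric vector of p-values.
#' @return BH step-up adjusted p-values.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Median-split Kaplan-Meier log-rank test
#'
#' Samples with expression strictly above the median form the `high` group,
#' the rest (ties included) the `low` group; the two survival curves are
#' compared by the standard log-rank test.
#'
#' @param expr_values Named numeric vector of per-sample expression.
#' @param surv Data frame with columns `sample_id`, `time`, `event`
#'   (1 = event, 0 = censored).
#' @return List with `groups` (named factor), `chi2`, `p`, and the
#'   `survival::survdiff` fit.
#' @export
km_logrank <- function(expr_values, surv) {
  if (any(surv$time < 0)) stop("negative survival times")
  common <- intersect(names(expr_values), surv$sample_id)
  v <- expr_values[common]
  surv <- surv[match(common, surv$sample_id), ]
  med <- stats::median(v)
  grp <- factor(ifelse(v > med, "high", "low"), levels = c("low", "high"))
  if (any(table(grp) < 2))
    stop("a group has fewer than 2 samples after the median split")
  sd <- survival::survdiff(survival::Surv(surv$time, surv$event) ~ grp)
  chi2 <- sd$chisq
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  list(groups = stats::setNames(grp, common), chi2 = chi2, p = p, fit = sd)
}

#' Read a survival table
#'
#' @param path TSV with header `sample_id`, `time`, `event`.
#' @return Data frame.
#' @export
read_survival <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "numeric", "integer"))
  if (any(df$time < 0)) stop("negative survival times")
  df
}

#' Per-sample mutation rates in regions and flanks, with shuffle nulls
#'
#' For every sample, the mutation rate in a region set is the number of
#' distinct mutated reference positions inside the (merged) set divided by
#' the set's total length; an indel contributes the overlapping part of its
#' reference span. Rates are reported for TFBSs, exons, and their flanks at
#' the given widths (flanks exclude all TFBS and exonic bases), together
#' with the mean rates over chromosome-preserving mutation shuffles and the
#' cohort-level paired two-tailed Wilcoxon signed-rank test comparing TFBS
#' and exon rates across samples.
#'
#' @param muts Mutation data frame.
#' @param tfbs,exons `GRanges` of binding sites / exons.
#' @param genome Named vector of chromosome lengths.
#' @param flank_widths Flank widths in nt (default 100, 500, 1000).
#' @param n_shuffles Number of mutation shuffles for the random expectation
#'   (default 150; 0 skips the expected-rate columns).
#' @param seed Master seed for the shuffles.
#' @param samples Optional character vector of cohort sample ids; defaults
#'   to the samples present in `muts`. Samples without mutations get zero
#'   rates and are excluded from the paired test with a warning.
#' @return List with `rates` (long data frame sample/region/rate/
#'   expected_rate), `region_lengths`, and `wilcoxon_p` (TFBS vs exon).
#' @export
mutation_rate_report <- function(muts, tfbs, exons, genome,
                                 flank_widths = c(100, 500, 1000),
                                 n_shuffles = 150, seed = 1,
                                 samples = NULL) {
  tfbs <- merge_intervals(set_genome(tfbs, genome))
  exons <- merge_intervals(set_genome(exons, genome))
  if (length(tfbs) == 0 || length(exons) == 0) stop("empty region set")
  excl <- merge_intervals(c(tfbs, exons))
  regions <- list(tfbs = tfbs, exon = exons)
  for (w in flank_widths) {
    regions[[paste0("tfbs_flank_", w)]] <- flank_regions(tfbs, w, excl)
    regions[[paste0("exon_flank_", w)]] <- flank_regions(exons, w, excl)
  }
  lens <- vapply(regions, total_length, numeric(1))

  if (is.null(samples)) samples <- sort(unique(muts$sample_id))

  # flatten each merged region set to per-chromosome boundary vectors so
  # the shuffle iterations can count in plain vectorized R (no per-shuffle
  # S4 object construction)
  flatten <- function(region) {
    ch <- as.character(GenomeInfoDb::seqnames(region))
    lapply(split(seq_along(region), ch), function(i)
      list(start = BiocGenerics::start(region)[i],
           end = BiocGenerics::end(region)[i]))
  }
  flat <- lapply(regions, flatten)

  # distinct mutated reference positions per sample inside a region set;
  # an indel contributes the overlapping part of its span
  rate_in <- function(sample_id, chrom, pos, span, flat_region) {
    p <- rep.int(pos, span) + sequence(span) - 1L
    ch <- rep.int(chrom, span)
    sm <- rep.int(sample_id, span)
    dup <- duplicated(paste0(sm, "\r", ch, "\r", p))
    if (any(dup)) {
      p <- p[!dup]; ch <- ch[!dup]; sm <- sm[!dup]
    }
    inside <- logical(length(p))
    for (cc in unique(ch)) {
      fr <- flat_region[[cc]]
      if (is.null(fr)) next
      idx <- which(ch == cc)
      i <- findInterval(p[idx], fr$start)
      inside[idx] <- i > 0 & p[idx] <= fr$end[pmax(i, 1L)]
    }
    tab <- table(factor(sm[inside], levels = samples))
    stats::setNames(as.numeric(tab), samples)
  }

  span <- ifelse(muts$variant_class == "insertion", 1L, nchar(muts$ref))
  counts <- lapply(flat, function(fr)
    rate_in(muts$sample_id, muts$chrom, muts$pos, span, fr))
  rates <- lapply(names(regions), function(nm) counts[[nm]] / lens[[nm]])
  names(rates) <- names(regions)

  expected <- NULL
  if (n_shuffles > 0) {
    acc <- lapply(regions, function(r) rep(0, length(samples)))
    for (i in seq_len(n_shuffles)) {
      sh <- shuffle_mutations(muts, genome, seed = seed + i)
      for (nm in names(regions))
        acc[[nm]] <- acc[[nm]] +
          rate_in(sh$sample_id, sh$chrom, sh$pos, span, flat[[nm]]) /
          lens[[nm]]
    }
    expected <- lapply(acc, function(x) x / n_shuffles)
  }

  long <- do.call(rbind, lapply(names(regions), function(nm) {
    data.frame(sample_id = samples, region = nm, rate = unname(rates[[nm]]),
               expected_rate = if (is.null(expected)) NA_real_ else
                 unname(expected[[nm]]),
               stringsAsFactors = FALSE)
  }))

  has_mut <- samples %in% muts$sample_id
  if (any(!has_mut))
    warning(sum(!has_mut), " sample(s) without mutations excluded from the ",
            "paired test")
  x <- rates$tfbs[has_mut]
  y <- rates$exon[has_mut]
  wp <- if (all(x == y)) 1 else
    suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                        alternative = "two.sided")$p.value)
  list(rates = long, region_lengths = lens, wilcoxon_p = wp)
}
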