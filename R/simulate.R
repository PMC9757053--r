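#' Simulation configuration for synthetic cohorts
#'
#' Defaults describe a small but realistic whole-genome cohort: 60 samples,
#' 200 protein-coding genes and 20 pre-miRNAs laid out on two 1-Mb
#' chromosomes, three binding sites per gene, five planted cis-regulatory
#' driver genes each mutated in eight samples, 70% of each driver's 20
#' network partners shifted by two neutral standard deviations, negative
#' binomial baseline counts, sparse copy-number alterations, and
#' exponential survival linked to one designated miRNA.
#'
#' @param seed Master seed; one seed reproduces every emitted file.
#' @param chrom_lengths Named vector of chromosome lengths (nt).
#' @param n_samples,n_genes,n_mirnas Cohort dimensions.
#' @param tfbs_per_gene Binding sites placed per gene.
#' @param tfbs_length_range Min/max TFBS length (nt).
#' @param element_fraction Fraction of TFBSs covered by an element-gene
#'   record (the rest resolve by closest TSS).
#' @param n_planted_drivers Number of planted protein-coding drivers.
#' @param n_planted_mirna_drivers Number of planted miRNA-arm drivers.
#' @param mutated_samples_per_driver Mutated samples per planted driver.
#' @param partner_count Network degree of each source gene.
#' @param effect_size Partner shift in units of the neutral (baseline)
#'   within-gene sd of log2 cpm.
#' @param fraction_partners_affected Fraction of a driver's partners that
#'   are shifted.
#' @param direction_mix Probability an affected partner is shifted up.
#' @param driver_cis_shift Shift the driver's own expression in its mutated
#'   samples (the cis consequence of a regulatory mutation), enabling the
#'   z-value prefilter to see it.
#' @param background_mutation_rate Background mutations per nt per sample.
#' @param cna_alteration_rate Probability a (gene, sample) CNA entry is
#'   non-zero.
#' @param nb_dispersion Negative binomial dispersion of baseline counts.
#' @param count_meanlog,count_sdlog Log-normal parameters of per-gene mean
#'   counts.
#' @param fraction_unexpressed Fraction of genes (and miRNA arms) drawn from
#'   a lowly-expressed mode, reproducing the bimodal low/high structure of
#'   real expression data that the expressed-gene mixture filter relies on.
#'   Planted drivers are always drawn from the expressed mode.
#' @param unexpressed_factor Mean-count scaling of the lowly-expressed mode.
#' @param weight_range Range of simulated network edge weights.
#' @param mirna_targets_per_arm Candidate target records per mature arm.
#' @param surv_beta Log-hazard slope on the designated miRNA's standardized
#'   expression.
#' @param surv_base_time Baseline mean survival time (days).
#' @param null_mode Disable all planted effects and the survival link.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1,
                       chrom_lengths = c(chr1 = 1e6, chr2 = 1e6),
                       n_samples = 60, n_genes = 200, n_mirnas = 20,
                       tfbs_per_gene = 3, tfbs_length_range = c(8, 20),
                       element_fraction = 0.5,
                       n_planted_drivers = 5, n_planted_mirna_drivers = 0,
                       mutated_samples_per_driver = 8,
                       partner_count = 20, effect_size = 2,
                       fraction_partners_affected = 0.7,
                       direction_mix = 0.5, driver_cis_shift = TRUE,
                       background_mutation_rate = 1e-5,
                       cna_alteration_rate = 0.02,
                       nb_dispersion = 0.2,
                       count_meanlog = log(200), count_sdlog = 1,
                       fraction_unexpressed = 0.15,
                       unexpressed_factor = 0.02,
                       weight_range = c(0.3, 1),
                       mirna_targets_per_arm = 30,
                       surv_beta = 0.5, surv_base_time = 1000,
                       null_mode = FALSE) {
  cfg <- as.list(environment())
  stopifnot(all(cfg$chrom_lengths > 0), n_samples > 0, n_genes > 0,
            effect_size >= 0,
            fraction_partners_affected >= 0, fraction_partners_affected <= 1,
            direction_mix >= 0, direction_mix <= 1,
            element_fraction >= 0, element_fraction <= 1)
  structure(cfg, class = "sim_config")
}

#' Simulate genome annotation
#'
#' Lays out non-overlapping gene and pre-miRNA loci with TSSs along the
#' chromosomes, places binding sites either inside a distal regulatory
#' element linked to the gene (an `element_fraction` of them) or within
#' 2 kb upstream of the gene's TSS (resolved later by closest TSS), and
#' builds the exon catalog. Deterministic given the config seed.
#'
#' @param cfg A [sim_config()].
#' @return List with `genome`, `tfbs` (`GRanges`, `name` = site id), `exons`
#'   (`GRanges`, `name` = gene), `tss` (data frame), `elements` (`GRanges`
#'   with `genes`), `gene_ids`, `mirna_ids`, `tfbs_gene` (ground-truth gene
#'   per site).
#' @export
simulate_annotation <- function(cfg) {
  seed_rng(cfg$seed * 13L + 1L)
  n_loci <- cfg$n_genes + cfg$n_mirnas
  genome <- cfg$chrom_lengths
  prop <- genome / sum(genome)
  n_per <- diff(round(c(0, cumsum(prop * n_loci))))
  spacing <- floor((genome - 10000) / pmax(n_per, 1))
  if (any(spacing < 6000 & n_per > 0))
    stop("genome too small: need at least ",
         6000 * n_loci + 10000 * length(genome), " nt for ", n_loci, " loci")
  gene_ids <- sprintf("g%03d", seq_len(cfg$n_genes))
  mirna_ids <- sprintf("mir%02d", seq_len(cfg$n_mirnas))
  ids <- sample(c(gene_ids, mirna_ids))  # interleave classes along the genome
  chrom <- rep(names(genome), n_per)
  offset <- unlist(lapply(seq_along(genome), function(i) {
    5000 + spacing[i] * (seq_len(n_per[i]) - 1)
  }))
  tss <- data.frame(gene_id = ids, chrom = chrom, pos = as.integer(offset),
                    strand = "+",
                    gene_class = ifelse(ids %in% gene_ids, "protein_coding",
                                        "miRNA"),
                    stringsAsFactors = FALSE)

  is_pc <- tss$gene_class == "protein_coding"
  exon_starts <- c(0, 600, 1200)
  exons <- GenomicRanges::GRanges(
    rep(tss$chrom[is_pc], each = length(exon_starts)),
    IRanges::IRanges(rep(tss$pos[is_pc], each = length(exon_starts)) +
                       rep(exon_starts, sum(is_pc)), width = 200))
  S4Vectors::mcols(exons)$name <- rep(tss$gene_id[is_pc],
                                      each = length(exon_starts))
  pre_mirna <- GenomicRanges::GRanges(
    tss$chrom[!is_pc], IRanges::IRanges(tss$pos[!is_pc], width = 120))
  S4Vectors::mcols(pre_mirna)$name <- tss$gene_id[!is_pc]

  n_tfbs <- n_loci * cfg$tfbs_per_gene
  owner_idx <- rep(seq_len(n_loci), each = cfg$tfbs_per_gene)
  via_element <- stats::runif(n_tfbs) < cfg$element_fraction
  len <- sample(seq(cfg$tfbs_length_range[1], cfg$tfbs_length_range[2]),
                n_tfbs, replace = TRUE)
  # element path: site inside a distal element 3.5-4 kb upstream of the TSS;
  # TSS path: site within 2 kb upstream (own TSS is then the closest)
  up <- ifelse(via_element,
               3500 + floor(stats::runif(n_tfbs) * (500 - len)),
               50 + floor(stats::runif(n_tfbs) * (1950 - len)))
  start <- pmax(1L, as.integer(tss$pos[owner_idx] - up - len))
  tfbs <- GenomicRanges::GRanges(tss$chrom[owner_idx],
                                 IRanges::IRanges(start, width = len))
  S4Vectors::mcols(tfbs)$name <- sprintf("site%04d", seq_len(n_tfbs))
  tfbs <- set_genome(tfbs, genome)

  el_owner <- unique(owner_idx[via_element])
  elements <- NULL
  if (length(el_owner) > 0) {
    elements <- GenomicRanges::GRanges(
      tss$chrom[el_owner],
      IRanges::IRanges(pmax(1L, as.integer(tss$pos[el_owner] - 4100)),
                       as.integer(tss$pos[el_owner] - 3400)))
    S4Vectors::mcols(elements)$genes <- as.list(tss$gene_id[el_owner])
  }
  list(genome = genome, tfbs = tfbs, exons = exons, pre_mirna = pre_mirna,
       tss = tss, elements = elements, gene_ids = gene_ids,
       mirna_ids = mirna_ids, tfbs_gene = tss$gene_id[owner_idx],
       tfbs_via_element = via_element)
}

#' Simulate gene-gene and miRNA-target networks
#'
#' Every protein-coding gene becomes a source with `partner_count` partners
#' drawn uniformly from the other genes, with weights uniform on
#' `weight_range`; each mature miRNA arm gets candidate target records with
#' 1-4 predicted sites and context-score percentiles, from which
#' [build_mirna_network()] derives the weighted arm-target network.
#'
#' @param cfg A [sim_config()].
#' @param ann Annotation from [simulate_annotation()].
#' @return List with `protein` (network data frame) and `mirna_records`
#'   (target record data frame).
#' @export
simulate_networks <- function(cfg, ann) {
  seed_rng(cfg$seed * 13L + 2L)
  genes <- ann$gene_ids
  deg <- min(cfg$partner_count, length(genes) - 1)
  protein <- do.call(rbind, lapply(genes, function(g) {
    partners <- sample(setdiff(genes, g), deg)
    data.frame(source = g, partner = partners,
               weight = stats::runif(deg, cfg$weight_range[1],
                                     cfg$weight_range[2]),
               stringsAsFactors = FALSE)
  }))
  arms <- as.vector(outer(ann$mirna_ids, c("-5p", "-3p"), paste0))
  mirna_records <- do.call(rbind, lapply(arms, function(a) {
    targets <- sample(genes, min(cfg$mirna_targets_per_arm, length(genes)))
    data.frame(mirna = a, target = targets,
               n_sites = sample(1:4, length(targets), replace = TRUE,
                                prob = c(0.3, 0.4, 0.2, 0.1)),
               t_score_percentile = round(stats::runif(length(targets),
                                                       30, 100), 1),
               stringsAsFactors = FALSE)
  }))
  list(protein = validate_network(protein), mirna_records = mirna_records)
}

#' Simulate a cohort with planted cis-regulatory drivers
#'
#' Baseline counts are negative binomial with log-normal per-gene means.
#' Each planted driver gets one mutation placed uniformly inside one of its
#' own binding sites in each of its designated mutated samples; the
#' affected fraction of its network partners is shifted on the log2 scale
#' by plus/minus `effect_size` neutral standard deviations (applied to the
#' counts as a multiplicative factor so the emitted files stay in count
#' space), and, when `driver_cis_shift` is set, the driver's own expression
#' is shifted likewise. Background mutations are scattered uniformly at the
#' configured per-nt rate (exonic ones receive consequence terms, a
#' fraction of them loss-of-function). The CNA matrix is mostly zero;
#' survival times are exponential with log-hazard linear in the designated
#' miRNA arm's standardized expression. `null_mode` suppresses every
#' planted effect and the hazard link.
#'
#' @param cfg A [sim_config()].
#' @param ann Annotation from [simulate_annotation()].
#' @param nets Networks from [simulate_networks()].
#' @return List with `mutations`, `counts`, `mirna_counts`, `cna`,
#'   `survival`, `truth`, `samples`.
#' @export
simulate_cohort <- function(cfg, ann, nets) {
  seed_rng(cfg$seed * 13L + 3L)
  samples <- sprintf("S%03d", seq_len(cfg$n_samples))
  G <- cfg$n_genes
  S <- cfg$n_samples

  lowly <- function(n) {
    low <- stats::runif(n) < cfg$fraction_unexpressed
    mu <- stats::rlnorm(n, cfg$count_meanlog, cfg$count_sdlog)
    mu[low] <- stats::rlnorm(sum(low), cfg$count_meanlog +
                               log(cfg$unexpressed_factor), 0.5)
    list(mu = mu, low = low)
  }
  bg <- lowly(G)
  mu_g <- bg$mu
  expressed_genes <- ann$gene_ids[!bg$low]
  counts <- matrix(stats::rnbinom(G * S, mu = rep(mu_g, S),
                                  size = 1 / cfg$nb_dispersion),
                   nrow = G, dimnames = list(ann$gene_ids, samples))
  arms <- as.vector(outer(ann$mirna_ids, c("-5p", "-3p"), paste0))
  bm <- lowly(length(arms))
  mirna_counts <- matrix(stats::rnbinom(length(arms) * S,
                                        mu = rep(bm$mu, S),
                                        size = 1 / cfg$nb_dispersion),
                         nrow = length(arms),
                         dimnames = list(arms, samples))
  expressed_arms <- arms[!bm$low]
  if (length(expressed_arms) == 0) expressed_arms <- arms
  # neutral per-gene sd on the log2 cpm scale, from the baseline counts
  base_l2 <- cpm_log2(counts + 0L)
  sd_g <- apply(base_l2, 1, stats::sd)

  drivers <- character(0)
  mirna_drivers <- character(0)
  mut_rows <- list()
  truth_samples <- list()
  truth_partners <- list()

  plant <- function(driver, owner_gene, partners_df) {
    mut_s <- sample(samples, cfg$mutated_samples_per_driver)
    site_idx <- which(ann$tfbs_gene == owner_gene)
    if (length(site_idx) == 0) stop("driver has no linked TFBS: ", owner_gene)
    k <- round(cfg$fraction_partners_affected * nrow(partners_df))
    aff <- partners_df$partner[seq_len(k)]
    dirs <- ifelse(stats::runif(k) < cfg$direction_mix, 1L, -1L)
    cis_dir <- if (stats::runif(1) < cfg$direction_mix) 1L else -1L
    for (s in mut_s) {
      site <- site_idx[sample.int(length(site_idx), 1)]
      st <- BiocGenerics::start(ann$tfbs)[site]
      en <- BiocGenerics::end(ann$tfbs)[site]
      pos <- st + sample.int(en - st + 1L, 1) - 1L
      mut_rows[[length(mut_rows) + 1]] <<- data.frame(
        sample_id = s, chrom = as.character(
          GenomeInfoDb::seqnames(ann$tfbs))[site],
        pos = pos, ref = "C", alt = "T", consequence = NA_character_,
        variant_class = "SNV", stringsAsFactors = FALSE)
      for (j in seq_len(k)) {
        p <- aff[j]
        counts[p, s] <<- round(counts[p, s] * 2^(dirs[j] * cfg$effect_size *
                                                   sd_g[p]))
      }
      if (cfg$driver_cis_shift && owner_gene %in% rownames(counts))
        counts[owner_gene, s] <<- round(counts[owner_gene, s] *
                                          2^(cis_dir * cfg$effect_size *
                                               sd_g[owner_gene]))
    }
    truth_samples[[length(truth_samples) + 1]] <<- data.frame(
      driver = driver, sample = mut_s, stringsAsFactors = FALSE)
    truth_partners[[length(truth_partners) + 1]] <<- data.frame(
      driver = driver, partner = aff, direction = dirs,
      stringsAsFactors = FALSE)
    invisible(NULL)
  }

  if (!cfg$null_mode && cfg$n_planted_drivers > 0) {
    drivers <- sort(sample(expressed_genes, cfg$n_planted_drivers))
    for (d in drivers)
      plant(d, d, nets$protein[nets$protein$source == d, , drop = FALSE])
  }
  if (!cfg$null_mode && cfg$n_planted_mirna_drivers > 0) {
    arm_net <- build_mirna_network(nets$mirna_records)
    cand <- intersect(unique(arm_net$source), expressed_arms)
    mirna_drivers <- sort(sample(cand, cfg$n_planted_mirna_drivers))
    for (d in mirna_drivers) {
      pre <- sub("-[53]p$", "", d)
      plant(d, pre, arm_net[arm_net$source == d, , drop = FALSE])
    }
  }

  # background mutations, uniform over the genome
  genome <- ann$genome
  glen <- sum(genome)
  n_bg <- stats::rpois(S, cfg$background_mutation_rate * glen)
  for (i in seq_len(S)) {
    if (n_bg[i] == 0) next
    gpos <- ceiling(stats::runif(n_bg[i]) * glen)
    cum <- cumsum(genome)
    ci <- findInterval(gpos - 1, c(0, cum[-length(cum)]))
    pos <- gpos - c(0, cum)[ci]
    is_indel <- stats::runif(n_bg[i]) < 0.1
    span <- ifelse(is_indel, sample(2:5, n_bg[i], replace = TRUE), 1L)
    ref <- strrep("A", span)
    alt <- ifelse(is_indel, "A", "G")
    mut_rows[[length(mut_rows) + 1]] <- data.frame(
      sample_id = samples[i], chrom = names(genome)[ci],
      pos = pmax(1L, pmin(as.integer(pos), as.integer(genome[ci] - span + 1L))),
      ref = ref, alt = alt, consequence = NA_character_,
      variant_class = ifelse(is_indel, "deletion", "SNV"),
      stringsAsFactors = FALSE)
  }
  muts <- do.call(rbind, mut_rows)
  if (is.null(muts))
    muts <- data.frame(sample_id = character(), chrom = character(),
                       pos = integer(), ref = character(), alt = character(),
                       consequence = character(), variant_class = character())
  rownames(muts) <- NULL
  # annotate exonic background mutations with consequence terms
  exonic <- IRanges::overlapsAny(mutation_ranges(muts), ann$exons,
                                 ignore.strand = TRUE) &
    is.na(muts$consequence)
  if (any(exonic)) {
    muts$consequence[exonic] <- sample(
      c("missense variant", "synonymous variant", "stop gained",
        "frameshift variant"),
      sum(exonic), replace = TRUE, prob = c(0.55, 0.2, 0.15, 0.1))
  }
  muts <- muts[order(muts$sample_id, muts$chrom, muts$pos), ]
  rownames(muts) <- NULL

  cna <- matrix(0L, G, S, dimnames = list(ann$gene_ids, samples))
  alter <- stats::runif(G * S) < cfg$cna_alteration_rate
  cna[alter] <- sample(c(-2L, -1L, 1L, 2L), sum(alter), replace = TRUE)

  surv_arm <- expressed_arms[1]
  zm <- as.numeric(scale(log2(edgeR::cpm(mirna_counts)[surv_arm, ] + 1)))
  beta <- if (cfg$null_mode) 0 else cfg$surv_beta
  haz <- exp(beta * zm) / cfg$surv_base_time
  t_ev <- stats::rexp(S, rate = haz)
  t_cn <- stats::runif(S, 0.5, 1.5) * cfg$surv_base_time
  surv <- data.frame(sample_id = samples,
                     time = round(pmin(t_ev, t_cn), 1),
                     event = as.integer(t_ev <= t_cn),
                     stringsAsFactors = FALSE)

  truth <- list(
    drivers = c(drivers, mirna_drivers),
    mutated_samples = do.call(rbind, c(truth_samples, list(
      data.frame(driver = character(), sample = character())))),
    partners = do.call(rbind, c(truth_partners, list(
      data.frame(driver = character(), partner = character(),
                 direction = integer())))),
    surv_arm = surv_arm)
  list(mutations = muts, counts = counts, mirna_counts = mirna_counts,
       cna = cna, survival = surv, truth = truth, samples = samples)
}

#' Write ground truth as TSV
#'
#' Machine-readable truth for driver-recovery scoring; [read_truth()]
#' restores it losslessly.
#'
#' @param truth Truth component of [simulate_cohort()] output.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
emit_truth <- function(truth, path) {
  ms <- truth$mutated_samples
  pt <- truth$partners
  block <- function(record, driver, sample = "", partner = "",
                    direction = NA_integer_) {
    n <- length(driver)
    data.frame(record = rep(record, n), driver = driver,
               sample = rep_len(sample, n), partner = rep_len(partner, n),
               direction = rep_len(direction, n))
  }
  rows <- rbind(
    block("driver", truth$drivers),
    block("mutated_sample", ms$driver, sample = ms$sample),
    block("affected_partner", pt$driver, partner = pt$partner,
          direction = pt$direction),
    block("surv_arm", truth$surv_arm))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read ground truth written by [emit_truth()]
#'
#' @param path Path to the truth TSV.
#' @return Truth list (`drivers`, `mutated_samples`, `partners`,
#'   `surv_arm`).
#' @export
read_truth <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character",
                                         "character", "character", "integer"))
  list(drivers = df$driver[df$record == "driver"],
       mutated_samples = data.frame(
         driver = df$driver[df$record == "mutated_sample"],
         sample = df$sample[df$record == "mutated_sample"],
         stringsAsFactors = FALSE),
       partners = data.frame(
         driver = df$driver[df$record == "affected_partner"],
         partner = df$partner[df$record == "affected_partner"],
         direction = df$direction[df$record == "affected_partner"],
         stringsAsFactors = FALSE),
       surv_arm = df$driver[df$record == "surv_arm"])
}

#' Simulate a full synthetic study
#'
#' @param cfg A [sim_config()].
#' @return List with `annotation`, `networks`, `cohort` and the `config`.
#' @export
simulate_study <- function(cfg = sim_config()) {
  ann <- simulate_annotation(cfg)
  nets <- simulate_networks(cfg, ann)
  cohort <- simulate_cohort(cfg, ann, nets)
  list(annotation = ann, networks = nets, cohort = cohort, config = cfg)
}

#' Write a simulated study to a directory
#'
#' Emits every file the pipeline reads: `genome.chrom.sizes`, `tfbs.bed`,
#' `exons.bed`, `tss.tsv`, `elements.tsv`, `network.tsv`,
#' `mirna_targets.tsv`, `mutations.tsv`, `counts.tsv`, `mirna_counts.tsv`,
#' `cna.tsv`, `survival.tsv`, `truth.tsv`, `config.yaml`.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- study$annotation
  write_chrom_sizes(ann$genome, file.path(dir, "genome.chrom.sizes"))
  write_bed(ann$tfbs, file.path(dir, "tfbs.bed"))
  write_bed(ann$exons, file.path(dir, "exons.bed"))
  tss_out <- data.frame(gene_id = ann$tss$gene_id, chrom = ann$tss$chrom,
                        pos_1based = ann$tss$pos, strand = ann$tss$strand,
                        gene_class = ann$tss$gene_class)
  utils::write.table(tss_out, file.path(dir, "tss.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(ann$elements)) {
    el <- data.frame(
      chrom = as.character(GenomeInfoDb::seqnames(ann$elements)),
      start = BiocGenerics::start(ann$elements) - 1L,
      end = BiocGenerics::end(ann$elements),
      genes = vapply(S4Vectors::mcols(ann$elements)$genes,
                     paste, character(1), collapse = ","))
    utils::write.table(el, file.path(dir, "elements.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  write_network(study$networks$protein, file.path(dir, "network.tsv"))
  utils::write.table(study$networks$mirna_records,
                     file.path(dir, "mirna_targets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  co <- study$cohort
  write_mutations(co$mutations, file.path(dir, "mutations.tsv"))
  write_expression(co$counts, file.path(dir, "counts.tsv"), "gene")
  write_expression(co$mirna_counts, file.path(dir, "mirna_counts.tsv"),
                   "mirna")
  write_expression(co$cna, file.path(dir, "cna.tsv"), "gene")
  utils::write.table(co$survival, file.path(dir, "survival.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  emit_truth(co$truth, file.path(dir, "truth.tsv"))
  yaml::write_yaml(unclass(study$config), file.path(dir, "config.yaml"))
  invisible(dir)
}
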