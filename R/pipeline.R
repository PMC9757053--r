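#' Assemble a pipeline run configuration
#'
#' Accepts a named list or a YAML file path and fills defaults. Fields:
#' `cohort_dir` (directory of input files, as written by
#' [pipeline_simulate()]), `out_dir`, `channel` (`"cis_protein_coding"`,
#' `"cis_mirna"` or `"lof"`), `seed`, `n_controls`, `fdr_level`,
#' `dac_floor`, `ssd_min`, `min_ssd_samples`, `grs_min`, `priors` (named
#' list for [dysnet_priors()]), `prenormalized`, `skip_expressed_filter`,
#' `update_network_weights`, `use_cna`.
#'
#' @param config Named list or YAML path.
#' @return Completed configuration list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(cohort_dir = NULL, out_dir = NULL,
                   channel = "cis_protein_coding", seed = 1,
                   n_controls = 100, fdr_level = 0.05, dac_floor = 0.5,
                   ssd_min = 0.5, min_ssd_samples = 2, grs_min = 0.5,
                   priors = list(), prenormalized = FALSE,
                   skip_expressed_filter = FALSE,
                   update_network_weights = TRUE, use_cna = TRUE,
                   flank_widths = c(100, 500, 1000), n_shuffles = 150)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  out <- utils::modifyList(defaults, config)
  if (is.null(out$cohort_dir)) stop("config field 'cohort_dir' is required")
  if (!out$channel %in% c("cis_protein_coding", "cis_mirna", "lof"))
    stop("invalid channel: ", out$channel)
  out
}

#' Simulate a synthetic study and write it to disk
#'
#' @param cfg A [sim_config()] (or named list of its fields).
#' @param out_dir Output directory.
#' @return Invisibly, the simulated study object (with `$dir` set).
#' @export
pipeline_simulate <- function(cfg = sim_config(), out_dir) {
  if (!inherits(cfg, "sim_config")) cfg <- do.call(sim_config, cfg)
  study <- simulate_study(cfg)
  write_study(study, out_dir)
  study$dir <- out_dir
  invisible(study)
}

read_cohort_inputs <- function(dir, channel) {
  genome <- read_chrom_sizes(file.path(dir, "genome.chrom.sizes"))
  inputs <- list(
    genome = genome,
    muts = read_mutations(file.path(dir, "mutations.tsv"), genome),
    counts = read_expression(file.path(dir, "counts.tsv")),
    tss = read_tss_table(file.path(dir, "tss.tsv")),
    tfbs = read_bed(file.path(dir, "tfbs.bed"), genome),
    exons = read_bed(file.path(dir, "exons.bed"), genome))
  ep <- file.path(dir, "elements.tsv")
  inputs$elements <- if (file.exists(ep)) read_element_map(ep) else NULL
  cp <- file.path(dir, "cna.tsv")
  inputs$cna <- if (file.exists(cp)) read_cna(cp) else NULL
  if (channel == "cis_mirna") {
    inputs$mirna_counts <- read_expression(file.path(dir, "mirna_counts.tsv"))
    inputs$mirna_targets <- read_mirna_targets(
      file.path(dir, "mirna_targets.tsv"))
  } else {
    inputs$network <- read_network(file.path(dir, "network.tsv"))
  }
  inputs
}

#' Run the full dysregulation analysis on a cohort directory
#'
#' Executes preprocessing (zero-gene filter, cpm/log2, expressed-gene
#' mixture filter), mutation-to-gene mapping for the selected channel,
#' network weight updating, the hierarchical model fit, the shuffled-control
#' empirical FDR, and gene selection; writes `dac.tsv`, `ssd.tsv`,
#' `grs.tsv`, `selection.tsv` and `manifest.json` to `out_dir` when one is
#' configured. Two runs with identical configuration and seed produce
#' byte-identical result files.
#'
#' @param config See [pipeline_config()].
#' @return List with `fit`, `control_dacs`, `t` (realized DAC threshold),
#'   `report`, `selected`, `config`.
#' @export
pipeline_run <- function(config) {
  cfg <- pipeline_config(config)
  inp <- read_cohort_inputs(cfg$cohort_dir, cfg$channel)
  sel_cfg <- selection_config(fdr_level = cfg$fdr_level,
                              n_controls = cfg$n_controls,
                              dac_floor = cfg$dac_floor,
                              ssd_min = cfg$ssd_min,
                              min_ssd_samples = cfg$min_ssd_samples,
                              grs_min = cfg$grs_min)
  priors <- do.call(dysnet_priors, cfg$priors)

  expr <- if (cfg$prenormalized) inp$counts else
    cpm_log2(filter_zero_genes(inp$counts))
  if (!cfg$skip_expressed_filter)
    expr <- expr[expressed_gene_filter(expr), , drop = FALSE]
  samples <- colnames(expr)

  pc_ids <- inp$tss$gene_id[inp$tss$gene_class == "protein_coding"]
  mir_ids <- inp$tss$gene_id[inp$tss$gene_class == "miRNA"]

  if (cfg$channel == "lof") {
    pairs <- lof_mutation_pairs(inp$muts, inp$exons)
    mat <- build_mutation_matrix(pairs, samples, "lof")
    net <- inp$network
  } else {
    tfbs_genes <- assign_tfbs_to_genes(inp$tfbs, inp$elements, inp$tss)
    pairs <- tfbs_mutation_pairs(inp$muts, inp$tfbs, tfbs_genes)
    if (cfg$channel == "cis_protein_coding") {
      pairs <- pairs[pairs$gene %in% pc_ids, , drop = FALSE]
      mat <- build_mutation_matrix(pairs, samples, "cis_protein_coding",
                                   z = z_values(expr))
      net <- inp$network
    } else {
      pairs <- pairs[pairs$gene %in% mir_ids, , drop = FALSE]
      pairs <- expand_mirna_arms(pairs)
      mexpr <- if (cfg$prenormalized) inp$mirna_counts else
        cpm_log2(filter_zero_genes(inp$mirna_counts))
      if (!cfg$skip_expressed_filter)
        mexpr <- mexpr[expressed_gene_filter(mexpr), , drop = FALSE]
      pairs <- pairs[pairs$gene %in% rownames(mexpr), , drop = FALSE]
      mat <- build_mutation_matrix(pairs, samples, "cis_mirna")
      net <- build_mirna_network(inp$mirna_targets)
    }
  }

  if (nrow(mat) == 0) {
    res <- list(fit = NULL, control_dacs = list(), t = Inf,
                report = data.frame(gene = character(), dac = numeric(),
                                    t = numeric(), n_ssd_samples = integer(),
                                    selected = logical()),
                selected = character(0), config = cfg)
    if (!is.null(cfg$out_dir)) write_pipeline_results(res, cfg)
    return(res)
  }

  if (cfg$update_network_weights)
    net <- update_weights(net, mat, expr)
  cna <- if (cfg$use_cna) inp$cna else NULL
  fit <- suppressWarnings(dysnet(mat, expr, net, cna = cna, priors = priors))
  controls <- dysnet_controls(fit, n_controls = cfg$n_controls,
                              seed = cfg$seed)
  t <- fdr_threshold(stats::na.omit(fit$dac), controls, sel_cfg)
  report <- selection_report(fit, t, sel_cfg)
  res <- list(fit = fit, control_dacs = controls, t = as.numeric(t),
              report = report, selected = report$gene[report$selected],
              config = cfg)
  if (!is.null(cfg$out_dir)) write_pipeline_results(res, cfg)
  res
}

write_pipeline_results <- function(res, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(channel = cfg$channel, seed = cfg$seed,
                   n_controls = cfg$n_controls, fdr_level = cfg$fdr_level,
                   dac_threshold = res$t,
                   n_selected = length(res$selected))
  if (!is.null(res$fit)) {
    write_dysnet_results(res$fit, cfg$out_dir, manifest = manifest)
  } else {
    jsonlite::write_json(
      c(manifest,
        list(package_version = as.character(utils::packageVersion("dysnet")))),
      file.path(cfg$out_dir, "manifest.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  rep <- res$report
  rep$dac <- round(rep$dac, 10)  # stabilize text output across platforms
  utils::write.table(rep, file.path(cfg$out_dir, "selection.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(cfg$out_dir)
}

#' Mutation-rate analysis on a cohort directory
#'
#' Wraps [mutation_rate_report()] over the cohort's mutation calls, binding
#' sites and exons; writes `rates.tsv` and `rates_summary.json` when an
#' output directory is configured.
#'
#' @param config See [pipeline_config()]; uses `flank_widths` and
#'   `n_shuffles`.
#' @return The [mutation_rate_report()] result.
#' @export
pipeline_rates <- function(config) {
  cfg <- pipeline_config(config)
  genome <- read_chrom_sizes(file.path(cfg$cohort_dir, "genome.chrom.sizes"))
  muts <- read_mutations(file.path(cfg$cohort_dir, "mutations.tsv"), genome)
  tfbs <- read_bed(file.path(cfg$cohort_dir, "tfbs.bed"), genome)
  exons <- read_bed(file.path(cfg$cohort_dir, "exons.bed"), genome)
  rep <- mutation_rate_report(muts, tfbs, exons, genome,
                              flank_widths = cfg$flank_widths,
                              n_shuffles = cfg$n_shuffles, seed = cfg$seed)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(rep$rates, file.path(cfg$out_dir, "rates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(wilcoxon_p_tfbs_vs_exon = rep$wilcoxon_p,
                              region_lengths = as.list(rep$region_lengths)),
                         file.path(cfg$out_dir, "rates_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  rep
}
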