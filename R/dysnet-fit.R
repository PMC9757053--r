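#' Priors of the hierarchical dysregulation model
#'
#' The model is two-level: a cohort-level indicator D (the gene's mutations
#' are functional, prior `pi_d`) and, per mutated sample, a sample-level
#' indicator F (`P(F = 1 | D = 1) = pi_f`, `P(F = 1 | D = 0) = epsilon`).
#' Given F = 1, a network partner with connection weight w is non-neutral
#' with probability `alpha * w` (split equally between up and down); given
#' F = 0 the background non-neutral probability is `b`.
#'
#' @param pi_d Prior probability that a gene's mutations are functional at
#'   the cohort level.
#' @param pi_f Probability a sample's mutation is functional when D = 1.
#' @param epsilon Probability a sample's mutation is functional when D = 0;
#'   must be below `pi_f`.
#' @param alpha Maximum partner dysregulation probability given a functional
#'   mutation.
#' @param b Background partner non-neutral probability; must be below
#'   `alpha`.
#' @return Object of class `"dysnet_priors"`.
#' @export
dysnet_priors <- function(pi_d = 0.5, pi_f = 0.8, epsilon = 0.01,
                          alpha = 0.9, b = 0.1) {
  p <- c(pi_d = pi_d, pi_f = pi_f, epsilon = epsilon, alpha = alpha, b = b)
  if (any(p <= 0 | p >= 1)) stop("all priors must lie strictly in (0, 1)")
  if (epsilon >= pi_f) stop("epsilon must be < pi_f")
  if (b >= alpha) stop("b must be < alpha")
  structure(as.list(p), class = "dysnet_priors")
}

# log-sum-exp of three equally-shaped arrays
.lse3 <- function(a, b, c) {
  m <- pmax(a, b, c)
  m[!is.finite(m)] <- 0
  m + log(exp(a - m) + exp(b - m) + exp(c - m))
}

#' Exact inference for one mutated gene
#'
#' Sums the tree-structured two-level model exactly (no sampling): the
#' partner regulatory statuses are marginalized against the fitted
#' three-status mixture densities, per-sample evidence is combined over
#' partners in log space, and the cohort indicator D is marginalized last.
#' Partner observations masked by copy-number alterations are excluded from
#' the per-sample evidence product.
#'
#' @param logdens List of three P x S matrices (`down`, `neutral`, `up`) of
#'   log observation densities for the gene's P partners in its S mutated
#'   samples.
#' @param weights Numeric vector of the P connection weights in (0, 1].
#' @param priors A [dysnet_priors()] object.
#' @param mask Logical P x S matrix, `TRUE` where the observation is used
#'   (default all).
#' @return List with `ssd` (length-S posterior P(F = 1 | data)), `dac`
#'   (posterior P(D = 1 | data)), and the per-sample log-evidence under
#'   F = 1 / F = 0. `dac` is `NA` when every observation is masked.
#' @export
infer_gene <- function(logdens, weights, priors, mask = NULL) {
  ld <- logdens$down
  ln <- logdens$neutral
  lu <- logdens$up
  stopifnot(is.matrix(ld), all(dim(ld) == dim(ln)), all(dim(ld) == dim(lu)),
            length(weights) == nrow(ld))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(ld), ncol(ld))
  if (!any(mask)) {
    return(list(ssd = rep(NA_real_, ncol(ld)), dac = NA_real_,
                logev_f1 = rep(0, ncol(ld)), logev_f0 = rep(0, ncol(ld))))
  }
  aw <- priors$alpha * weights
  l1 <- .lse3(log(aw / 2) + ld, log1p(-aw) + ln, log(aw / 2) + lu)
  l0 <- .lse3(log(priors$b / 2) + ld, log1p(-priors$b) + ln,
              log(priors$b / 2) + lu)
  l1[!mask] <- 0
  l0[!mask] <- 0
  logev_f1 <- colSums(l1)
  logev_f0 <- colSums(l0)

  # per-sample marginal under each D; F integrated out
  lg <- function(p) log(p)
  m1 <- .lse2(lg(priors$pi_f) + logev_f1, log1p(-priors$pi_f) + logev_f0)
  m0 <- .lse2(lg(priors$epsilon) + logev_f1, log1p(-priors$epsilon) + logev_f0)
  log_d1 <- lg(priors$pi_d) + sum(m1)
  log_d0 <- log1p(-priors$pi_d) + sum(m0)
  dac <- 1 / (1 + exp(log_d0 - log_d1))
  post_d1 <- dac

  # P(F_s = 1 | D, data_s), then mixed over the posterior of D
  pf_d1 <- 1 / (1 + exp(log1p(-priors$pi_f) + logev_f0 -
                          lg(priors$pi_f) - logev_f1))
  pf_d0 <- 1 / (1 + exp(log1p(-priors$epsilon) + logev_f0 -
                          lg(priors$epsilon) - logev_f1))
  ssd <- pf_d1 * post_d1 + pf_d0 * (1 - post_d1)
  list(ssd = ssd, dac = dac, logev_f1 = logev_f1, logev_f0 = logev_f0)
}

.lse2 <- function(a, b) {
  m <- pmax(a, b)
  m[!is.finite(m)] <- 0
  m + log(exp(a - m) + exp(b - m))
}

# Fit status mixtures for a set of genes and precompute, for every gene and
# sample, the log observation density under each status and the signed GRS.
# Fitting once per cohort lets the shuffled controls reuse the observation
# model (expression is never shuffled).
precompute_observation_model <- function(expr, genes = rownames(expr), ...) {
  genes <- intersect(genes, rownames(expr))
  S <- ncol(expr)
  G <- length(genes)
  ld <- ln <- lu <- grs <- matrix(NA_real_, G, S,
                                  dimnames = list(genes, colnames(expr)))
  mixtures <- vector("list", G)
  names(mixtures) <- genes
  for (g in genes) {
    mix <- fit_status_mixture(expr[g, ], ...)
    mixtures[[g]] <- mix
    y <- expr[g, ]
    ld[g, ] <- stats::dnorm(y, mix$mu["down"], mix$sigma["down"], log = TRUE)
    ln[g, ] <- stats::dnorm(y, mix$mu["neutral"], mix$sigma["neutral"],
                            log = TRUE)
    lu[g, ] <- stats::dnorm(y, mix$mu["up"], mix$sigma["up"], log = TRUE)
    post <- status_posteriors(y, mix)
    grs[g, ] <- (post[, "down"] + post[, "up"]) *
      ifelse(post[, "up"] >= post[, "down"], 1, -1)
  }
  list(logdens = list(down = ld, neutral = ln, up = lu),
       grs = grs, mixtures = mixtures)
}

# Inference over every mutated gene given a precomputed observation model.
# Returns the DAC vector and, optionally, per-sample SSD records.
dysnet_core <- function(mut_matrix, net, obs, cna = NULL, priors,
                        keep_ssd = TRUE) {
  partners_known <- rownames(obs$grs)
  net <- net[net$partner %in% partners_known, , drop = FALSE]
  by_src <- split(net[c("partner", "weight")], net$source)
  genes <- rownames(mut_matrix)[rowSums(mut_matrix) > 0]
  dac <- stats::setNames(rep(NA_real_, length(genes)), genes)
  ssd <- if (keep_ssd) vector("list", length(genes)) else NULL
  for (i in seq_along(genes)) {
    g <- genes[i]
    edges <- by_src[[g]]
    if (is.null(edges) || nrow(edges) == 0) next
    s_idx <- which(mut_matrix[g, ] == 1L)
    p <- edges$partner
    logdens <- list(down = obs$logdens$down[p, s_idx, drop = FALSE],
                    neutral = obs$logdens$neutral[p, s_idx, drop = FALSE],
                    up = obs$logdens$up[p, s_idx, drop = FALSE])
    mask <- matrix(TRUE, length(p), length(s_idx))
    if (!is.null(cna)) {
      pc <- intersect(p, rownames(cna))
      if (length(pc) > 0) {
        sub <- abs(cna[pc, colnames(mut_matrix)[s_idx], drop = FALSE]) >= 1
        mask[match(pc, p), ] <- !sub
      }
    }
    res <- infer_gene(logdens, edges$weight, priors, mask)
    dac[g] <- res$dac
    if (keep_ssd)
      ssd[[i]] <- data.frame(gene = g,
                             sample = colnames(mut_matrix)[s_idx],
                             ssd = res$ssd, stringsAsFactors = FALSE)
  }
  list(dac = dac,
       ssd = if (keep_ssd) do.call(rbind, ssd) else NULL)
}

#' Fit the hierarchical mutation-network dysregulation model on a cohort
#'
#' For every gene with at least one entry in the binary mutation matrix, the
#' model evaluates whether the expression of the gene's network partners
#' deviates from neutral in the mutated samples, first per sample and then
#' across the cohort. Each partner's expression is decomposed once into
#' down/neutral/up Gaussian statuses ([fit_status_mixture()]); exact
#' posterior inference then yields the sample-specific dysregulation
#' probability (SSD) and the dysregulation-across-cohort probability (DAC),
#' plus signed gene regulatory status (GRS) values for the partners.
#' Partner observations carrying a copy-number alteration
#' (|GISTIC| >= 1) are excluded so that cis-effects of CNAs do not
#' masquerade as trans-dysregulation.
#'
#' @param mut_matrix Binary gene x sample matrix
#'   ([build_mutation_matrix()]); columns must match `expr` samples.
#' @param expr Normalized expression matrix, partner genes x samples.
#' @param net Weighted network data frame (`source`, `partner`, `weight`);
#'   partners absent from `expr` are dropped with a warning.
#' @param cna Optional gene x sample GISTIC-coded CNA matrix.
#' @param priors A [dysnet_priors()] object.
#' @return Object of class `"dysnet"`: list with `dac` (named vector),
#'   `ssd` (data frame gene/sample/ssd over mutated entries), `grs` (signed
#'   partner x sample GRS matrix), `mixtures`, `net`, `priors`, and the
#'   precomputed observation model (reused by [dysnet_controls()]).
#' @seealso [select_genes()], [fdr_threshold()], [dysregulation_table()]
#' @export
dysnet <- function(mut_matrix, expr, net, cna = NULL,
                   priors = dysnet_priors()) {
  validate_network(net)
  if (!identical(sort(colnames(mut_matrix)), sort(colnames(expr))))
    stop("mutation-matrix samples and expression samples differ")
  mut_matrix <- mut_matrix[, colnames(expr), drop = FALSE]
  missing_p <- setdiff(unique(net$partner), rownames(expr))
  if (length(missing_p) > 0) {
    warning(length(missing_p), " network partner(s) absent from expression ",
            "dropped")
    net <- net[net$partner %in% rownames(expr), , drop = FALSE]
  }
  if (nrow(net) == 0) stop("no network partner is present in expression")
  obs <- precompute_observation_model(expr, unique(net$partner))
  core <- dysnet_core(mut_matrix, net, obs, cna, priors, keep_ssd = TRUE)
  structure(list(dac = core$dac, ssd = core$ssd, grs = obs$grs,
                 mixtures = obs$mixtures, net = net, priors = priors,
                 mut_matrix = mut_matrix, cna = cna, obs = obs,
                 samples = colnames(expr), call = match.call()),
            class = "dysnet")
}

#' Null DAC distributions from shuffled controls
#'
#' Re-runs the cohort inference on `n_controls` independent controls in
#' which the network (partner slots and weight multiset) and the gene
#' labels of the mutation matrix are shuffled; the expression matrix -- and
#' hence the fitted observation model -- is never shuffled. Control seeds
#' are derived from `seed` by a counter, so results do not depend on
#' execution order.
#'
#' @param fit A fitted [dysnet()] object.
#' @param n_controls Number of shuffled controls (default 100).
#' @param seed Master integer seed.
#' @return List of `n_controls` named DAC vectors.
#' @export
dysnet_controls <- function(fit, n_controls = 100, seed = 1) {
  lapply(seq_len(n_controls), function(i) {
    net_i <- shuffle_network(fit$net, seed = seed + 2L * i)
    mut_i <- shuffle_mutation_matrix(fit$mut_matrix, seed = seed + 2L * i + 1L)
    dysnet_core(mut_i, net_i, fit$obs, fit$cna, fit$priors,
                keep_ssd = FALSE)$dac
  })
}

#' @export
print.dysnet <- function(x, ...) {
  cat("Hierarchical mutation-network dysregulation fit\n")
  cat(sprintf("  %d mutated genes x %d samples; %d network edges\n",
              length(x$dac), length(x$samples), nrow(x$net)))
  ok <- x$dac[!is.na(x$dac)]
  if (length(ok) > 0) {
    top <- sort(ok, decreasing = TRUE)
    cat("  top DAC:\n")
    print(round(utils::head(top, 5), 4))
  }
  invisible(x)
}

#' Summarize a dysregulation fit
#'
#' @param object A `"dysnet"` fit.
#' @param ssd_min SSD level used to count supporting samples (default 0.5).
#' @param ... Unused.
#' @return Data frame with one row per mutated gene: `gene`, `dac`,
#'   `n_mutated_samples`, `n_ssd_samples` (samples at or above `ssd_min`),
#'   ordered by decreasing DAC.
#' @export
summary.dysnet <- function(object, ssd_min = 0.5, ...) {
  genes <- names(object$dac)
  n_mut <- rowSums(object$mut_matrix[genes, , drop = FALSE])
  n_ssd <- vapply(genes, function(g) {
    sum(object$ssd$ssd[object$ssd$gene == g] >= ssd_min, na.rm = TRUE)
  }, integer(1))
  out <- data.frame(gene = genes, dac = unname(object$dac),
                    n_mutated_samples = unname(n_mut),
                    n_ssd_samples = unname(n_ssd),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$dac, out$gene), ]
  rownames(out) <- NULL
  out
}

#' @export
coef.dysnet <- function(object, ...) object$dac

#' Plot the cohort DAC profile
#'
#' Genes ordered by decreasing DAC; an optional selection threshold is drawn
#' as a horizontal line.
#'
#' @param x A `"dysnet"` fit.
#' @param threshold Optional DAC threshold (e.g. from [fdr_threshold()]).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.dysnet <- function(x, threshold = NULL, ...) {
  d <- sort(x$dac[!is.na(x$dac)], decreasing = TRUE)
  graphics::plot(seq_along(d), d, xlab = "gene rank", ylab = "DAC",
                 ylim = c(0, 1), pch = 19, ...)
  if (!is.null(threshold) && is.finite(threshold))
    graphics::abline(h = threshold, lty = 2)
  invisible(x)
}

#' Write fit results as TSV tables
#'
#' Writes `dac.tsv` (gene, dac), `ssd.tsv` (gene, sample, ssd) and
#' `grs.tsv` (gene, partner, sample, signed grs restricted to each gene's
#' partners and mutated samples), plus a JSON run manifest.
#'
#' @param fit A `"dysnet"` fit.
#' @param dir Output directory (created if needed).
#' @param manifest Named list of extra manifest entries (seeds, thresholds).
#' @return `dir`, invisibly.
#' @export
write_dysnet_results <- function(fit, dir, manifest = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dac <- data.frame(gene = names(fit$dac), dac = unname(fit$dac))
  utils::write.table(dac[order(dac$gene), ], file.path(dir, "dac.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ssd <- fit$ssd[order(fit$ssd$gene, fit$ssd$sample), ]
  utils::write.table(ssd, file.path(dir, "ssd.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  grs_rows <- list()
  for (g in names(fit$dac)) {
    p <- fit$net$partner[fit$net$source == g]
    p <- intersect(p, rownames(fit$grs))
    s <- colnames(fit$mut_matrix)[fit$mut_matrix[g, ] == 1L]
    if (length(p) == 0 || length(s) == 0) next
    sub <- fit$grs[p, s, drop = FALSE]
    grs_rows[[g]] <- data.frame(gene = g,
                                partner = rep(p, times = length(s)),
                                sample = rep(s, each = length(p)),
                                grs = as.vector(sub))
  }
  grs <- do.call(rbind, grs_rows)
  if (is.null(grs))
    grs <- data.frame(gene = character(), partner = character(),
                      sample = character(), grs = numeric())
  grs <- grs[order(grs$gene, grs$partner, grs$sample), ]
  utils::write.table(grs, file.path(dir, "grs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  man <- c(list(priors = unclass(fit$priors),
                n_genes = length(fit$dac),
                n_samples = length(fit$samples),
                package_version = as.character(utils::packageVersion("dysnet"))),
           manifest)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
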