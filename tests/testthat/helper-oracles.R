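# Independent oracles used across the suite. These deliberately use naive
# per-base / exhaustive computations, not the package's code paths.

# --- per-base boolean-array interval oracle -------------------------------

# cover: named list of logical vectors (one per chromosome, 1-based)
oracle_empty_cover <- function(genome) {
  lapply(as.list(genome), function(len) rep(FALSE, len))
}

oracle_cover <- function(df, genome) {
  cov <- oracle_empty_cover(genome)
  if (nrow(df) > 0) {
    for (i in seq_len(nrow(df))) {
      cov[[df$chrom[i]]][df$start1[i]:df$end1[i]] <- TRUE
    }
  }
  cov
}

granges_cover <- function(gr, genome) {
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start1 = BiocGenerics::start(gr),
                   end1 = BiocGenerics::end(gr))
  oracle_cover(df, genome)
}

oracle_flank_cover <- function(df, width, exclude_cov, genome) {
  cov <- oracle_empty_cover(genome)
  if (nrow(df) > 0) {
    for (i in seq_len(nrow(df))) {
      len <- genome[[df$chrom[i]]]
      l_lo <- max(1, df$start1[i] - width)
      l_hi <- df$start1[i] - 1
      r_lo <- df$end1[i] + 1
      r_hi <- min(len, df$end1[i] + width)
      l <- if (l_hi >= l_lo) l_lo:l_hi else integer(0)
      r <- if (r_hi >= r_lo) r_lo:r_hi else integer(0)
      cov[[df$chrom[i]]][c(l, r)] <- TRUE
    }
  }
  mapply(function(a, b) a & !b, cov, exclude_cov, SIMPLIFY = FALSE)
}

random_interval_df <- function(n, genome, max_width = 400) {
  chrom <- sample(names(genome), n, replace = TRUE)
  len <- unname(genome[chrom])
  start1 <- 1 + floor(runif(n) * (len - 1))
  width <- 1 + floor(runif(n) * pmin(max_width, len - start1 + 1))
  data.frame(chrom = chrom, start1 = start1, end1 = start1 + width - 1)
}

df_to_granges <- function(df, genome = NULL) {
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start1, df$end1))
  if (!is.null(genome)) gr <- dysnet::set_genome(gr, genome)
  gr
}

# --- exhaustive enumeration oracle for the hierarchical model -------------

# dens: list of three P x S matrices of *plain* observation densities
# (down/neutral/up). Enumerates D, every F vector and every status
# configuration explicitly. Masked cells contribute a constant factor that
# cancels in the posteriors.
bf_infer <- function(dens, weights, priors, mask = NULL) {
  P <- nrow(dens$down)
  S <- ncol(dens$down)
  if (is.null(mask)) mask <- matrix(TRUE, P, S)
  cells <- which(mask)  # column-major cell indices
  n_cells <- length(cells)
  r_grid <- as.matrix(expand.grid(rep(list(1:3), n_cells)))
  f_grid <- as.matrix(expand.grid(rep(list(0:1), S)))
  dens_arr <- array(c(dens$down, dens$neutral, dens$up), dim = c(P, S, 3))

  total <- 0
  sum_d1 <- 0
  sum_f1 <- numeric(S)
  for (d in 0:1) {
    p_d <- if (d == 1) priors$pi_d else 1 - priors$pi_d
    pf <- if (d == 1) priors$pi_f else priors$epsilon
    for (fi in seq_len(nrow(f_grid))) {
      f <- f_grid[fi, ]
      p_f <- prod(ifelse(f == 1, pf, 1 - pf))
      # per-cell status probabilities given this F vector
      cell_probs <- matrix(NA_real_, nrow(r_grid), 0)
      logw <- 0
      cfg_log <- numeric(nrow(r_grid))
      for (ci in seq_len(n_cells)) {
        cell <- cells[ci]
        p_idx <- (cell - 1) %% P + 1
        s_idx <- (cell - 1) %/% P + 1
        nn <- if (f[s_idx] == 1) priors$alpha * weights[p_idx] else priors$b
        pr_r <- c(nn / 2, 1 - nn, nn / 2)
        v <- pr_r * dens_arr[p_idx, s_idx, ]
        cfg_log <- cfg_log + log(v[r_grid[, ci]])
      }
      contrib <- p_d * p_f * sum(exp(cfg_log))
      total <- total + contrib
      if (d == 1) sum_d1 <- sum_d1 + contrib
      for (s in seq_len(S)) if (f[s] == 1) sum_f1[s] <- sum_f1[s] + contrib
    }
  }
  list(dac = sum_d1 / total, ssd = sum_f1 / total)
}

# --- exact hypergeometric upper tail by summation -------------------------

oracle_hyper_upper <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

# --- hand-rolled log-rank statistic and permutation p ---------------------

oracle_logrank_chi2 <- function(time, event, grp) {
  # grp: logical (TRUE = group 1)
  times <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in times) {
    at_risk <- time >= t
    n1 <- sum(at_risk & grp)
    n0 <- sum(at_risk & !grp)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp)
    n <- n1 + n0
    if (n < 2 || d == 0) next
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + (d1 - e1)
    v <- v + d * (n1 / n) * (n0 / n) * (n - d) / (n - 1)
  }
  if (v == 0) return(0)
  o_minus_e^2 / v
}

oracle_logrank_perm_p <- function(time, event, grp, n_perm = 1e5) {
  obs <- oracle_logrank_chi2(time, event, grp)
  hits <- 0
  for (i in seq_len(n_perm)) {
    hits <- hits + (oracle_logrank_chi2(time, event, sample(grp)) >=
                      obs - 1e-12)
  }
  hits / n_perm
}

# --- union-find connected components --------------------------------------

oracle_components <- function(nodes, edges_from, edges_to) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (i in seq_along(edges_from)) {
    a <- find(edges_from[i])
    b <- find(edges_to[i])
    if (a != b) parent[[a]] <- b
  }
  roots <- vapply(nodes, find, character(1))
  sizes <- table(roots)
  list(n_components_ge2 = sum(sizes >= 2), n_isolated = sum(sizes == 1),
       sizes = sort(as.integer(sizes)))
}

# quiet wrapper for pipeline runs in tests
quiet_run <- function(config) {
  suppressWarnings(suppressMessages(pipeline_run(config)))
}

# --- random model parameterizations shared by model and acceptance tests --

random_case <- function(P, S, seed, masked = FALSE) {
  set.seed(seed)
  dens <- list(down = matrix(exp(rnorm(P * S)), P, S),
               neutral = matrix(exp(rnorm(P * S)), P, S),
               up = matrix(exp(rnorm(P * S)), P, S))
  pf <- runif(1, 0.5, 0.95)
  alpha <- runif(1, 0.5, 0.95)
  priors <- dysnet_priors(pi_d = runif(1, 0.2, 0.8), pi_f = pf,
                          epsilon = runif(1, 0.001, pf / 2), alpha = alpha,
                          b = runif(1, 0.01, alpha / 2))
  mask <- matrix(TRUE, P, S)
  if (masked && P * S > 1) mask[sample(P * S, 1)] <- FALSE
  list(dens = dens, weights = runif(P, 0.1, 1), priors = priors,
       mask = mask)
}

log_dens <- function(dens) lapply(dens, log)

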