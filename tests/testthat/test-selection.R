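fake_fit <- function(dac, ssd, mut_matrix, grs = NULL, net = NULL) {
  structure(list(dac = dac, ssd = ssd, mut_matrix = mut_matrix,
                 grs = grs, net = net,
                 samples = colnames(mut_matrix)),
            class = "dysnet")
}

test_that("the empirical FDR threshold is floored and obeys the controls", {
  cfg <- selection_config()
  # strong observed gene, all nulls below 0.3: the grid value 0.35 already
  # achieves zero FDR, so the threshold is floored at 0.5 and 0.9 passes
  set.seed(59)
  t1 <- fdr_threshold(c(0.9, 0.45, 0.35), replicate(10, runif(5, 0, 0.3),
                                                    simplify = FALSE), cfg)
  expect_equal(as.numeric(t1), 0.5)
  # controls all zero: the floor again
  t2 <- fdr_threshold(c(0.7, 0.2), replicate(10, rep(0, 5),
                                             simplify = FALSE), cfg)
  expect_equal(as.numeric(t2), 0.5)
  # observed distribution identical to the nulls: nothing passes
  set.seed(60)
  obs <- runif(50)
  t3 <- fdr_threshold(obs, replicate(20, runif(50), simplify = FALSE), cfg)
  expect_true(is.infinite(t3) || sum(obs >= t3) <= 3)
  expect_error(fdr_threshold(numeric(0), list(runif(5))), "empty")
})

test_that("the FDR threshold is monotone in the null distribution", {
  cfg <- selection_config()
  obs <- c(0.95, 0.9, 0.6, 0.3)
  weak_nulls <- replicate(20, runif(4, 0, 0.2), simplify = FALSE)
  strong_nulls <- lapply(weak_nulls, function(x) c(x, 0.97, 0.99))
  t_weak <- as.numeric(fdr_threshold(obs, weak_nulls, cfg))
  t_strong <- as.numeric(fdr_threshold(obs, strong_nulls, cfg))
  expect_gte(t_strong, t_weak)
})

test_that("gene selection requires both DAC and repeated SSD support", {
  mut <- matrix(1L, 2, 4, dimnames = list(c("gA", "gB"),
                                          sprintf("s%d", 1:4)))
  ssd <- data.frame(gene = rep(c("gA", "gB"), each = 4),
                    sample = rep(sprintf("s%d", 1:4), 2),
                    ssd = c(0.9, 0.8, 0.7, 0.1, 0.9, 0.2, 0.1, 0.1))
  fit <- fake_fit(c(gA = 0.95, gB = 0.95), ssd, mut)
  sel <- select_genes(fit, t = 0.5)
  expect_identical(sel, "gA")  # gB has SSD >= 0.5 in only one sample
  expect_identical(select_genes(fit, t = 0.96), character(0))
  rep <- selection_report(fit, t = 0.5)
  expect_identical(rep$gene[rep$selected], "gA")
  expect_equal(rep$t, rep(0.5, 2))
  # empty result stays empty
  fit0 <- fake_fit(stats::setNames(numeric(0), character(0)),
                   ssd[0, ], mut[0, , drop = FALSE])
  expect_identical(select_genes(fit0, t = 0.5), character(0))
})

test_that("dysregulation tables keep partners with GRS support in SSD-positive samples", {
  mut <- matrix(0L, 1, 3, dimnames = list("gA", c("s1", "s2", "s3")))
  mut[1, c(1, 2)] <- 1L
  grs <- matrix(c(0.6, 0.2, 0.1,
                  -0.7, -0.1, 0.9,
                  0.3, 0.45, 0.2), nrow = 3, byrow = TRUE,
                dimnames = list(c("P1", "P2", "P3"), c("s1", "s2", "s3")))
  ssd <- data.frame(gene = "gA", sample = c("s1", "s2"), ssd = c(0.7, 0.3))
  net <- data.frame(source = "gA", partner = c("P1", "P2", "P3"),
                    weight = 0.5)
  fit <- fake_fit(c(gA = 0.9), ssd, mut, grs = grs, net = net)
  tab <- dysregulation_table(fit, "gA")
  # P1: |GRS| 0.6 in s1 (SSD 0.7): kept. P2: 0.7 in s1: kept (signed down).
  # P3: 0.45 nowhere above 0.5: dropped. s3 is not a mutated column.
  expect_setequal(rownames(tab), c("P1", "P2"))
  expect_identical(colnames(tab), c("s1", "s2"))
  expect_lt(tab["P2", "s1"], 0)  # downregulation carries a negative sign
  # GRS only where SSD qualifies: shifting SSD below 0.5 empties the table
  fit2 <- fake_fit(c(gA = 0.9),
                   transform(ssd, ssd = c(0.3, 0.2)), mut, grs, net)
  tab2 <- dysregulation_table(fit2, "gA")
  expect_equal(nrow(tab2), 0)
  expect_identical(colnames(tab2), c("s1", "s2"))
  expect_error(dysregulation_table(fit, "nope"), "not in fit")
})

test_that("hypergeometric enrichment matches closed forms and summation", {
  expect_equal(hypergeometric_enrichment(4, 5, 4, 10), 5 / 210,
               tolerance = 1e-12)
  expect_equal(hypergeometric_enrichment(0, 5, 4, 10), 1)
  p <- hypergeometric_enrichment(20, 50, 100, 1000)
  expect_equal(p, oracle_hyper_upper(20, 50, 100, 1000), tolerance = 1e-12)
  expect_error(hypergeometric_enrichment(6, 5, 4, 10), "inconsistent")
})

test_that("category enrichment wraps the hypergeometric tail with BH", {
  universe <- sprintf("g%03d", 1:100)
  genes <- universe[1:10]
  cats <- list(cancer = universe[1:15],       # 10 of 10 hits
               tf = universe[90:99],          # 0 hits
               outside = c("x1", "x2"))       # empty after intersection
  rep <- enrichment_report(genes, cats, universe)
  expect_equal(rep$hits, c(10, 0, 0))
  expect_equal(rep$p[1], oracle_hyper_upper(10, 15, 10, 100),
               tolerance = 1e-12)
  expect_equal(rep$p[2:3], c(1, 1))
  expect_equal(rep$p_adj, bh_adjust(rep$p))
})

test_that("BH adjustment follows the step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- c(0.001, 0.02, 0.9)
  expect_equal(bh_adjust(p), p.adjust(p, "BH"))
})

toy_surv <- function() {
  data.frame(sample_id = sprintf("s%d", 1:8),
             time = c(2, 4, 6, 8, 10, 12, 14, 16),
             event = c(1, 1, 1, 0, 1, 1, 0, 1))
}

test_that("median-split log-rank behaves on degenerate and toy data", {
  surv <- toy_surv()
  # identical survival in the two groups: chi2 = 0, p = 1
  surv_id <- data.frame(sample_id = sprintf("s%d", 1:8),
                        time = rep(c(2, 5, 9, 13), 2),
                        event = rep(c(1, 1, 0, 1), 2))
  v <- stats::setNames(c(1, 2, 3, 4, 10, 11, 12, 13), surv_id$sample_id)
  out <- km_logrank(v, surv_id)
  expect_lt(out$chi2, 1e-9)
  expect_equal(out$p, 1, tolerance = 1e-6)
  # ties at the median go to the low group
  v2 <- stats::setNames(c(1, 1, 1, 1, 1, 9, 9, 9), surv$sample_id)
  out2 <- km_logrank(v2, surv)
  expect_equal(sum(out2$groups == "low"), 5)
  # swapping which side of the split is "high" leaves the statistic alone
  v3 <- stats::setNames(c(1, 1, 1, 1, 9, 9, 9, 9), surv$sample_id)
  out3a <- km_logrank(v3, surv)
  out3b <- km_logrank(-v3, surv)
  expect_equal(out3a$chi2, out3b$chi2, tolerance = 1e-9)
  expect_error(km_logrank(stats::setNames(rep(1, 8), surv$sample_id), surv),
               "fewer than 2")
})

test_that("the log-rank p matches a permutation oracle on the toy data", {
  surv <- toy_surv()
  v <- stats::setNames(c(10, 9, 12, 1, 11, 2, 3, 4), surv$sample_id)
  out <- km_logrank(v, surv)
  grp <- out$groups == "high"
  expect_equal(oracle_logrank_chi2(surv$time, surv$event, grp), out$chi2,
               tolerance = 1e-9)
  set.seed(61)
  p_perm <- oracle_logrank_perm_p(surv$time, surv$event, grp, n_perm = 2e4)
  # chi-square approximation against the exact permutation distribution:
  # Monte-Carlo error plus the small-sample approximation gap at n = 8
  expect_lt(abs(out$p - p_perm), 0.05)
})

rate_setup <- function() {
  genome <- c(chr1 = 10000)
  tfbs <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1100))
  exons <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5001, 5100))
  list(genome = genome, tfbs = tfbs, exons = exons)
}

test_that("mutation rates divide mutated positions by region length", {
  rs <- rate_setup()
  muts <- data.frame(sample_id = "s1", chrom = "chr1",
                     pos = c(1010, 1050, 7000), ref = "A", alt = "G",
                     consequence = NA, variant_class = "SNV")
  rep <- mutation_rate_report(muts, rs$tfbs, rs$exons, rs$genome,
                              n_shuffles = 0)
  r <- rep$rates
  expect_equal(r$rate[r$region == "tfbs" & r$sample_id == "s1"], 0.02)
  expect_equal(r$rate[r$region == "exon" & r$sample_id == "s1"], 0)
  expect_true(all(is.na(r$expected_rate)))
  # an indel spanning the region boundary counts only overlapping bases
  muts2 <- data.frame(sample_id = "s1", chrom = "chr1", pos = 1099,
                      ref = "AAAA", alt = "A", consequence = NA,
                      variant_class = "deletion")
  rep2 <- mutation_rate_report(muts2, rs$tfbs, rs$exons, rs$genome,
                               n_shuffles = 0)
  expect_equal(rep2$rates$rate[rep2$rates$region == "tfbs"], 0.02)
})

test_that("samples without mutations get zero rates and a paired-test warning", {
  rs <- rate_setup()
  muts <- data.frame(sample_id = "s1", chrom = "chr1", pos = 1010,
                     ref = "A", alt = "G", consequence = NA,
                     variant_class = "SNV")
  expect_warning(
    rep <- mutation_rate_report(muts, rs$tfbs, rs$exons, rs$genome,
                                n_shuffles = 0,
                                samples = c("s1", "s2")),
    "without mutations")
  r <- rep$rates
  expect_true(all(r$rate[r$sample_id == "s2"] == 0))
})

test_that("identical TFBS and exon rates give a Wilcoxon p of one", {
  rs <- rate_setup()
  # one mutation in the TFBS and one in the exon for each sample
  muts <- data.frame(sample_id = rep(c("s1", "s2"), each = 2),
                     chrom = "chr1", pos = c(1010, 5010, 1020, 5020),
                     ref = "A", alt = "G", consequence = NA,
                     variant_class = "SNV")
  rep <- mutation_rate_report(muts, rs$tfbs, rs$exons, rs$genome,
                              n_shuffles = 0)
  expect_equal(rep$wilcoxon_p, 1)
  expect_error(mutation_rate_report(muts, GenomicRanges::GRanges(),
                                    rs$exons, rs$genome), "empty region")
})
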