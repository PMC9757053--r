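test_that("the LoF whitelist covers exactly the 11 nonsense/frameshift/splice terms", {
  terms <- c("disruptive in-frame deletion", "disruptive in-frame insertion",
             "stop gained", "start lost", "stop lost",
             "stop retained variant", "frameshift variant",
             "initiator codon variant", "splice region variant",
             "splice donor variant", "splice acceptor variant")
  expect_length(terms, 11)
  expect_true(all(classify_lof(terms)))
  expect_true(classify_lof("splice_acceptor_variant"))  # underscore form
  expect_true(classify_lof("Stop Gained"))              # case-insensitive
  expect_false(classify_lof("missense variant"))
  expect_false(classify_lof("synonymous_variant"))
  expect_false(classify_lof(NA_character_))
  # pure function: same input, same output
  expect_identical(classify_lof(terms), classify_lof(terms))
})

make_tss <- function(gene_id, pos, gene_class = "protein_coding",
                     chrom = "chr1") {
  data.frame(gene_id = gene_id, chrom = chrom, pos = pos, strand = "+",
             gene_class = gene_class, stringsAsFactors = FALSE)
}

test_that("element overlap takes priority over closest TSS", {
  tfbs <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(c(100, 5000, 1900),
                                                  width = 10))
  elements <- GenomicRanges::GRanges("chr1", IRanges::IRanges(90, 130))
  S4Vectors::mcols(elements)$genes <- list(c("G1", "G2"))
  tss <- rbind(make_tss("G3", 120),  # nearest to the first TFBS
               make_tss("mirX", 5100, gene_class = "miRNA"),
               make_tss("G4", 2000))
  got <- assign_tfbs_to_genes(tfbs, elements, tss)
  # multi-gene element: all linked genes, even though G3's TSS is nearer
  expect_identical(got[[1]], c("G1", "G2"))
  # no element: closest TSS may be a miRNA
  expect_identical(got[[2]], "mirX")
  expect_identical(got[[3]], "G4")
  expect_identical(attr(got, "via"), c("element", "tss", "tss"))
})

test_that("assignment equals an exhaustive per-TFBS scan", {
  set.seed(20)
  genome <- c(chr1 = 50000)
  n <- 300
  tfbs <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(sample(49000, n),
                                                  width = 12))
  ne <- 40
  el_start <- sample(49500, ne)
  elements <- GenomicRanges::GRanges("chr1",
                                     IRanges::IRanges(el_start, width = 300))
  S4Vectors::mcols(elements)$genes <-
    lapply(seq_len(ne), function(i)
      sample(sprintf("e%02d", 1:20), sample(1:2, 1)))
  tss <- make_tss(sprintf("t%02d", 1:25), sample(50000, 25))
  got <- assign_tfbs_to_genes(tfbs, elements, tss)
  st <- BiocGenerics::start(tfbs)
  en <- BiocGenerics::end(tfbs)
  for (i in seq_len(n)) {
    ov <- which(BiocGenerics::start(elements) <= en[i] &
                  BiocGenerics::end(elements) >= st[i])
    if (length(ov) > 0) {
      expect_identical(got[[i]],
                       sort(unique(unlist(
                         S4Vectors::mcols(elements)$genes[ov]))))
    } else {
      d <- ifelse(tss$pos >= st[i] & tss$pos <= en[i], 0,
                  pmin(abs(tss$pos - st[i]), abs(tss$pos - en[i])))
      cand <- tss[d == min(d), ]
      cand <- cand[order(cand$pos, cand$gene_id), ]
      expect_identical(got[[i]], cand$gene_id[1])
    }
  }
})

test_that("the cis matrix gates protein-coding entries on the z flag", {
  pairs <- data.frame(gene = c("G1", "G1", "G2"),
                      sample_id = c("s1", "s2", "s1"))
  z <- matrix(c(1.5, 0.2, -2, 0), nrow = 2, byrow = TRUE,
              dimnames = list(c("G1", "G2"), c("s1", "s2")))
  m <- build_mutation_matrix(pairs, c("s1", "s2"), "cis_protein_coding",
                             z = z)
  expect_equal(m["G1", "s1"], 1L)           # z = 1.5: dysregulated
  expect_false("s2" %in% colnames(m)[m["G1", ] == 1])  # z = 0.2: gated out
  expect_equal(m["G2", "s1"], 1L)
  # miRNA channel: no z filter
  mm <- build_mutation_matrix(data.frame(gene = "mirX-5p",
                                         sample_id = "s2"),
                              c("s1", "s2"), "cis_mirna")
  expect_equal(mm["mirX-5p", "s2"], 1L)
  # channel/z mismatches are errors
  expect_error(build_mutation_matrix(pairs, c("s1", "s2"),
                                     "cis_protein_coding"), "requires")
  expect_error(build_mutation_matrix(pairs, c("s1", "s2"), "lof", z = z),
               "does not use")
  # unknown gene dropped with warning
  p2 <- rbind(pairs, data.frame(gene = "G9", sample_id = "s1"))
  expect_warning(build_mutation_matrix(p2, c("s1", "s2"),
                                       "cis_protein_coding", z = z),
                 "dropped")
})

test_that("matrix entries are monotone in the mutation input", {
  z <- matrix(2, nrow = 3, ncol = 3,
              dimnames = list(c("A", "B", "C"), c("s1", "s2", "s3")))
  small <- data.frame(gene = "A", sample_id = "s1")
  big <- rbind(small, data.frame(gene = c("B", "A"),
                                 sample_id = c("s2", "s3")))
  m_small <- build_mutation_matrix(small, colnames(z),
                                   "cis_protein_coding", z = z)
  m_big <- build_mutation_matrix(big, colnames(z),
                                 "cis_protein_coding", z = z)
  for (g in rownames(m_small))
    expect_true(all(m_big[g, ] >= m_small[g, ]))
})

test_that("pre-miRNA ids expand to both mature arms", {
  pairs <- data.frame(gene = c("mir1", "mir2"), sample_id = c("s1", "s1"))
  out <- expand_mirna_arms(pairs)
  expect_setequal(out$gene, c("mir1-5p", "mir1-3p", "mir2-5p", "mir2-3p"))
  expect_equal(nrow(expand_mirna_arms(pairs[0, ])), 0)
})

test_that("LoF pairs require a whitelisted consequence and exon overlap", {
  exons <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 500),
                                                           width = 100))
  S4Vectors::mcols(exons)$name <- c("G1", "G2")
  muts <- data.frame(sample_id = c("s1", "s2", "s3", "s4"),
                     chrom = "chr1", pos = c(150, 550, 150, 9000),
                     ref = "A", alt = "G",
                     consequence = c("stop gained", "missense variant",
                                     "frameshift_variant", "stop gained"),
                     variant_class = "SNV", stringsAsFactors = FALSE)
  pairs <- lof_mutation_pairs(muts, exons)
  expect_setequal(paste(pairs$gene, pairs$sample_id),
                  c("G1 s1", "G1 s3"))  # s2 not LoF; s4 outside exons
})

test_that("element maps and TSS tables read from disk", {
  d <- withr::local_tempdir()
  writeLines(c("chr1\t90\t130\tG1,G2", "chr2\t10\t40\tG3"),
             file.path(d, "el.tsv"))
  el <- read_element_map(file.path(d, "el.tsv"))
  expect_equal(BiocGenerics::start(el), c(91, 11))  # 0-based on disk
  expect_identical(S4Vectors::mcols(el)$genes[[1]], c("G1", "G2"))
  writeLines("chr1\t90\t80\tG1", file.path(d, "bad.tsv"))
  expect_error(read_element_map(file.path(d, "bad.tsv")), "malformed")
  writeLines(c("gene_id\tchrom\tpos_1based\tstrand\tgene_class",
               "G1\tchr1\t100\t+\tprotein_coding"),
             file.path(d, "tss.tsv"))
  tt <- read_tss_table(file.path(d, "tss.tsv"))
  expect_equal(tt$pos, 100L)
})
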