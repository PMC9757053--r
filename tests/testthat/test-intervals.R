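genome2 <- c(chr1 = 10000, chr2 = 8000)

gr <- function(chrom, start1, end1, genome = NULL) {
  g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start1, end1))
  if (!is.null(genome)) g <- set_genome(g, genome)
  g
}

test_that("merge collapses overlapping and book-ended intervals", {
  # 0-based (0,10)+(5,15) -> (0,15): 1-based 1..10 + 6..15 -> 1..15
  m <- merge_intervals(gr("chr1", c(1, 6), c(10, 15)))
  expect_equal(BiocGenerics::start(m), 1)
  expect_equal(BiocGenerics::end(m), 15)
  # book-ended: 0-based (0,10)+(10,20) -> (0,20)
  m2 <- merge_intervals(gr("chr1", c(1, 11), c(10, 20)))
  expect_equal(length(m2), 1L)
  expect_equal(BiocGenerics::end(m2), 20)
  # empty in, empty out
  expect_length(merge_intervals(GenomicRanges::GRanges()), 0)
  # malformed (zero-width) rejected with index
  expect_error(merge_intervals(gr("chr1", 6, 5)), "malformed")
})

test_that("merge is idempotent and total length is subadditive", {
  set.seed(42)
  a <- df_to_granges(random_interval_df(30, genome2))
  b <- df_to_granges(random_interval_df(30, genome2))
  m <- merge_intervals(c(a, b))
  expect_identical(merge_intervals(m), m)
  expect_lte(total_length(c(a, b)), total_length(a) + total_length(b))
})

test_that("interval engine matches the per-base boolean oracle", {
  set.seed(7)
  for (i in 1:25) {
    df_a <- random_interval_df(sample(1:40, 1), genome2)
    df_b <- random_interval_df(sample(1:40, 1), genome2)
    a <- df_to_granges(df_a, genome2)
    b <- df_to_granges(df_b, genome2)
    cov_a <- oracle_cover(df_a, genome2)
    cov_b <- oracle_cover(df_b, genome2)
    expect_identical(granges_cover(merge_intervals(a), genome2), cov_a)
    expect_identical(granges_cover(subtract_regions(a, b), genome2),
                     mapply(function(x, y) x & !y, cov_a, cov_b,
                            SIMPLIFY = FALSE))
    w <- sample(c(50, 100, 500), 1)
    expect_identical(granges_cover(flank_regions(a, w, exclude = b), genome2),
                     oracle_flank_cover(df_a, w, cov_b, genome2))
  }
})

test_that("flanks are truncated at chromosome bounds and exclude the source", {
  g <- gr("chr1", 1001, 1010, genome2)  # 0-based (1000,1010)
  fl <- flank_regions(g, 100)
  expect_equal(BiocGenerics::start(fl), c(901, 1011))
  expect_equal(BiocGenerics::end(fl), c(1000, 1110))
  # at the chromosome start only the right flank survives
  g2 <- gr("chr1", 1, 10, genome2)  # 0-based (0,10)
  fl2 <- flank_regions(g2, 100)
  expect_equal(BiocGenerics::start(fl2), 11)
  expect_equal(BiocGenerics::end(fl2), 110)
  expect_error(flank_regions(gr("chr1", 1001, 1010), 100), "genome lengths")
})

make_muts <- function(sample_id, chrom, pos, ref = "A", alt = "G") {
  df <- data.frame(sample_id = sample_id, chrom = chrom, pos = pos,
                   ref = ref, alt = alt, consequence = NA_character_,
                   stringsAsFactors = FALSE)
  df$variant_class <- variant_class(df$ref, df$alt)
  df
}

test_that("mutation intersection respects spans and half-open boundaries", {
  region <- gr("chr1", 1, 10)  # 0-based (0,10)
  snv_in <- make_muts("s1", "chr1", 6)    # 0-based pos 5
  snv_out <- make_muts("s1", "chr1", 11)  # 0-based pos 10, outside
  del <- make_muts("s1", "chr1", 9, ref = "AAA", alt = "A")  # span 9..11
  expect_equal(nrow(intersect_mutations(snv_in, region)), 1)
  expect_equal(nrow(intersect_mutations(snv_out, region)), 0)
  expect_equal(nrow(intersect_mutations(del, region)), 1)
  # idempotent and order preserving
  both <- rbind(del, snv_in)
  once <- intersect_mutations(both, region)
  expect_identical(intersect_mutations(once, region), once)
  expect_equal(once$pos, c(9, 6))
  # absent chromosome: dropped with a message
  off <- make_muts("s1", "chrX", 5)
  expect_message(res <- intersect_mutations(off, region), "chrX")
  expect_equal(nrow(res), 0)
})

test_that("shuffling preserves counts, classes and spans per chromosome", {
  set.seed(11)
  muts <- rbind(make_muts(sprintf("s%d", 1:5), "chr1", c(5, 50, 500, 900, 42)),
                make_muts(sprintf("s%d", 1:3), "chr2", c(7, 70, 700),
                          ref = c("A", "AAAA", "A"), alt = c("G", "A", "AT")))
  sh <- shuffle_mutations(muts, genome2, seed = 99)
  expect_equal(table(sh$chrom), table(muts$chrom))
  expect_equal(sort(sh$variant_class), sort(muts$variant_class))
  expect_identical(sh$ref, muts$ref)
  span <- ifelse(sh$variant_class == "insertion", 1L, nchar(sh$ref))
  expect_true(all(sh$pos >= 1 & sh$pos + span - 1 <= genome2[sh$chrom]))
  expect_identical(shuffle_mutations(muts, genome2, seed = 99), sh)
  expect_false(identical(shuffle_mutations(muts, genome2, seed = 100), sh))
  expect_error(shuffle_mutations(make_muts("s", "chr9", 1), genome2),
               "absent")
})

test_that("closest TSS uses minimal end distance with deterministic ties", {
  tss <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                    pos = c(101, 1001), strand = "+",
                    gene_class = "protein_coding")
  q <- gr("chr1", 451, 460)  # 0-based (450,460)
  expect_equal(closest_tss(q, tss), "gA")
  # a TSS inside the interval wins with distance 0
  tss2 <- rbind(tss, data.frame(gene_id = "gC", chrom = "chr1", pos = 455,
                                strand = "+", gene_class = "protein_coding"))
  expect_equal(closest_tss(q, tss2), "gC")
  # equidistant: lower coordinate wins
  tie <- data.frame(gene_id = c("far", "near_hi", "near_lo"), chrom = "chr1",
                    pos = c(5000, 470, 441), strand = "+",
                    gene_class = "protein_coding")
  expect_equal(closest_tss(q, tie), "near_lo")
  # equidistant, equal coordinate: lexicographic gene id
  lex <- data.frame(gene_id = c("zz", "aa"), chrom = "chr1", pos = c(441, 441),
                    strand = "+", gene_class = "protein_coding")
  expect_equal(closest_tss(q, lex), "aa")
  # no TSS on the chromosome: NA, flagged not fatal
  expect_message(r <- closest_tss(gr("chr2", 1, 10), tss), "without a TSS")
  expect_true(is.na(r))
})

test_that("closest TSS matches a brute-force distance scan", {
  set.seed(5)
  tss <- data.frame(gene_id = sprintf("g%02d", 1:30),
                    chrom = sample(names(genome2), 30, replace = TRUE),
                    pos = sample(1000:9000, 30), strand = "+",
                    gene_class = "protein_coding")
  df <- random_interval_df(40, genome2, max_width = 50)
  got <- closest_tss(df_to_granges(df), tss)
  for (i in seq_len(nrow(df))) {
    tt <- tss[tss$chrom == df$chrom[i], ]
    d <- ifelse(tt$pos >= df$start1[i] & tt$pos <= df$end1[i], 0,
                pmin(abs(tt$pos - df$start1[i]), abs(tt$pos - df$end1[i])))
    best <- min(d)
    cand <- tt[d == best, ]
    cand <- cand[order(cand$pos, cand$gene_id), ]
    expect_identical(got[i], cand$gene_id[1])
  }
})

test_that("BED, chrom.sizes and mutation TSV round-trip", {
  d <- withr::local_tempdir()
  g <- gr("chr1", c(11, 101), c(20, 200), genome2)
  S4Vectors::mcols(g)$name <- c("a", "b")
  write_bed(g, file.path(d, "x.bed"))
  # on disk: 0-based half-open
  raw <- read.table(file.path(d, "x.bed"), sep = "\t")
  expect_equal(raw$V2, c(10, 100))
  expect_equal(raw$V3, c(20, 200))
  back <- read_bed(file.path(d, "x.bed"), genome2)
  expect_equal(BiocGenerics::start(back), BiocGenerics::start(g))
  expect_equal(as.character(S4Vectors::mcols(back)$name), c("a", "b"))

  write_chrom_sizes(genome2, file.path(d, "g.sizes"))
  expect_equal(read_chrom_sizes(file.path(d, "g.sizes")), genome2)

  muts <- make_muts(c("s1", "s2"), "chr1", c(5, 9),
                    ref = c("A", "AC"), alt = c("G", "A"))
  write_mutations(muts, file.path(d, "m.tsv"))
  back_m <- read_mutations(file.path(d, "m.tsv"), genome2)
  expect_equal(back_m$pos, muts$pos)
  expect_equal(back_m$variant_class, c("SNV", "deletion"))
})

test_that("a minimal VCF with a SAMPLE info key is read", {
  skip_if_not_installed("VariantAnnotation")
  d <- withr::local_tempdir()
  vcf <- file.path(d, "m.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Sample id\">",
    "##contig=<ID=chr1,length=10000>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t42\t.\tA\tG\t.\tPASS\tSAMPLE=s1",
    "chr1\t99\t.\tAT\tA\t.\tPASS\tSAMPLE=s2"), vcf)
  m <- read_mutations_vcf(vcf, genome2)
  expect_equal(m$sample_id, c("s1", "s2"))
  expect_equal(m$pos, c(42L, 99L))
  expect_equal(m$variant_class, c("SNV", "deletion"))
})
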