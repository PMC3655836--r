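test_that("load_het_snps keeps phased single-base hets and maps haplotypes", {
  rec <- data.frame(
    chrom = "chr1", pos = c(100L, 200L, 300L, 400L, 500L, 600L),
    ref = c("C", "A", "G", "AT", "C", "T"),
    alt = c("T", "G", "G", "A", "G", "A"),
    gt = c("0|1", "1|1", "0|0", "0|1", "0/1", "1|0")
  )
  expect_warning(snps <- load_het_snps(write_mini_vcf(rec)),
                 "unphased")
  # phased het SNVs only: rows 1 (C/T) and 6 (T/A hap-swapped); indel and
  # homozygous records excluded, unphased het skipped
  expect_equal(nrow(snps), 2L)
  expect_equal(snps$pos, c(100L, 600L))
  expect_equal(snps$allele_paternal, c("C", "A"))  # 1|0 -> paternal = ALT
  expect_equal(snps$allele_maternal, c("T", "T"))
  # reversed haplotype convention swaps the labels
  suppressWarnings(rev_snps <- load_het_snps(write_mini_vcf(rec),
                                             haplotype_order = c(2L, 1L)))
  expect_equal(rev_snps$allele_paternal, snps$allele_maternal)
  expect_error(load_het_snps(tempfile()), "not found")
})

test_that("reverse_complement matches known antisense motifs and is an involution", {
  expect_equal(reverse_complement("CTCCTGAC"), "GTCAGGAG")
  expect_equal(reverse_complement("CACGTG"), "CACGTG")  # palindrome
  expect_equal(reverse_complement("A"), "T")
  expect_error(reverse_complement("ACGU"), "only A/C/G/T/N")
  set.seed(42)
  s <- rand_dna(25, 12, alphabet = c("A", "C", "G", "T", "N"))
  expect_equal(reverse_complement(reverse_complement(s)), s)
})

test_that("extract_allele_window substitutes focal and nearby alleles per haplotype", {
  snp <- data.frame(pos = 4L, allele_paternal = "C", allele_maternal = "G")
  w <- extract_allele_window("AAAAAAA", snp, flank = 3L)
  expect_equal(w$paternal, "AAACAAA")
  expect_equal(w$maternal, "AAAGAAA")
  expect_equal(w$status, "ok")
  expect_false(w$flagged)
  # haplotype-specific nearby variant two bases left of centre
  nv <- data.frame(pos = 2L, allele_paternal = "T", allele_maternal = "A")
  w2 <- extract_allele_window("AAAAAAA", snp, flank = 3L, nearby_variants = nv)
  expect_equal(w2$paternal, "ATACAAA")
  expect_equal(w2$maternal, "AAAGAAA")
  expect_true(w2$flagged)
  # too close to the chromosome end -> rejected, not truncated
  edge <- extract_allele_window(strrep("A", 100), data.frame(
    pos = 2L, allele_paternal = "C", allele_maternal = "G"), flank = 20L)
  expect_equal(edge$status, "edge")
  expect_true(is.na(edge$paternal))
})

test_that("windows have the focal allele at the flank index and differ only at variant offsets", {
  set.seed(7)
  for (rep in 1:20) {
    len <- 200L
    ref <- rand_dna(1, len)
    pos <- sample(25:175, 1)
    alleles <- sample(c("A", "C", "G", "T"), 2)
    snp <- data.frame(pos = pos, allele_paternal = alleles[1],
                      allele_maternal = alleles[2])
    w <- extract_allele_window(ref, snp, flank = 20L)
    expect_equal(substr(w$paternal, 21, 21), alleles[1])
    expect_equal(substr(w$maternal, 21, 21), alleles[2])
    diffs <- which(strsplit(w$paternal, "")[[1]] != strsplit(w$maternal, "")[[1]])
    expect_equal(diffs, 21L)
  }
})

test_that("vectorised window extraction equals the per-SNP path", {
  set.seed(11)
  ref <- rand_dna(1, 2000)
  genome <- Biostrings::DNAStringSet(ref)
  names(genome) <- "chrZ"
  # dense variant set so nearby-variant substitution is exercised
  pos <- sort(sample(30:1970, 60))
  als <- t(replicate(60, sample(c("A", "C", "G", "T"), 2)))
  snps <- data.frame(chrom = "chrZ", pos = pos,
                     allele_paternal = als[, 1], allele_maternal = als[, 2])
  vec <- chromotif:::.extract_windows(genome, snps, flank = 20L)
  expect_true(any(vec$flagged))
  for (i in seq_len(nrow(snps))) {
    one <- extract_allele_window(ref, snps[i, ], flank = 20L,
                                 nearby_variants = snps)
    expect_identical(vec$seq_paternal[i], one$paternal)
    expect_identical(vec$seq_maternal[i], one$maternal)
    expect_identical(vec$flagged[i], one$flagged)
  }
})

test_that("classify_region applies strand-aware promoters with precedence", {
  genes <- data.frame(
    chrom = c("chr1", "chr1"),
    tx_start = c(10000L, 30000L), tx_end = c(20000L, 40000L),
    strand = c("+", "-"), gene_id = c("g1", "g2")
  )
  snps <- data.frame(
    chrom = "chr1",
    pos = c(9500L,   # 500 upstream of + TSS -> promoter
            15000L,  # inside g1 body -> genic
            3000L,   # 5 kb upstream of everything -> intergenic
            41000L,  # 1 kb past g2 end = upstream of - strand TSS -> promoter
            29000L)  # 1 kb before g2 start = downstream on - strand -> intergenic
  )
  expect_equal(classify_region(snps, genes),
               c("promoter", "genic", "intergenic", "promoter", "intergenic"))
  # empty gene set -> everything intergenic; classes are exhaustive
  expect_equal(classify_region(snps, NULL), rep("intergenic", 5))
  cls <- classify_region(snps, genes)
  expect_equal(sum(cls == "promoter") + sum(cls == "genic") +
                 sum(cls == "intergenic"), nrow(snps))
})

test_that("gene models round-trip through BED", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t999\t2000\tgeneA\t0\t+",
               "chr2\t5000\t7000\tgeneB\t0\t-"), bed)
  g <- read_gene_models(bed)
  expect_equal(g$tx_start, c(999L, 5000L))
  expect_equal(g$tx_end, c(2000L, 7000L))
  expect_equal(g$strand, c("+", "-"))
  expect_equal(g$gene_id, c("geneA", "geneB"))
})
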