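# small, fast simulation for structural checks
.small_sim <- function(seed = 5, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_chrom = 1L, chrom_len = 150000L, n_het_snps = 300L),
    list(...))
  do.call(sim_config, args)
}

test_that("simulation is byte-identical given the seed", {
  a <- simulate_dataset(.small_sim(), dir = tempfile())
  b <- simulate_dataset(.small_sim(), dir = tempfile())
  for (f in c("fasta", "vcf", "depths_path", "truth_path")) {
    expect_identical(unname(tools::md5sum(a[[f]])), unname(tools::md5sum(b[[f]])))
  }
  c2 <- simulate_dataset(.small_sim(seed = 6), dir = tempfile())
  expect_false(identical(unname(tools::md5sum(a$vcf)), unname(tools::md5sum(c2$vcf))))
})

test_that("the emitted VCF and depth table agree with the in-memory tables", {
  sim <- simulate_dataset(.small_sim(), dir = tempfile())
  snps <- load_het_snps(sim$vcf)
  expect_equal(nrow(snps), 300L)
  expect_identical(snps$allele_paternal, sim$snps$allele_paternal)
  expect_identical(snps$allele_maternal, sim$snps$allele_maternal)
  expect_identical(load_depth_table(sim$depths_path), sim$depths)
  expect_true(all(snps$allele_paternal != snps$allele_maternal))
})

test_that("planted SNPs carry the motif on the intact haplotype only, spanning the SNP", {
  sim <- simulate_dataset(.small_sim(), dir = tempfile())
  tr <- sim$truth[sim$truth$planted, ]
  expect_gt(nrow(tr), 50)
  motif <- "CACGTG"
  L <- nchar(motif)
  win <- chromotif:::.extract_windows(sim$genome,
                                      sim$snps[match(paste(tr$chrom, tr$pos),
                                                     paste(sim$snps$chrom, sim$snps$pos)), ],
                                      flank = 20L, variants = sim$snps)
  for (i in seq_len(nrow(tr))) {
    # windows with another het variant inside can legitimately perturb the
    # planted motif; the invariant is about the planted substitution itself
    if (win$flagged[i]) next
    intact_seq <- if (tr$intact_hap[i] == "paternal") win$seq_paternal[i]
      else win$seq_maternal[i]
    broken_seq <- if (tr$intact_hap[i] == "paternal") win$seq_maternal[i]
      else win$seq_paternal[i]
    o <- tr$motif_offset[i]
    # the motif sits at the recorded offset, spanning the central base
    expect_identical(substr(intact_seq, 21L - o, 21L - o + L - 1L), motif)
    expect_false(identical(substr(broken_seq, 21L - o, 21L - o + L - 1L), motif))
  }
  # offsets cover the whole motif (uniformly random phase)
  expect_gt(length(unique(tr$motif_offset)), 3)
})

test_that("null configuration gives depths exchangeable between alleles", {
  sim <- simulate_dataset(.small_sim(seed = 11, planted_fraction = 0,
                                     effect_fold = 1, n_het_snps = 2000L,
                                     chrom_len = 1000000L),
                          dir = tempfile())
  d <- sim$depths$depth_pat - sim$depths$depth_mat
  nz <- d[d != 0]
  # sign test: paternal excess should be ~ Binomial(n, 1/2)
  bt <- binom.test(sum(nz > 0), length(nz))
  expect_gt(bt$p.value, 0.001)
  expect_false(any(sim$truth$planted))
})

test_that("truth-manifest DCSR eligibility matches the called DCSR set exactly", {
  sim <- simulate_dataset(.small_sim(), dir = tempfile())
  dcsr <- suppressMessages(call_pairs(sim$depths, sim$genome, mode = "DCSR"))
  expect_setequal(paste(dcsr$chrom, dcsr$pos),
                  paste(sim$truth$chrom, sim$truth$pos)[sim$truth$dcsr_eligible])
})

test_that("sim_config validates the planted motif", {
  expect_error(sim_config(planted_motif = "CACGUG"), "A/C/G/T")
  expect_error(sim_config(planted_motif = strrep("CA", 30), flank = 20),
               "2\\*flank")
})

test_that("the TFBS fixture exercises both annotation filters", {
  fix <- simulate_tfbs_fixture(dir = tempfile())
  expect_true(any(nchar(fix$db$site_seq) > 30))        # over-long site present
  expect_true(any(fix$expression$fpkm < 1))            # unexpressed TF present
  db <- suppressMessages(load_tfbs(fix$fasta))
  expect_true(all(nchar(db$site_seq) <= 30))
  expect_true("CACGTG" %in% db$site_seq)
})

test_that("simulated peak calls overlap their source windows and label kinds", {
  set.seed(31)
  pairs <- rbind(make_pairs(rand_dna(200, 41), rand_dna(200, 41), kind = "DCSR"),
                 make_pairs(rand_dna(200, 41), rand_dna(200, 41), kind = "NDCSR",
                            chrom = "chr2"))
  bed <- tempfile(fileext = ".bed")
  peaks <- simulate_peak_calls(pairs, cover_dcsr = 0.5, cover_ndcsr = 0.5,
                               bed_path = bed)
  expect_gt(nrow(peaks), 0)
  expect_equal(read_peaks(bed), peaks)
  tab <- peak_association(pairs, peaks)
  expect_equal(sum(tab), nrow(peaks))
})
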