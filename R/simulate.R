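#' Simulation configuration
#'
#' Parameters of the synthetic allele-specific accessibility data set. The
#' defaults describe the reference simulation used throughout the package's
#' tests: 2,000 phased het SNPs on two 1.35 Mb chromosomes (about one het
#' per 1.35 kb, the density of a typical human genome), negative-binomial
#' per-allele depths with mean 20 and dispersion (size) 5, and 30% of SNPs
#' "planted" so that one haplotype completes a CACGTG spanning the SNP
#' while the other breaks it, the intact-motif allele drawing its depth
#' with a 5-fold boosted mean.
#'
#' @param seed RNG seed; every source of randomness flows from it.
#' @param n_chrom,chrom_len number and length (bases) of chromosomes.
#' @param n_het_snps total phased het SNPs.
#' @param planted_motif DNA word planted across SNPs (default CACGTG).
#' @param planted_fraction fraction of SNPs carrying a planted disruption.
#' @param base_depth_mean,depth_dispersion negative-binomial mean and size
#'   for per-allele read depth.
#' @param effect_fold multiplicative depth-mean boost for the motif-intact
#'   allele (1 = null, no signal).
#' @param gc_content genome GC fraction (default 0.41, human-like).
#' @param flank window flank used downstream; the planted motif must fit in
#'   a `2 * flank + 1` window.
#' @return named list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chrom = 2L, chrom_len = 1350000L,
                       n_het_snps = 2000L, planted_motif = "CACGTG",
                       planted_fraction = 0.3, base_depth_mean = 20,
                       depth_dispersion = 5, effect_fold = 5,
                       gc_content = 0.41, flank = 20L) {
  cfg <- list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
              chrom_len = as.integer(chrom_len),
              n_het_snps = as.integer(n_het_snps),
              planted_motif = toupper(planted_motif),
              planted_fraction = planted_fraction,
              base_depth_mean = base_depth_mean,
              depth_dispersion = depth_dispersion,
              effect_fold = effect_fold, gc_content = gc_content,
              flank = as.integer(flank))
  stopifnot(cfg$planted_fraction >= 0, cfg$planted_fraction <= 1,
            cfg$effect_fold >= 1, cfg$base_depth_mean > 0,
            cfg$depth_dispersion > 0, cfg$gc_content > 0, cfg$gc_content < 1,
            cfg$n_het_snps >= 1, cfg$n_chrom >= 1)
  if (grepl("[^ACGT]", cfg$planted_motif))
    stop("planted_motif must be over A/C/G/T")
  if (nchar(cfg$planted_motif) > 2L * cfg$flank + 1L)
    stop("planted motif is longer than the ", 2L * cfg$flank + 1L,
         "-base window (2*flank + 1)")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a full synthetic input set
#'
#' Generates a random reference genome, phased het SNPs, and per-allele
#' FAIRE-style depths, and writes the exact formats the pipeline consumes:
#' a FASTA reference, a phased VCF 4.2, a depth TSV, and a truth manifest
#' TSV. At planted SNPs one haplotype's base completes `planted_motif`
#' spanning the SNP at a uniformly random in-motif offset and the other
#' haplotype breaks it; the intact allele's depth is drawn with mean
#' `base_depth_mean * effect_fold`. Non-planted SNP depths are independent
#' draws from the same distribution on both alleles, hence exchangeable.
#' Output is deterministic given the seed, which is recorded in every file
#' header.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return list with paths (`fasta`, `vcf`, `depths`, `truth`) and the
#'   in-memory `genome` (DNAStringSet), `snps`, `depths` and `truth` tables.
#'   The truth manifest records each SNP's planted status, intact
#'   haplotype, in-motif offset and realized DCSR eligibility (fold > 2,
#'   greater depth >= 10).
#' @export
simulate_dataset <- function(config = sim_config(), dir = tempfile("simdat")) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  bases <- c("A", "C", "G", "T")
  pbase <- c((1 - config$gc_content) / 2, config$gc_content / 2,
             config$gc_content / 2, (1 - config$gc_content) / 2)
  motif <- strsplit(config$planted_motif, "")[[1]]
  L <- length(motif)
  margin <- config$flank + L + 1L

  chroms <- paste0("chr", seq_len(config$n_chrom))
  seqs <- lapply(seq_len(config$n_chrom), function(i)
    sample(bases, config$chrom_len, replace = TRUE, prob = pbase))
  names(seqs) <- chroms

  # spread SNPs over chromosomes; distinct sorted positions per chromosome
  # with pairwise gaps > motif length, so one SNP's planted footprint can
  # never overwrite another SNP's allele (gaps of 7-20 bases still occur,
  # exercising the nearby-variant flagging)
  snp_chrom_idx <- sort(sample.int(config$n_chrom, config$n_het_snps, replace = TRUE))
  pos_list <- lapply(seq_len(config$n_chrom), function(i) {
    k <- sum(snp_chrom_idx == i)
    span <- config$chrom_len - 2L * margin - k * L
    if (span <= k) stop("chrom_len too small for n_het_snps")
    sort(sample.int(span, k)) + margin + seq_len(k) * L
  })
  snp_chrom <- chroms[snp_chrom_idx]
  snp_pos <- unlist(pos_list)
  n <- config$n_het_snps
  planted <- rep(FALSE, n)
  planted[sample.int(n, round(config$planted_fraction * n))] <- TRUE

  allele_pat <- allele_mat <- character(n)
  intact_hap <- rep(NA_character_, n)
  motif_offset <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    ci <- snp_chrom_idx[i]; p <- snp_pos[i]
    if (planted[i]) {
      o <- sample.int(L, 1L) - 1L              # motif index of the SNP base
      seqs[[ci]][(p - o):(p - o + L - 1L)] <- motif
      intact <- motif[o + 1L]
      broken <- sample(setdiff(bases, intact), 1L)
      hap <- sample(c("paternal", "maternal"), 1L)
      if (hap == "paternal") { allele_pat[i] <- intact; allele_mat[i] <- broken }
      else { allele_pat[i] <- broken; allele_mat[i] <- intact }
      intact_hap[i] <- hap
      motif_offset[i] <- o
      seqs[[ci]][p] <- sample(c(intact, broken), 1L)  # REF independent of effect
    } else {
      r <- seqs[[ci]][p]
      other <- sample(setdiff(bases, r), 1L)
      if (stats::runif(1) < 0.5) { allele_pat[i] <- r; allele_mat[i] <- other }
      else { allele_pat[i] <- other; allele_mat[i] <- r }
    }
  }

  mu_pat <- ifelse(planted & intact_hap == "paternal",
                   config$base_depth_mean * config$effect_fold,
                   config$base_depth_mean)
  mu_mat <- ifelse(planted & intact_hap == "maternal",
                   config$base_depth_mean * config$effect_fold,
                   config$base_depth_mean)
  depth_pat <- as.integer(stats::rnbinom(n, size = config$depth_dispersion, mu = mu_pat))
  depth_mat <- as.integer(stats::rnbinom(n, size = config$depth_dispersion, mu = mu_mat))

  genome <- Biostrings::DNAStringSet(vapply(seqs, paste, character(1), collapse = ""))
  names(genome) <- paste0(chroms, " seed=", config$seed)
  fasta <- file.path(dir, "reference.fa")
  Biostrings::writeXStringSet(genome, fasta)
  names(genome) <- chroms

  snps <- data.frame(chrom = snp_chrom, pos = snp_pos,
                     allele_paternal = allele_pat, allele_maternal = allele_mat,
                     phased = TRUE)
  depths <- data.frame(chrom = snp_chrom, pos = snp_pos,
                       allele_pat = allele_pat, allele_mat = allele_mat,
                       depth_pat = depth_pat, depth_mat = depth_mat)
  hi <- pmax(depth_pat, depth_mat); lo <- pmin(depth_pat, depth_mat)
  truth <- data.frame(
    chrom = snp_chrom, pos = snp_pos, planted = planted,
    intact_hap = intact_hap, motif_offset = motif_offset,
    depth_pat = depth_pat, depth_mat = depth_mat,
    dcsr_eligible = ifelse(lo == 0L, hi >= 10L, hi / lo > 2 & hi >= 10L)
  )

  vcf <- file.path(dir, "variants.vcf")
  ref_at <- vapply(seq_len(n), function(i) seqs[[snp_chrom_idx[i]]][snp_pos[i]],
                   character(1))
  alt_at <- ifelse(allele_pat == ref_at, allele_mat, allele_pat)
  gt <- ifelse(allele_pat == ref_at, "0|1", "1|0")
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=chromotif simulate_dataset seed=", config$seed),
           paste0("##contig=<ID=", chroms, ",length=", config$chrom_len, ">"),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "SIM001", sep = "\t"))
  body <- paste(snp_chrom, snp_pos, ".", ref_at, alt_at, ".", "PASS", ".",
                "GT", gt, sep = "\t")
  writeLines(c(hdr, body), vcf)

  depths_path <- file.path(dir, "depths.tsv")
  write_depth_table(depths, depths_path, comment = paste("seed:", config$seed))
  truth_path <- file.path(dir, "truth.tsv")
  con <- file(truth_path, "w")
  writeLines(paste("# seed:", config$seed), con)
  utils::write.table(truth, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)

  list(fasta = fasta, vcf = vcf, depths_path = depths_path,
       truth_path = truth_path, genome = genome, snps = snps,
       depths = depths, truth = truth)
}

#' Simulate allele-specific peak calls over called pairs
#'
#' Emulates a ChIP-seq peak set for the validation stage: a small fraction
#' of DCSR and NDCSR windows receive an overlapping peak, labelled
#' allele-specific with a kind-dependent probability. The defaults mirror
#' the margins of the published MYC validation (about 0.9% of DCSRs and
#' 1.6% of NDCSRs overlapping a peak; 46% vs 26% of those allele-specific).
#'
#' @param pairs called pairs of both kinds (row-bound [call_pairs()] output).
#' @param cover_dcsr,cover_ndcsr probability a window of each kind gets a peak.
#' @param p_as_dcsr,p_as_ndcsr probability an overlapping peak is
#'   allele-specific, by kind.
#' @param halfwidth peak half-width in bases (default 100).
#' @param bed_path optional path; when given, the peaks are also written as
#'   BED with names `AS`/`NAS`.
#' @return peaks data.frame as from [read_peaks()].
#' @export
simulate_peak_calls <- function(pairs, cover_dcsr = 0.009, cover_ndcsr = 0.016,
                                p_as_dcsr = 31 / 67, p_as_ndcsr = 21 / 82,
                                halfwidth = 100L, bed_path = NULL) {
  is_d <- pairs$kind == "DCSR"
  cover <- ifelse(is_d, cover_dcsr, cover_ndcsr)
  has_peak <- stats::runif(nrow(pairs)) < cover
  p_as <- ifelse(is_d, p_as_dcsr, p_as_ndcsr)
  as_flag <- stats::runif(nrow(pairs)) < p_as
  idx <- which(has_peak)
  centre <- (pairs$start[idx] + pairs$end[idx]) %/% 2L
  peaks <- data.frame(
    chrom = pairs$chrom[idx],
    start = pmax(centre - halfwidth, 0L),
    end = centre + halfwidth,
    allele_specific = as_flag[idx]
  )
  if (!is.null(bed_path)) {
    bed <- data.frame(peaks$chrom, peaks$start, peaks$end,
                      ifelse(peaks$allele_specific, "AS", "NAS"))
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  peaks
}

#' Simulate a TFBS fixture database and expression table
#'
#' Emits a small FASTA of binding-site sequences (headers `TF|source`) and
#' a TSV of FPKM values for annotation tests. The default specs include a
#' CACGTG-binding factor, one unexpressed factor (FPKM 0.2) and one
#' over-long (35-base) site, so both annotation filters are exercised.
#'
#' @param tf_specs data.frame with `tf_name`, `site_seq`, `source`, `fpkm`;
#'   `NULL` uses the built-in fixture specs.
#' @param dir output directory.
#' @return list with `fasta`, `expression_path`, and the `db` and
#'   `expression` data.frames as written.
#' @export
simulate_tfbs_fixture <- function(tf_specs = NULL, dir = tempfile("tfbs")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(tf_specs)) {
    tf_specs <- data.frame(
      tf_name = c("MAXFIX", "USF1FIX", "RXRFIX", "SILENTFIX", "LONGFIX"),
      site_seq = c("CACGTG", "GGTCACGTGAC", "AGGTCAGGAG", "CTCCTGAC",
                   paste(rep("ACGTT", 7), collapse = "")),  # 35 bases
      source = c("TFe", "hPDI", "TFe", "TFe", "TFe"),
      fpkm = c(12, 8, 5, 0.2, 7)
    )
  }
  fasta <- file.path(dir, "tfbs.fa")
  writeLines(as.vector(rbind(
    paste0(">", tf_specs$tf_name, "|", tf_specs$source),
    tf_specs$site_seq)), fasta)
  expression <- unique(tf_specs[, c("tf_name", "fpkm")])
  expression_path <- file.path(dir, "expression.tsv")
  utils::write.table(expression, expression_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(fasta = fasta, expression_path = expression_path,
       db = tf_specs[, c("tf_name", "site_seq", "source")],
       expression = expression)
}
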