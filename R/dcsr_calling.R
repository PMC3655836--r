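#' Call DCSR or NDCSR pairs from allele depths
#'
#' A differential chromatin-state region (DCSR) pair is the pair of 41-base
#' haplotype windows around a het SNP whose allele-resolved read depths are
#' strongly imbalanced: fold change strictly > 2 and greater depth >= 10.
#' The higher-depth window is the accessible member, the lower-depth one
#' inaccessible. NDCSRs are the balanced controls: fold change strictly
#' < 1.5 and greater depth >= 5; equal depths (fold 1) qualify, with the
#' accessible label assigned to the paternal allele for reproducibility.
#' A zero lower depth gives infinite fold change, which can qualify as a
#' DCSR (given the depth floor) but never as an NDCSR.
#'
#' Windows that would run past a chromosome end, or that contain an `N`
#' after substitution, are dropped; a summary of skipped records is
#' reported via `message()`. Overlapping windows from nearby qualifying
#' SNPs are all retained. Pairs whose windows differ away from the centre
#' because another phased variant fell inside the window are flagged in
#' `flagged_nearby_variant`.
#'
#' @param depths depth table from [load_depth_table()] (also serves as the
#'   phased-variant set for window substitution).
#' @param genome `DNAStringSet` reference (e.g. [read_genome()]).
#' @param genes optional gene models for region classification
#'   ([read_gene_models()]); `NULL` classifies all pairs intergenic.
#' @param mode `"DCSR"` or `"NDCSR"`.
#' @param config thresholds ([default_config()]): `flank`, `dcsr_fold`,
#'   `dcsr_depth`, `ndcsr_fold`, `ndcsr_depth`, `promoter_up`.
#' @return data.frame with one row per called pair: `chrom`, `pos`, `start`,
#'   `end` (0-based half-open window), alleles, `accessible_allele`,
#'   `depth_high`, `depth_low`, `fold_change`, `region`, `kind`,
#'   `seq_accessible`, `seq_inaccessible`, `flagged_nearby_variant`.
#' @export
call_pairs <- function(depths, genome, genes = NULL,
                       mode = c("DCSR", "NDCSR"), config = default_config()) {
  mode <- match.arg(mode)
  validate_config(config)
  if (nrow(depths) == 0L) return(.empty_pairs())
  hi <- pmax(depths$depth_pat, depths$depth_mat)
  lo <- pmin(depths$depth_pat, depths$depth_mat)
  fold <- ifelse(lo == 0L, Inf, hi / lo)   # 0/0 -> Inf but fails the depth floor
  qual <- if (mode == "DCSR") {
    fold > config$dcsr_fold & hi >= config$dcsr_depth
  } else {
    fold < config$ndcsr_fold & hi >= config$ndcsr_depth
  }
  qual <- qual & hi > 0L
  n_skipped <- sum(!qual)
  cand <- depths[qual, , drop = FALSE]
  if (nrow(cand) == 0L) {
    message(mode, " calling: 0 of ", nrow(depths), " SNPs qualified")
    return(.empty_pairs())
  }
  snps <- data.frame(chrom = cand$chrom, pos = cand$pos,
                     allele_paternal = cand$allele_pat,
                     allele_maternal = cand$allele_mat)
  allvars <- data.frame(chrom = depths$chrom, pos = depths$pos,
                        allele_paternal = depths$allele_pat,
                        allele_maternal = depths$allele_mat)
  win <- .extract_windows(genome, snps, flank = config$flank, variants = allvars)
  edge <- win$status == "edge"
  hasN <- !edge & (grepl("N", win$seq_paternal, fixed = TRUE) |
                     grepl("N", win$seq_maternal, fixed = TRUE))
  keep <- !edge & !hasN
  message(mode, " calling: ", sum(keep), " pairs from ", nrow(depths),
          " SNPs (", n_skipped, " below thresholds, ", sum(edge),
          " at chromosome edge, ", sum(hasN), " with N)")
  if (!any(keep)) return(.empty_pairs())
  cand <- cand[keep, , drop = FALSE]
  win <- win[keep, , drop = FALSE]
  # accessible = higher-depth allele; ties -> paternal (NDCSR only)
  acc_pat <- cand$depth_pat >= cand$depth_mat
  out <- data.frame(
    chrom = cand$chrom,
    pos = cand$pos,
    start = win$start,
    end = win$end,
    allele_paternal = cand$allele_pat,
    allele_maternal = cand$allele_mat,
    accessible_allele = ifelse(acc_pat, "paternal", "maternal"),
    depth_high = pmax(cand$depth_pat, cand$depth_mat),
    depth_low = pmin(cand$depth_pat, cand$depth_mat),
    fold_change = ifelse(pmin(cand$depth_pat, cand$depth_mat) == 0L, Inf,
                         pmax(cand$depth_pat, cand$depth_mat) /
                           pmin(cand$depth_pat, cand$depth_mat)),
    region = classify_region(cand, genes, promoter_up = config$promoter_up),
    kind = mode,
    seq_accessible = ifelse(acc_pat, win$seq_paternal, win$seq_maternal),
    seq_inaccessible = ifelse(acc_pat, win$seq_maternal, win$seq_paternal),
    flagged_nearby_variant = win$flagged,
    row.names = NULL
  )
  out
}

.empty_pairs <- function() {
  data.frame(chrom = character(), pos = integer(), start = integer(),
             end = integer(), allele_paternal = character(),
             allele_maternal = character(), accessible_allele = character(),
             depth_high = integer(), depth_low = integer(),
             fold_change = numeric(), region = character(), kind = character(),
             seq_accessible = character(), seq_inaccessible = character(),
             flagged_nearby_variant = logical())
}

#' Partition called pairs by region class
#'
#' @param pairs data.frame from [call_pairs()].
#' @return named list with `genome_wide` (all pairs), `promoter`, `genic`
#'   and `intergenic`; the three region lists concatenate back to
#'   `genome_wide`.
#' @export
partition_by_region <- function(pairs) {
  list(
    genome_wide = pairs,
    promoter = pairs[pairs$region == "promoter", , drop = FALSE],
    genic = pairs[pairs$region == "genic", , drop = FALSE],
    intergenic = pairs[pairs$region == "intergenic", , drop = FALSE]
  )
}

#' Write called pairs to TSV and paired FASTA
#'
#' Emits `<prefix>.pairs.tsv` (one row per pair, BED-like coordinates) and
#' `<prefix>.pairs.fa` with two records per pair whose headers encode
#' `chrom:pos:allele:role` (role `accessible` or `inaccessible`).
#'
#' @param pairs data.frame from [call_pairs()].
#' @param prefix output path prefix.
#' @return character vector of the two paths written, invisibly.
#' @export
write_pairs <- function(pairs, prefix) {
  tsv <- paste0(prefix, ".pairs.tsv")
  fa <- paste0(prefix, ".pairs.fa")
  utils::write.table(pairs, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(pairs) > 0L) {
    acc_allele <- ifelse(pairs$accessible_allele == "paternal",
                         pairs$allele_paternal, pairs$allele_maternal)
    inacc_allele <- ifelse(pairs$accessible_allele == "paternal",
                           pairs$allele_maternal, pairs$allele_paternal)
    seqs <- Biostrings::DNAStringSet(
      as.vector(rbind(pairs$seq_accessible, pairs$seq_inaccessible)))
    names(seqs) <- as.vector(rbind(
      paste(pairs$chrom, pairs$pos, acc_allele, "accessible", sep = ":"),
      paste(pairs$chrom, pairs$pos, inacc_allele, "inaccessible", sep = ":")))
    Biostrings::writeXStringSet(seqs, fa)
  } else {
    file.create(fa)
  }
  invisible(c(tsv, fa))
}

#' Read a pairs table written by [write_pairs()]
#'
#' @param tsv_path path to a `.pairs.tsv` file.
#' @return pairs data.frame.
#' @export
read_pairs <- function(tsv_path) {
  utils::read.table(tsv_path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
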