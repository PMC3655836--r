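#' Load a per-allele read-depth table
#'
#' The primary depth input: one row per phased het SNP with the FAIRE-seq
#' read count observed on each haplotype. The canonical upstream producer is
#' an aligner run against the personal diploid genome; [depth_from_alignments()]
#' provides an approximation from haploid-reference alignments.
#'
#' @param tsv_path tab-separated file with a header line and columns
#'   `chrom`, `pos`, `allele_pat`, `allele_mat`, `depth_pat`, `depth_mat`.
#'   Lines starting with `#` are ignored.
#' @return data.frame with those columns (`pos` and depths integer).
#' @export
load_depth_table <- function(tsv_path) {
  if (!file.exists(tsv_path)) stop("depth table not found: ", tsv_path)
  d <- utils::read.table(tsv_path, header = TRUE, sep = "\t",
                         comment.char = "#", stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "allele_pat", "allele_mat", "depth_pat", "depth_mat")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("depth table schema error: missing column(s) ", paste(miss, collapse = ", "))
  d <- d[, req]
  if (nrow(d) == 0L) return(d)
  d$pos <- as.integer(d$pos)
  d$depth_pat <- as.integer(d$depth_pat)
  d$depth_mat <- as.integer(d$depth_mat)
  if (any(is.na(d$depth_pat)) || any(is.na(d$depth_mat)) ||
      any(d$depth_pat < 0L) || any(d$depth_mat < 0L))
    stop("depth table validation error: depths must be non-negative integers")
  key <- paste(d$chrom, d$pos)
  if (anyDuplicated(key))
    stop("depth table validation error: duplicated position(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  d
}

#' Write a per-allele read-depth table
#'
#' Inverse of [load_depth_table()]; the round trip is exact.
#'
#' @param records depth data.frame.
#' @param tsv_path output path.
#' @param comment optional `#`-prefixed header comment lines (e.g. the seed).
#' @return `tsv_path`, invisibly.
#' @export
write_depth_table <- function(records, tsv_path, comment = NULL) {
  con <- file(tsv_path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(records, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tsv_path)
}

# read base aligned over 1-based reference position `target`, or NA when
# the read has a deletion/skip there or does not cover it
.base_at <- function(read_start, cigar, seq, target) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1L]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1L]]
  ref <- read_start
  q <- 1L
  for (i in seq_along(ops)) {
    op <- ops[i]; len <- lens[i]
    if (op %in% c("M", "=", "X")) {
      if (target >= ref && target < ref + len)
        return(substr(seq, q + (target - ref), q + (target - ref)))
      ref <- ref + len; q <- q + len
    } else if (op %in% c("I", "S")) {
      q <- q + len
    } else if (op %in% c("D", "N")) {
      if (target >= ref && target < ref + len) return(NA_character_)
      ref <- ref + len
    }  # H, P consume nothing
  }
  NA_character_
}

#' Count per-allele read depth at het SNPs from alignments
#'
#' Approximates diploid-genome allele-resolved depth from haploid-reference
#' alignments: for each het SNP, reads overlapping the position are
#' classified by their aligned base there, and tallied as paternal or
#' maternal depth when the base equals that haplotype's allele. Reads
#' carrying any other base, or a deletion at the position, contribute to
#' neither count; each read is counted at most once per SNP, and a read
#' spanning several het SNPs is tallied at each independently.
#'
#' With `require_perfect = TRUE`, only reads aligned without any mismatch
#' *outside the focal base* are counted (emulating perfect-match diploid
#' mapping): a read whose SNP base equals the reference may carry no
#' mismatch (`NM` 0), a read carrying the alternate allele exactly one.
#' This needs the `NM` tag and the reference `genome`.
#'
#' @param alignment_path coordinate-sorted, indexed BAM.
#' @param snps het SNP table from [load_het_snps()].
#' @param require_perfect drop reads with mismatches away from the SNP.
#' @param dedup exclude duplicate-flagged reads (default counts them as-is).
#' @param min_mapq minimum mapping quality (default 0).
#' @param genome reference `DNAStringSet`; required when `require_perfect`.
#' @return depth data.frame as from [load_depth_table()]; SNPs with no
#'   qualifying coverage get depth 0 on both alleles.
#' @export
depth_from_alignments <- function(alignment_path, snps, require_perfect = FALSE,
                                  dedup = FALSE, min_mapq = 0L, genome = NULL) {
  if (!file.exists(alignment_path)) stop("alignment file not found: ", alignment_path)
  idx <- paste0(alignment_path, ".bai")
  if (!file.exists(idx) && !file.exists(sub("\\.bam$", ".bai", alignment_path)))
    stop("alignment file is not indexed: ", alignment_path,
         " -- index it first (Rsamtools::indexBam or `samtools index`)")
  if (require_perfect && is.null(genome))
    stop("require_perfect = TRUE needs the reference `genome` to place the SNP base")
  which_gr <- GenomicRanges::GRanges(snps$chrom,
                                     IRanges::IRanges(snps$pos, width = 1L))
  sbp <- Rsamtools::ScanBamParam(
    which = which_gr,
    what = c("pos", "cigar", "seq"),
    tag = "NM",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isDuplicate = if (dedup) FALSE else NA),
    mapqFilter = min_mapq
  )
  hits <- Rsamtools::scanBam(alignment_path, param = sbp)
  out <- data.frame(
    chrom = snps$chrom, pos = as.integer(snps$pos),
    allele_pat = toupper(snps$allele_paternal),
    allele_mat = toupper(snps$allele_maternal),
    depth_pat = 0L, depth_mat = 0L
  )
  for (i in seq_len(nrow(out))) {
    h <- hits[[i]]
    nreads <- length(h$pos)
    if (nreads == 0L) next
    bases <- vapply(seq_len(nreads), function(j)
      .base_at(h$pos[j], h$cigar[j], as.character(h$seq[j]), out$pos[i]),
      character(1))
    if (require_perfect) {
      ref_base <- toupper(substr(as.character(genome[[out$chrom[i]]]),
                                 out$pos[i], out$pos[i]))
      nm <- h$tag$NM
      allowed_nm <- ifelse(is.na(bases) | bases == ref_base, 0L, 1L)
      keep <- !is.na(nm) & nm == allowed_nm
      bases <- bases[keep]
    }
    out$depth_pat[i] <- sum(bases == out$allele_pat[i], na.rm = TRUE)
    out$depth_mat[i] <- sum(bases == out$allele_mat[i], na.rm = TRUE)
  }
  out
}
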