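#' Load phased heterozygous SNPs from a VCF
#'
#' Reads a VCF 4.x file and returns the biallelic, single-base, phased
#' heterozygous records as a data frame of het SNPs. The two phased
#' haplotypes of the GT field are mapped to the paternal and maternal
#' alleles; with the default `haplotype_order = c(1, 2)` the first field of
#' `a|b` is paternal. Fully phased parental assignment is a property of the
#' input (e.g. a trio-phased personal genome); for arbitrary VCFs the labels
#' are conventional.
#'
#' Records are dropped (never errors) when they are homozygous, multiallelic,
#' indels, or missing genotypes. Heterozygous but *unphased* records ("0/1")
#' are skipped with a warning, since their alleles cannot be assigned to a
#' haplotype.
#'
#' @param vcf_path path to a VCF (optionally bgzipped).
#' @param haplotype_order integer permutation of 1:2; which GT field is the
#'   paternal haplotype.
#' @param sample sample name or index to use; defaults to the first sample.
#' @return data.frame with columns `chrom`, `pos` (1-based), `allele_paternal`,
#'   `allele_maternal`, `phased` (all TRUE in the returned set).
#' @export
load_het_snps <- function(vcf_path, haplotype_order = c(1L, 2L), sample = 1L) {
  if (!file.exists(vcf_path)) stop("VCF not found: ", vcf_path)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(fix) || nrow(fix) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      allele_paternal = character(),
                      allele_maternal = character(),
                      phased = logical()))
  }
  gt_all <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt_all) || ncol(gt_all) == 0L) stop("VCF has no GT field: ", vcf_path)
  gt <- gt_all[, sample]

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snv <- !is.na(ref) & !is.na(alt) &
    ref %in% c("A", "C", "G", "T") &
    alt %in% c("A", "C", "G", "T")        # excludes indels and multiallelics

  phased <- grepl("|", gt, fixed = TRUE)
  sep <- ifelse(phased, "|", "/")
  a1 <- suppressWarnings(as.integer(substr(gt, 1L, regexpr("[|/]", gt) - 1L)))
  a2 <- suppressWarnings(as.integer(sub("^[0-9.]+[|/]", "", gt)))
  het <- !is.na(a1) & !is.na(a2) & a1 != a2 & a1 <= 1L & a2 <= 1L

  n_unphased_het <- sum(snv & het & !phased, na.rm = TRUE)
  if (n_unphased_het > 0L) {
    warning(n_unphased_het,
            " unphased heterozygous record(s) skipped (cannot assign haplotypes)")
  }
  keep <- which(snv & het & phased)
  alleles <- cbind(ref, alt)  # index 0 -> REF, 1 -> ALT
  hap <- cbind(a1, a2)
  pat <- alleles[cbind(keep, hap[keep, haplotype_order[1L]] + 1L)]
  mat <- alleles[cbind(keep, hap[keep, haplotype_order[2L]] + 1L)]
  data.frame(
    chrom = fix[keep, "CHROM"],
    pos = as.integer(fix[keep, "POS"]),
    allele_paternal = pat,
    allele_maternal = mat,
    phased = TRUE,
    row.names = NULL
  )
}

#' Reverse complement of DNA sequences
#'
#' Vectorised; input restricted to A/C/G/T/N (uppercase or lowercase),
#' output uppercase. Used to report the antisense form of each motif;
#' palindromic motifs (e.g. CACGTG) are their own reverse complement.
#'
#' @param seq character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @examples
#' reverse_complement("CTCCTGAC")  # "GTCAGGAG"
#' @export
reverse_complement <- function(seq) {
  seq <- toupper(seq)
  if (any(grepl("[^ACGTN]", seq)))
    stop("sequences must contain only A/C/G/T/N")
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Extract the paternal/maternal sequence windows around a het SNP
#'
#' Builds the two haplotype sequences of the window `[pos - flank, pos + flank]`
#' by substituting the focal allele at the centre and every other phased
#' heterozygous variant inside the window on its own haplotype. A window
#' whose flank would run off the chromosome end is rejected with status
#' `"edge"` rather than truncated. The result is flagged when at least one
#' non-focal variant was substituted, since such windows can differ at more
#' than the central base.
#'
#' @param ref_seq the chromosome sequence: a single character string or a
#'   `DNAString`.
#' @param snp a one-row data.frame (or list) with `pos`, `allele_paternal`,
#'   `allele_maternal`.
#' @param flank bases on each side of the SNP (default 20, i.e. 41-base
#'   windows).
#' @param nearby_variants optional data.frame of phased het SNPs on the same
#'   chromosome (`pos`, `allele_paternal`, `allele_maternal`); the focal
#'   position is ignored if present.
#' @return list with `paternal`, `maternal` (uppercase sequences, the focal
#'   allele at index `flank + 1`), `start`/`end` (0-based half-open),
#'   `status` (`"ok"` or `"edge"`), and `flagged` (nearby variant
#'   substituted).
#' @export
extract_allele_window <- function(ref_seq, snp, flank = 20L, nearby_variants = NULL) {
  stopifnot(flank >= 1L)
  ref_seq <- toupper(as.character(ref_seq))
  pos <- as.integer(snp$pos)
  L <- nchar(ref_seq)
  if (pos - flank < 1L || pos + flank > L) {
    return(list(paternal = NA_character_, maternal = NA_character_,
                start = pos - flank - 1L, end = pos + flank,
                status = "edge", flagged = FALSE))
  }
  w <- substr(ref_seq, pos - flank, pos + flank)
  pat <- mat <- w
  centre <- flank + 1L
  substr(pat, centre, centre) <- toupper(snp$allele_paternal)
  substr(mat, centre, centre) <- toupper(snp$allele_maternal)
  flagged <- FALSE
  if (!is.null(nearby_variants) && nrow(nearby_variants) > 0L) {
    nv <- nearby_variants[nearby_variants$pos != pos &
                            nearby_variants$pos >= pos - flank &
                            nearby_variants$pos <= pos + flank, , drop = FALSE]
    if (nrow(nv) > 0L) {
      flagged <- TRUE
      off <- nv$pos - (pos - flank) + 1L
      for (i in seq_len(nrow(nv))) {
        substr(pat, off[i], off[i]) <- toupper(nv$allele_paternal[i])
        substr(mat, off[i], off[i]) <- toupper(nv$allele_maternal[i])
      }
    }
  }
  list(paternal = pat, maternal = mat,
       start = pos - flank - 1L, end = pos + flank,
       status = "ok", flagged = flagged)
}

# Vectorised window extraction over a whole SNP table; equivalent to
# calling extract_allele_window() per row (property-tested), but the centre
# substitution is done in bulk and the per-variant loop only runs for the
# few windows that contain a nearby het variant.
# genome: named DNAStringSet (or named character); variants: het SNP table
# used for nearby-variant substitution (normally the full het set).
# Returns data.frame(seq_paternal, seq_maternal, start, end, status, flagged)
# aligned row-by-row with `snps`.
.extract_windows <- function(genome, snps, flank = 20L, variants = snps) {
  chrseq <- if (is(genome, "DNAStringSet")) {
    setNames(as.character(genome), names(genome))
  } else setNames(toupper(as.character(genome)), names(genome))
  names(chrseq) <- sub("\\s.*$", "", names(chrseq))
  n <- nrow(snps)
  out <- data.frame(
    seq_paternal = rep(NA_character_, n),
    seq_maternal = rep(NA_character_, n),
    start = as.integer(snps$pos) - flank - 1L,
    end = as.integer(snps$pos) + flank,
    status = rep("ok", n), flagged = rep(FALSE, n)
  )
  centre <- flank + 1L
  width <- 2L * flank + 1L
  for (ch in unique(snps$chrom)) {
    if (!ch %in% names(chrseq)) stop("chromosome not in genome: ", ch)
    s <- toupper(chrseq[[ch]])
    L <- nchar(s)
    idx <- which(snps$chrom == ch)
    pos <- as.integer(snps$pos[idx])
    edge <- pos - flank < 1L | pos + flank > L
    out$status[idx[edge]] <- "edge"
    ok <- idx[!edge]
    if (!length(ok)) next
    pos <- pos[!edge]
    w <- substring(s, pos - flank, pos + flank)
    left <- substr(w, 1L, flank)
    right <- substr(w, centre + 1L, width)
    pat <- paste0(left, toupper(snps$allele_paternal[ok]), right)
    mat <- paste0(left, toupper(snps$allele_maternal[ok]), right)
    vv <- variants[variants$chrom == ch, , drop = FALSE]
    vv <- vv[order(vv$pos), , drop = FALSE]
    vpos <- as.integer(vv$pos)
    if (length(vpos)) {
      lo <- findInterval(pos - flank - 1L, vpos) + 1L
      hi <- findInterval(pos + flank, vpos)
      self_j <- findInterval(pos, vpos)
      has_self <- self_j >= 1L & vpos[pmax(self_j, 1L)] == pos
      n_near <- (hi - lo + 1L) - as.integer(has_self)
      for (k in which(n_near > 0L)) {
        jj <- setdiff(seq.int(lo[k], hi[k]),
                      if (has_self[k]) self_j[k] else integer(0))
        off <- vpos[jj] - (pos[k] - flank) + 1L
        pk <- pat[k]; mk <- mat[k]
        for (m in seq_along(jj)) {
          substr(pk, off[m], off[m]) <- toupper(vv$allele_paternal[jj[m]])
          substr(mk, off[m], off[m]) <- toupper(vv$allele_maternal[jj[m]])
        }
        pat[k] <- pk; mat[k] <- mk
        out$flagged[ok[k]] <- TRUE
      }
    }
    out$seq_paternal[ok] <- pat
    out$seq_maternal[ok] <- mat
  }
  out
}

#' Read gene models from BED or GTF/GFF
#'
#' Wraps `rtracklayer::import()` and converts to the internal 0-based
#' half-open transcript table. For GTF/GFF input, rows of type `gene`,
#' `transcript` or `mRNA` are used (exons are aggregated per `gene_id` when
#' no such rows exist).
#'
#' @param path BED6 or GTF/GFF file.
#' @param format `"auto"` (by extension), `"bed"` or `"gtf"`.
#' @return data.frame with `chrom`, `tx_start`, `tx_end` (0-based half-open),
#'   `strand`, `gene_id`.
#' @export
read_gene_models <- function(path, format = c("auto", "bed", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "bed" else "gtf"
  }
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF")
  if (format == "gtf") {
    ty <- as.character(gr$type)
    keep <- ty %in% c("gene", "transcript", "mRNA")
    if (any(keep)) {
      gr <- gr[keep]
    } else {
      ids <- if (!is.null(gr$gene_id)) gr$gene_id else as.character(seq_along(gr))
      gr <- unlist(range(GenomicRanges::split(gr, ids)))
      gr$name <- names(gr)
    }
  }
  ids <- if (!is.null(gr$name)) as.character(gr$name)
    else if (!is.null(gr$gene_id)) as.character(gr$gene_id)
    else paste0("gene", seq_along(gr))
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    tx_start = GenomicRanges::start(gr) - 1L,
    tx_end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = ids,
    row.names = NULL
  )
}

#' Classify SNP positions as promoter, genic or intergenic
#'
#' Promoters are the strand-aware upstream interval `[TSS - promoter_up, TSS)`
#' of each gene; genic is anywhere inside a transcript body; everything else
#' is intergenic. Precedence is promoter > genic > intergenic, so a position
#' that is both upstream of one gene and inside another is called promoter.
#'
#' @param snps data.frame with `chrom` and `pos` (1-based).
#' @param genes gene model table as from [read_gene_models()]; `NULL` or
#'   empty classifies everything intergenic.
#' @param promoter_up promoter extent upstream of the TSS (default 2000).
#' @return character vector, one of `"promoter"`, `"genic"`, `"intergenic"`
#'   per SNP.
#' @export
classify_region <- function(snps, genes, promoter_up = 2000L) {
  n <- nrow(snps)
  region <- rep("intergenic", n)
  if (is.null(genes) || nrow(genes) == 0L) return(region)
  stopifnot(all(genes$tx_start < genes$tx_end), all(genes$strand %in% c("+", "-")))
  snp_gr <- GenomicRanges::GRanges(snps$chrom,
                                   IRanges::IRanges(snps$pos, width = 1L))
  gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$tx_start + 1L, genes$tx_end))
  # strand-aware upstream window, 0-based [TSS - up, TSS) -> 1-based
  plus <- genes$strand == "+"
  prom_start <- ifelse(plus, genes$tx_start - promoter_up + 1L, genes$tx_end + 1L)
  prom_end <- ifelse(plus, genes$tx_start, genes$tx_end + promoter_up)
  prom_start <- pmax(prom_start, 1L)
  ok <- prom_start <= prom_end
  prom_gr <- GenomicRanges::GRanges(genes$chrom[ok],
                                    IRanges::IRanges(prom_start[ok], prom_end[ok]))
  in_gene <- IRanges::overlapsAny(snp_gr, gene_gr)
  in_prom <- IRanges::overlapsAny(snp_gr, prom_gr)
  region[in_gene] <- "genic"
  region[in_prom] <- "promoter"
  region
}

#' Read a genome FASTA
#'
#' @param path FASTA file (single or multi-record).
#' @return a `DNAStringSet`, names truncated at the first whitespace.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}
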