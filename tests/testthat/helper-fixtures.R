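# fixtures are built in code at test time; nothing binary is stored

# minimal phased VCF writer for hand-built records
write_mini_vcf <- function(records, path = tempfile(fileext = ".vcf")) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "S1", sep = "\t"))
  body <- with(records, paste(chrom, pos, ".", ref, alt, ".", "PASS", ".",
                              "GT", gt, sep = "\t"))
  writeLines(c(hdr, body), path)
  path
}

# hand-built pairs table from raw window sequences (coordinates synthetic)
make_pairs <- function(seq_inaccessible, seq_accessible, kind = "DCSR",
                       region = "intergenic", chrom = "chr1") {
  n <- length(seq_accessible)
  w <- nchar(seq_accessible[1])
  pos <- seq(1000L, by = 1000L, length.out = n)
  data.frame(
    chrom = chrom, pos = pos,
    start = pos - (w %/% 2L) - 1L, end = pos + (w %/% 2L),
    allele_paternal = "A", allele_maternal = "C",
    accessible_allele = "paternal",
    depth_high = 30L, depth_low = 5L, fold_change = 6,
    region = region, kind = kind,
    seq_accessible = seq_accessible, seq_inaccessible = seq_inaccessible,
    flagged_nearby_variant = FALSE
  )
}

# tiny sorted+indexed BAM built from in-code SAM text; returns bam path
make_mini_bam <- function(sam_lines, dir = tempfile("bam")) {
  dir.create(dir, showWarnings = FALSE)
  sam <- file.path(dir, "reads.sam")
  writeLines(sam_lines, sam)
  bam0 <- Rsamtools::asBam(sam, file.path(dir, "reads_unsorted"),
                           overwrite = TRUE, indexDestination = FALSE)
  bam <- Rsamtools::sortBam(bam0, file.path(dir, "reads"))
  Rsamtools::indexBam(bam)
  bam
}

# brute-force all-offsets oracle for sliding-window k-mer counting
oracle_count <- function(kmer, window) {
  kmer <- toupper(kmer); window <- toupper(window)
  k <- nchar(kmer); L <- nchar(window)
  if (k > L || grepl("[^ACGT]", kmer)) return(0L)
  sum(vapply(seq_len(L - k + 1L),
             function(i) substr(window, i, i + k - 1L) == kmer, logical(1)))
}

# random DNA string helper
rand_dna <- function(n, len, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i)
    paste(sample(alphabet, len, replace = TRUE), collapse = ""), character(1))
}
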