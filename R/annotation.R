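#' Load a TFBS sequence collection
#'
#' Accepts FASTA (headers `TFNAME|source`, source optional) or a 2-3 column
#' TSV (`tf_name`, `site_seq`, optional `source`). Sites longer than
#' `max_len` bases are discarded at load time (long sites may concatenate
#' several binding sites); sites shorter than 4 bases are dropped with a
#' warning; duplicate (tf, sequence) rows are deduplicated.
#'
#' @param path FASTA or TSV file.
#' @param max_len maximum retained site length (default 30).
#' @return data.frame with `tf_name`, `site_seq`, `source`.
#' @export
load_tfbs <- function(path, max_len = 30L) {
  if (!file.exists(path)) stop("TFBS database not found: ", path)
  if (grepl("\\.(fa|fasta|fna)(\\.gz)?$", path, ignore.case = TRUE)) {
    ss <- Biostrings::readDNAStringSet(path)
    nm <- names(ss)
    tf <- sub("\\|.*$", "", nm)
    src <- ifelse(grepl("|", nm, fixed = TRUE), sub("^[^|]*\\|", "", nm), "custom")
    db <- data.frame(tf_name = tf, site_seq = toupper(as.character(ss)),
                     source = src, row.names = NULL)
  } else {
    db <- utils::read.table(path, header = TRUE, sep = "\t",
                            comment.char = "#", stringsAsFactors = FALSE)
    if (!all(c("tf_name", "site_seq") %in% names(db)))
      stop("TFBS TSV must have columns tf_name, site_seq")
    if (nrow(db) == 0L) stop("TFBS database is empty: ", path)
    if (is.null(db$source)) db$source <- "custom"
    db$site_seq <- toupper(db$site_seq)
    db <- db[, c("tf_name", "site_seq", "source")]
  }
  if (nrow(db) == 0L) stop("TFBS database is empty: ", path)
  long <- nchar(db$site_seq) > max_len
  if (any(long))
    message("load_tfbs: dropped ", sum(long), " site(s) longer than ",
            max_len, " bases")
  db <- db[!long, , drop = FALSE]
  short <- nchar(db$site_seq) < 4L
  if (any(short)) {
    warning("load_tfbs: dropped ", sum(short), " site(s) shorter than 4 bases")
    db <- db[!short, , drop = FALSE]
  }
  db <- db[!duplicated(db[, c("tf_name", "site_seq")]), , drop = FALSE]
  if (nrow(db) == 0L) stop("TFBS database has no usable sites after filtering")
  rownames(db) <- NULL
  db
}

# ungapped Karlin-Altschul parameters for match +1 / mismatch -2 at equal
# base frequencies: lambda solves 0.25 e^l + 0.75 e^(-2l) = 1
.KA_LAMBDA <- 1.332719
.KA_K <- 0.621

#' Align a motif to one TFBS sequence
#'
#' Best local alignment of the k-mer (either strand) against the site,
#' scored with match +1 / mismatch -2 (gap open 5, extend 2). Homology is
#' the number of aligned identities divided by the k-mer length, so an
#' 80% rule on a 6-mer demands at least 5 identities. The E-value is the
#' ungapped Karlin-Altschul estimate `K * m * n * exp(-lambda * S)` for the
#' alignment score S; with queries of 6-10 bases it is a permissive gate
#' and homology is the operative filter.
#'
#' @param kmer DNA word (query).
#' @param site_seq a TFBS sequence, or a one-row data.frame with `site_seq`.
#' @param evalue_max no-hit threshold (default 10).
#' @return list with `e_value`, `homology`, `strand` (`"+"`/`"-"`), or
#'   `NULL` when the E-value exceeds `evalue_max`.
#' @export
align_motif <- function(kmer, site_seq, evalue_max = 10) {
  if (is.data.frame(site_seq)) site_seq <- site_seq$site_seq[1L]
  kmer <- toupper(kmer)
  site_seq <- toupper(site_seq)
  stopifnot(!grepl("[^ACGT]", kmer), !grepl("[^ACGTN]", site_seq))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  best <- NULL
  for (strand in c("+", "-")) {
    q <- if (strand == "+") kmer else reverse_complement(kmer)
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(q),
      subject = Biostrings::DNAString(gsub("N", "A", site_seq)),
      type = "local", substitutionMatrix = mat,
      gapOpening = 5, gapExtension = 2
    )
    cand <- list(score = Biostrings::score(aln),
                 nmatch = Biostrings::nmatch(aln), strand = strand)
    if (is.null(best) || cand$score > best$score) best <- cand
  }
  e_value <- .KA_K * nchar(kmer) * nchar(site_seq) *
    exp(-.KA_LAMBDA * max(best$score, 0))
  if (e_value > evalue_max) return(NULL)
  list(e_value = e_value, homology = best$nmatch / nchar(kmer),
       strand = best$strand)
}

#' Annotate motifs with candidate transcription factors
#'
#' For every k-mer in `results` and every TF in the database, keeps the
#' best-E-value alignment over that TF's sites and retains it when the
#' E-value is at most `evalue_max` and homology strictly exceeds
#' `homology_min`. When an expression table is supplied, TFs with FPKM
#' below `fpkm_min` are marked unexpressed and not retained; without one
#' the expression filter is skipped with a warning. The fraction of k-mers
#' with at least one retained annotation is attached as
#' `attr(, "annotated_fraction")` and reported via `message()`.
#'
#' @param results data.frame with a `kmer` column ([discover_motifs()]).
#' @param db TFBS data.frame from [load_tfbs()].
#' @param expression optional data.frame with `tf_name` and `fpkm`.
#' @param fpkm_min expressed-TF threshold (default 1; FPKM < 1 removed).
#' @param evalue_max E-value gate (default 10).
#' @param homology_min identity-fraction threshold (strict; default 0.8).
#' @return data.frame with `kmer`, `tf_name`, `source`, `e_value`,
#'   `homology`, `fpkm`, `expressed`, `retained` (one row per scored
#'   kmer-TF combination with E-value within the gate).
#' @export
annotate_motifs <- function(results, db, expression = NULL, fpkm_min = 1,
                            evalue_max = 10, homology_min = 0.8) {
  kmers <- unique(results$kmer)
  if (length(kmers) == 0L) return(.empty_annotations())
  if (is.null(expression)) {
    warning("no expression table supplied; skipping the expressed-TF filter")
  }
  fpkm_of <- function(tf) {
    if (is.null(expression)) return(NA_real_)
    i <- match(tf, expression$tf_name)
    if (is.na(i)) NA_real_ else expression$fpkm[i]
  }
  rows <- list()
  for (km in kmers) {
    for (grp in split(db, paste(db$tf_name, db$source, sep = "\r"))) {
      best <- NULL
      for (j in seq_len(nrow(grp))) {
        a <- align_motif(km, grp$site_seq[j], evalue_max = evalue_max)
        if (!is.null(a) && (is.null(best) || a$e_value < best$e_value)) best <- a
      }
      if (is.null(best)) next
      fp <- fpkm_of(grp$tf_name[1L])
      expressed <- if (is.null(expression)) NA else (!is.na(fp) && fp >= fpkm_min)
      rows[[length(rows) + 1L]] <- data.frame(
        kmer = km, tf_name = grp$tf_name[1L], source = grp$source[1L],
        e_value = best$e_value, homology = best$homology, fpkm = fp,
        expressed = expressed,
        retained = best$homology > homology_min &
          (is.null(expression) || isTRUE(expressed))
      )
    }
  }
  ann <- if (length(rows)) do.call(rbind, rows) else .empty_annotations()
  annotated <- unique(ann$kmer[ann$retained])
  frac <- length(annotated) / length(kmers)
  message("annotate_motifs: ", length(annotated), " of ", length(kmers),
          " motifs annotated (", sprintf("%.1f%%", 100 * frac), ")")
  attr(ann, "annotated_fraction") <- frac
  ann
}

.empty_annotations <- function() {
  data.frame(kmer = character(), tf_name = character(), source = character(),
             e_value = numeric(), homology = numeric(), fpkm = numeric(),
             expressed = logical(), retained = logical())
}

#' Load a TF expression table
#'
#' @param path TSV with columns `tf_name` and `fpkm`.
#' @return data.frame.
#' @export
load_expression <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("tf_name", "fpkm") %in% names(d)))
    stop("expression table must have columns tf_name, fpkm")
  d
}

#' Chromatin-annotation enrichment between two motif lists
#'
#' Tags each motif in the two annotated lists by whether any of its retained
#' TFs belongs to a chromatin-specific set (e.g. TFs under GO chromatin
#' remodeling / histone modification / chromatin DNA binding, supplied as a
#' flat name list), builds the 2x2 contingency table (chromatin-specific
#' vs not, list A vs list B) and runs the Pearson chi-squared test.
#'
#' @param top_a,top_b annotation data.frames ([annotate_motifs()]); only
#'   rows with `retained == TRUE` count as annotations, but every distinct
#'   `kmer` in the table counts as a motif.
#' @param chromatin_tf_set character vector of chromatin-associated TF names.
#' @return list with `table` (2x2 matrix), `chi2` and `p_value`.
#' @export
chromatin_go_enrichment <- function(top_a, top_b, chromatin_tf_set) {
  tally <- function(ann) {
    kmers <- unique(ann$kmer)
    if (length(kmers) == 0L) stop("empty motif list")
    hit <- vapply(kmers, function(km)
      any(ann$tf_name[ann$kmer == km & ann$retained] %in% chromatin_tf_set),
      logical(1))
    c(sum(hit), sum(!hit))
  }
  tab <- rbind(A = tally(top_a), B = tally(top_b))
  colnames(tab) <- c("chromatin_specific", "other")
  res <- chi2_test(tab)
  list(table = tab, chi2 = res$statistic, p_value = res$p_value)
}
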