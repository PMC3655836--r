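#' Pearson chi-squared test on a 2x2 table
#'
#' The plain Pearson statistic sum((O - E)^2 / E) with expected counts from
#' the row/column margins and the upper-tail p-value on 1 degree of
#' freedom. No Yates continuity correction is applied: on the MYC
#' allele-specific binding table (31, 36; 21, 61) the uncorrected p is
#' 0.0085 while the corrected one would be 0.015.
#'
#' @param table a 2x2 matrix of non-negative counts, or a length-4 vector
#'   `(a, b, c, d)` filled by row.
#' @return list with `statistic`, `p_value`, `expected` and `table`.
#' @examples
#' chi2_test(matrix(c(31, 36, 21, 61), 2, byrow = TRUE))$p_value  # 0.00849
#' @export
chi2_test <- function(table) {
  if (!is.matrix(table)) {
    stopifnot(length(table) == 4L)
    table <- matrix(table, nrow = 2L, byrow = TRUE)
  }
  stopifnot(all(dim(table) == c(2L, 2L)))
  if (any(table < 0) || any(!is.finite(table)))
    stop("counts must be finite and non-negative")
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0))
    stop("degenerate table: row ", which(rs == 0)[1L], " has zero margin")
  if (any(cs == 0))
    stop("degenerate table: column ", which(cs == 0)[1L], " has zero margin")
  ht <- stats::chisq.test(table, correct = FALSE)
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       expected = ht$expected, table = table)
}

#' Read peak calls from BED
#'
#' BED intervals whose name field marks allele specificity: names `AS`,
#' `allele_specific` or `allele-specific` (case-insensitive) are
#' allele-specific peaks, everything else is not.
#'
#' @param path BED file (>= 4 columns).
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `allele_specific`.
#' @export
read_peaks <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- if (is.null(gr$name)) rep("", length(gr)) else as.character(gr$name)
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    allele_specific = tolower(nm) %in% c("as", "allele_specific", "allele-specific"),
    row.names = NULL
  )
}

#' Associate DCSR/NDCSR windows with allele-specific peaks
#'
#' Each 41-base window overlapping at least one peak (>= 1 shared base) is
#' classified by the overlapping peak's allele-specificity flag, with
#' allele-specific taking precedence when both kinds overlap; windows
#' touching no peak are excluded. Returns the 2x2 table of kind
#' (DCSR/NDCSR) against peak class, ready for [chi2_test()].
#'
#' @param pairs data.frame of called pairs including both kinds
#'   ([call_pairs()] output, possibly row-bound).
#' @param peaks data.frame from [read_peaks()] (same genome coordinates).
#' @return 2x2 integer matrix with rows `DCSR`, `NDCSR` and columns
#'   `allele_specific`, `non_allele_specific`.
#' @export
peak_association <- function(pairs, peaks) {
  tab <- matrix(0L, 2L, 2L,
                dimnames = list(c("DCSR", "NDCSR"),
                                c("allele_specific", "non_allele_specific")))
  if (nrow(pairs) == 0L || nrow(peaks) == 0L) return(tab)
  win_gr <- GenomicRanges::GRanges(pairs$chrom,
                                   IRanges::IRanges(pairs$start + 1L, pairs$end))
  peak_gr <- GenomicRanges::GRanges(peaks$chrom,
                                    IRanges::IRanges(peaks$start + 1L, peaks$end))
  ov <- GenomicRanges::findOverlaps(win_gr, peak_gr)
  if (length(ov) == 0L) return(tab)
  qh <- S4Vectors::queryHits(ov)
  as_flag <- peaks$allele_specific[S4Vectors::subjectHits(ov)]
  # allele-specific precedence when a window touches both peak kinds
  any_as <- tapply(as_flag, qh, any)
  idx <- as.integer(names(any_as))
  for (i in seq_along(idx)) {
    row <- if (pairs$kind[idx[i]] == "DCSR") 1L else 2L
    col <- if (any_as[i]) 1L else 2L
    tab[row, col] <- tab[row, col] + 1L
  }
  tab
}
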