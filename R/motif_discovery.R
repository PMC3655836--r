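#' Enumerate all DNA k-mers in a length range
#'
#' All 4^k words over A/C/G/T for each k in `[kmin, kmax]`, each block in
#' lexicographic order. The full default range 6-10 has
#' sum(4^(6:10)) = 1,396,736 candidates.
#'
#' @param kmin,kmax inclusive length bounds, `1 <= kmin <= kmax`.
#' @return character vector of k-mers.
#' @export
enumerate_kmers <- function(kmin, kmax) {
  if (kmin > kmax) stop("kmin must not exceed kmax")
  stopifnot(kmin >= 1L)
  bases <- c("A", "C", "G", "T")
  unlist(lapply(kmin:kmax, function(k) {
    g <- expand.grid(rep(list(bases), k), stringsAsFactors = FALSE)
    # expand.grid varies the first column fastest; reverse the columns so
    # the last sequence position varies fastest -> lexicographic order
    do.call(paste0, g[, seq(k, 1L), drop = FALSE])
  }), use.names = FALSE)
}

#' Count sliding-window occurrences of a k-mer
#'
#' Exact, case-insensitive matching at every start offset; overlapping
#' matches all count. `N` (in the window or the k-mer) never matches. A
#' k-mer longer than the window yields 0.
#'
#' @param kmer a single DNA word.
#' @param window_seq character vector of window sequences.
#' @return integer vector of per-window hit counts.
#' @examples
#' count_occurrences("CTC", "CTCTC")  # 2 (offsets 1 and 3)
#' @export
count_occurrences <- function(kmer, window_seq) {
  kmer <- toupper(kmer)
  if (grepl("[^ACGT]", kmer)) return(integer(length(window_seq)))
  window_seq <- toupper(window_seq)
  # lookahead so overlapping occurrences are all found
  hits <- gregexpr(paste0("(?=", kmer, ")"), window_seq, perl = TRUE)
  vapply(hits, function(h) if (h[1L] == -1L) 0L else length(h), integer(1))
}

#' Per-pair occurrence count vectors for one k-mer
#'
#' Convenience accessor giving the two frequency vectors the paired t-test
#' compares, in pair order.
#'
#' @param pairs data.frame from [call_pairs()].
#' @param kmer a single DNA word.
#' @return list with integer vectors `inaccessible` and `accessible`.
#' @export
kmer_counts <- function(pairs, kmer) {
  list(inaccessible = count_occurrences(kmer, pairs$seq_inaccessible),
       accessible = count_occurrences(kmer, pairs$seq_accessible))
}

#' Paired t-test on two frequency vectors
#'
#' Computes differences `d = x - y`, `t = mean(d) / (sd(d) / sqrt(n))` with
#' the sample (n-1) standard deviation, and the two-sided p-value from
#' Student's t with n-1 degrees of freedom. Degenerate cases follow fixed
#' conventions: `sd(d) == 0` with `mean(d) == 0` returns `(0, 1)`;
#' `sd(d) == 0` with `mean(d) != 0` returns (signed infinity, 0).
#'
#' @param x,y equal-length numeric vectors, `n >= 2` (here: per-pair counts
#'   in the inaccessible and accessible groups).
#' @return list with `t_stat` and `p_value`.
#' @examples
#' paired_t_test(c(2, 2, 0), c(1, 0, 0))  # t = sqrt(3), p ~ 0.2254
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 2L) stop("paired t-test needs n >= 2")
  d <- as.numeric(x) - as.numeric(y)
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    if (m == 0) return(list(t_stat = 0, p_value = 1))
    return(list(t_stat = sign(m) * Inf, p_value = 0))
  }
  t_stat <- m / (s / sqrt(n))
  list(t_stat = t_stat, p_value = 2 * stats::pt(-abs(t_stat), df = n - 1L))
}

#' Occurrence rate of a k-mer across windows
#'
#' Fraction of windows with at least one hit.
#'
#' @param counts integer vector of per-window hit counts (non-empty).
#' @return fraction in `[0, 1]`.
#' @export
occurrence_rate <- function(counts) {
  if (length(counts) == 0L) stop("occurrence_rate: empty count vector")
  mean(counts >= 1L)
}

#' Discover chromatin motifs by exhaustive k-mer testing
#'
#' For every k-mer of length `kmin..kmax`, counts sliding-window occurrences
#' in the inaccessible and the accessible window of each pair, runs the
#' paired t-test between the two frequency vectors (positive t = enriched in
#' the inaccessible group), and computes the occurrence rate (fraction of
#' windows with >= 1 hit) in each group. With `filter = TRUE` (the default)
#' only k-mers passing both published selection rules are returned:
#' two-sided p strictly below `p_max` and occurrence rate strictly above
#' `rate_min` in at least one group. Results are sorted by ascending
#' p-value, ties broken lexicographically by k-mer.
#'
#' Pairs whose windows contain `N` are excluded before counting (with a
#' message). Counting is forward-strand on the stored windows; the reverse
#' complement is reported as the `antisense` column, never merged into the
#' counts, so palindromes are not double-counted. K-mers that never occur in
#' any window have t = 0, p = 1 and rate 0 and are omitted from the output.
#' A Benjamini-Hochberg column (`p_adjust`, computed against the full
#' enumeration size) is included for information only; selection uses the
#' raw p-values.
#'
#' @param pairs data.frame from [call_pairs()] (>= 2 pairs).
#' @param kmin,kmax k-mer length range (defaults 6 and 10).
#' @param p_max p-value threshold (strict; default 0.01).
#' @param rate_min occurrence-rate threshold (strict; default 0.01).
#' @param filter apply the two selection rules (`FALSE` returns every
#'   observed k-mer, mirroring an unfiltered results stream).
#' @return data.frame with `kmer`, `antisense`, `t_stat`, `p_value`,
#'   `p_adjust`, `rate_inaccessible`, `rate_accessible`, `n_pairs`.
#' @export
discover_motifs <- function(pairs, kmin = 6L, kmax = 10L,
                            p_max = 0.01, rate_min = 0.01, filter = TRUE) {
  if (kmin > kmax) stop("kmin must not exceed kmax")
  hasN <- grepl("N", pairs$seq_accessible, fixed = TRUE) |
    grepl("N", pairs$seq_inaccessible, fixed = TRUE)
  if (any(hasN)) {
    message("discover_motifs: excluding ", sum(hasN), " pair(s) containing N")
    pairs <- pairs[!hasN, , drop = FALSE]
  }
  n <- nrow(pairs)
  if (n < 2L) stop("motif discovery needs at least 2 pairs")
  acc <- toupper(pairs$seq_accessible)
  inacc <- toupper(pairs$seq_inaccessible)
  res <- rbindlist(lapply(kmin:kmax, function(k)
    .kmer_stats_one_k(inacc, acc, k, n)))
  if (nrow(res) == 0L) return(.empty_motifs())
  n_enumerated <- sum(4^(kmin:kmax))
  res[, p_adjust := stats::p.adjust(p_value, method = "BH", n = n_enumerated)]
  res[, antisense := reverse_complement(kmer)]
  if (filter) {
    res <- res[p_value < p_max &
                 pmax(rate_inaccessible, rate_accessible) > rate_min]
  }
  setorder(res, p_value, kmer)
  out <- as.data.frame(res[, .(kmer, antisense, t_stat, p_value, p_adjust,
                               rate_inaccessible, rate_accessible)])
  out$n_pairs <- rep.int(n, nrow(out))
  out
}

.empty_motifs <- function() {
  data.frame(kmer = character(), antisense = character(), t_stat = numeric(),
             p_value = numeric(), p_adjust = numeric(),
             rate_inaccessible = numeric(), rate_accessible = numeric(),
             n_pairs = integer())
}

# One pass over all windows for a single k: tabulate every k-length
# substring of every window (a 41-base window contributes 41-k+1
# instances), then aggregate the paired statistics per k-mer from the
# sparse (kmer, pair) count table. Equivalent to running
# count_occurrences() + paired_t_test() per k-mer.
.kmer_stats_one_k <- function(inacc, acc, k, n) {
  tab <- function(seqs) {
    lens <- nchar(seqs)
    noff <- pmax(lens - k + 1L, 0L)
    maxoff <- max(noff)
    if (maxoff == 0L) return(data.table(kmer = character(), id = integer()))
    dt <- rbindlist(lapply(seq_len(maxoff), function(i) {
      use <- which(noff >= i)
      data.table(kmer = substring(seqs[use], i, i + k - 1L), id = use)
    }))
    dt[!grepl("[^ACGT]", kmer)]
  }
  ci <- tab(inacc)[, .(cnt_inacc = .N), by = .(kmer, id)]
  ca <- tab(acc)[, .(cnt_acc = .N), by = .(kmer, id)]
  mg <- merge(ci, ca, by = c("kmer", "id"), all = TRUE)
  if (nrow(mg) == 0L) return(NULL)
  mg[is.na(cnt_inacc), cnt_inacc := 0L]
  mg[is.na(cnt_acc), cnt_acc := 0L]
  mg[, d := cnt_inacc - cnt_acc]
  st <- mg[, .(
    sum_d = sum(d), sum_d2 = sum(as.numeric(d)^2),
    n_inacc = sum(cnt_inacc >= 1L), n_acc = sum(cnt_acc >= 1L)
  ), by = kmer]
  m <- st$sum_d / n
  ss <- pmax(st$sum_d2 - n * m^2, 0)       # implicit zeros for absent pairs
  v <- ss / (n - 1L)
  t_stat <- ifelse(v > 0, m / sqrt(v / n),
                   ifelse(m == 0, 0, sign(m) * Inf))
  p <- ifelse(is.finite(t_stat), 2 * stats::pt(-abs(t_stat), df = n - 1L),
              0)
  p[t_stat == 0 & v == 0] <- 1
  data.table(kmer = st$kmer, t_stat = t_stat, p_value = p,
             rate_inaccessible = st$n_inacc / n,
             rate_accessible = st$n_acc / n)
}

#' Write a motif results table
#'
#' @param results data.frame from [discover_motifs()].
#' @param path output TSV path.
#' @param region_scope label recorded in a `region_scope` column
#'   (genome_wide, intergenic, genic or promoter).
#' @return `path`, invisibly.
#' @export
write_motifs <- function(results, path, region_scope = "genome_wide") {
  results$region_scope <- region_scope
  utils::write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
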