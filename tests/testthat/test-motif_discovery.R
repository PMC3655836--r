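test_that("enumerate_kmers yields complete lexicographic blocks", {
  expect_equal(enumerate_kmers(1, 1), c("A", "C", "G", "T"))
  two <- enumerate_kmers(2, 2)
  expect_length(two, 16L)
  expect_equal(two[1], "AA")
  expect_equal(two[16], "TT")
  expect_equal(two, sort(two))
  expect_false(anyDuplicated(two) > 0)
  expect_error(enumerate_kmers(3, 2), "kmin")
})

test_that("count_occurrences counts overlapping hits exactly", {
  expect_equal(count_occurrences("CTC", "CTCTC"), 2L)
  expect_equal(count_occurrences("AAA", "CCCCCCC"), 0L)
  expect_equal(count_occurrences("AAAA", "AAA"), 0L)  # kmer longer than window
  expect_equal(count_occurrences("acgt", "TACGTA"), 1L)  # case-insensitive
  expect_equal(count_occurrences("ANA", "AAAAA"), 0L)    # N never matches
  expect_equal(count_occurrences("AAA", "AANAA"), 0L)
})

test_that("scanning counts equal the brute-force all-offsets oracle", {
  set.seed(13)
  for (i in 1:200) {
    k <- sample(1:10, 1)
    w <- rand_dna(1, sample(10:41, 1))
    km <- rand_dna(1, k)
    expect_identical(count_occurrences(km, w), oracle_count(km, w))
  }
})

test_that("paired_t_test matches closed form and stats::t.test", {
  r <- paired_t_test(c(2, 2, 0), c(1, 0, 0))
  expect_equal(r$t_stat, sqrt(3), tolerance = 1e-12)
  expect_equal(r$p_value, 0.2254033, tolerance = 1e-6)
  # identity and degenerate conventions
  expect_equal(paired_t_test(c(3, 1, 4), c(3, 1, 4)), list(t_stat = 0, p_value = 1))
  expect_equal(paired_t_test(c(2, 3, 4), c(1, 2, 3)),
               list(t_stat = Inf, p_value = 0))
  expect_equal(paired_t_test(c(1, 2, 3), c(2, 3, 4))$t_stat, -Inf)
  # swap symmetry
  set.seed(3)
  x <- rpois(20, 2); y <- rpois(20, 2)
  a <- paired_t_test(x, y); b <- paired_t_test(y, x)
  expect_equal(a$t_stat, -b$t_stat)
  expect_equal(a$p_value, b$p_value)
  # independent oracle on non-degenerate draws
  for (i in 1:20) {
    x <- rpois(sample(3:30, 1), 3); y <- rpois(length(x), 3)
    if (sd(x - y) == 0) next
    ht <- t.test(x, y, paired = TRUE)
    r <- paired_t_test(x, y)
    expect_equal(r$t_stat, unname(ht$statistic), tolerance = 1e-12)
    expect_equal(r$p_value, ht$p.value, tolerance = 1e-12)
  }
  expect_error(paired_t_test(1, 1), "n >= 2")
  expect_error(paired_t_test(1:3, 1:4), "equal length")
})

test_that("occurrence_rate is the fraction of windows with a hit", {
  expect_equal(occurrence_rate(c(2, 2, 0)), 2 / 3)
  expect_equal(occurrence_rate(c(0, 0, 0, 0)), 0)
  expect_equal(occurrence_rate(c(1, 5, 2)), 1)
  expect_error(occurrence_rate(integer(0)), "empty")
})

test_that("a planted allele-completing motif is discovered with full separation", {
  acc <- paste0(strrep("A", 18), "CACGTG", strrep("A", 17))
  inacc <- acc
  substr(inacc, 21, 21) <- "T"  # the focal base breaks the motif
  pairs <- make_pairs(rep(inacc, 3), rep(acc, 3))
  res <- discover_motifs(pairs, kmin = 6, kmax = 6)
  hit <- res[res$kmer == "CACGTG", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$rate_accessible, 1)
  expect_equal(hit$rate_inaccessible, 0)
  # constant nonzero difference with n = 3: degenerate-variance convention
  expect_equal(hit$t_stat, -Inf)
  expect_equal(hit$p_value, 0)
  expect_equal(hit$antisense, "CACGTG")  # palindrome equals its antisense
})

test_that("the rate filter excludes rare k-mers regardless of p", {
  # one hit in 1 of 300 windows: rate 1/300 < 1%
  acc <- c(paste0("CACGTG", strrep("A", 35)), rand_dna(299, 41, c("G", "T")))
  inacc <- rand_dna(300, 41, c("G", "T"))
  pairs <- make_pairs(inacc, acc)
  res <- discover_motifs(pairs, kmin = 6, kmax = 6)
  expect_false("CACGTG" %in% res$kmer)
  unfiltered <- discover_motifs(pairs, kmin = 6, kmax = 6, filter = FALSE)
  expect_true("CACGTG" %in% unfiltered$kmer)
})

test_that("vectorised discovery equals per-kmer counting plus paired t-test", {
  set.seed(17)
  pairs <- make_pairs(rand_dna(20, 41), rand_dna(20, 41))
  res <- discover_motifs(pairs, kmin = 3, kmax = 4, filter = FALSE)
  expect_gt(nrow(res), 0L)
  pick <- res[sample(nrow(res), 40), ]
  for (i in seq_len(nrow(pick))) {
    km <- pick$kmer[i]
    cnts <- kmer_counts(pairs, km)
    ref <- paired_t_test(cnts$inaccessible, cnts$accessible)
    expect_equal(pick$t_stat[i], ref$t_stat, tolerance = 1e-9)
    expect_equal(pick$p_value[i], ref$p_value, tolerance = 1e-9)
    expect_equal(pick$rate_inaccessible[i], occurrence_rate(cnts$inaccessible))
    expect_equal(pick$rate_accessible[i], occurrence_rate(cnts$accessible))
  }
  # a k-mer absent from the output never occurs in any window
  absent <- setdiff(enumerate_kmers(3, 3), res$kmer[nchar(res$kmer) == 3])
  if (length(absent)) {
    cnts <- kmer_counts(pairs, absent[1])
    expect_equal(sum(cnts$inaccessible) + sum(cnts$accessible), 0L)
  }
})

test_that("swapping group labels negates t and preserves the selected set", {
  set.seed(19)
  acc <- paste0(strrep("C", 18), "CACGTG", strrep("C", 17))
  inacc <- acc; substr(inacc, 21, 21) <- "T"
  pairs <- make_pairs(c(rep(inacc, 8), rand_dna(42, 41)),
                      c(rep(acc, 8), rand_dna(42, 41)))
  swapped <- pairs
  swapped$seq_accessible <- pairs$seq_inaccessible
  swapped$seq_inaccessible <- pairs$seq_accessible
  a <- discover_motifs(pairs, kmin = 6, kmax = 6, filter = FALSE)
  b <- discover_motifs(swapped, kmin = 6, kmax = 6, filter = FALSE)
  b <- b[match(a$kmer, b$kmer), ]
  expect_equal(a$t_stat, -b$t_stat)
  expect_equal(a$p_value, b$p_value)
  sel_a <- discover_motifs(pairs, kmin = 6, kmax = 6)$kmer
  sel_b <- discover_motifs(swapped, kmin = 6, kmax = 6)$kmer
  expect_setequal(sel_a, sel_b)
})

test_that("results are ordered by p-value with lexicographic ties", {
  set.seed(23)
  pairs <- make_pairs(rand_dna(10, 41), rand_dna(10, 41))
  res <- discover_motifs(pairs, kmin = 3, kmax = 3, filter = FALSE)
  expect_true(!is.unsorted(res$p_value))
  ties <- split(res$kmer, res$p_value)
  for (grp in ties) expect_equal(grp, sort(grp))
})

test_that("windows containing N are excluded before counting", {
  pairs <- make_pairs(c("AAANAAA", "CTCCTCA"), c("AAAAAAA", "CTCAAAA"))
  expect_message(res <- discover_motifs(pairs[c(1, 1, 2, 2), ], kmin = 3,
                                        kmax = 3, filter = FALSE),
                 "excluding 2 pair")
  expect_equal(unique(res$n_pairs), 2L)
  expect_false(any(grepl("N", res$kmer)))
  expect_error(suppressMessages(discover_motifs(pairs[c(1, 1), ], kmin = 3, kmax = 3)),
               "at least 2 pairs")
})
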