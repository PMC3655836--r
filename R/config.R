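#' Default run configuration
#'
#' All tunable thresholds of the workflow in one flat list. The defaults are
#' the published operating point of the method: 41-base windows (`flank` 20),
#' DCSR calls at depth fold change > 2 with greater depth >= 10, NDCSR
#' controls at fold < 1.5 with greater depth >= 5, exhaustive 6-10mers,
#' selection at paired-t p < 0.01 and occurrence rate > 1%, TFBS annotation
#' at homology > 0.8 with E-value <= 10 and sites <= 30 bases, expressed-TF
#' filter at FPKM >= 1, and promoters as the strand-aware 2000 bases
#' upstream of the TSS.
#'
#' @param ... named overrides for any default.
#' @return A named list of class `chromotif_config`.
#' @examples
#' cfg <- default_config(kmax = 6)
#' cfg$dcsr_fold
#' @export
default_config <- function(...) {
  cfg <- list(
    flank         = 20L,   # bases each side of the focal SNP -> 41-base windows
    dcsr_fold     = 2,     # DCSR: depth fold change strictly > 2
    dcsr_depth    = 10L,   # DCSR: greater allele depth >= 10
    ndcsr_fold    = 1.5,   # NDCSR: fold change strictly < 1.5
    ndcsr_depth   = 5L,    # NDCSR: greater allele depth >= 5
    kmin          = 6L,
    kmax          = 10L,
    p_max         = 0.01,  # paired t-test p strictly < 0.01
    rate_min      = 0.01,  # occurrence rate strictly > 1% in either group
    homology_min  = 0.8,   # TFBS annotation identity fraction strictly > 0.8
    evalue_max    = 10,    # alignment E-value gate
    tfbs_max_len  = 30L,   # TFBS sequences longer than this are discarded
    fpkm_min      = 1,     # TFs with FPKM below this are unexpressed
    promoter_up   = 2000L, # promoter = [TSS - 2000, TSS), strand-aware
    haplotype_order = c(1L, 2L),  # phased GT "a|b": which field is paternal
    seed          = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  class(cfg) <- "chromotif_config"
  validate_config(cfg)
  cfg
}

#' Validate a run configuration
#'
#' @param cfg a list as produced by [default_config()].
#' @return `cfg`, invisibly, or an error describing the violated constraint.
#' @export
validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  pos <- c("flank", "dcsr_fold", "dcsr_depth", "ndcsr_fold", "ndcsr_depth",
           "kmin", "kmax", "evalue_max", "tfbs_max_len", "promoter_up")
  for (k in pos) {
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1L || cfg[[k]] <= 0)
      stop("config error: '", k, "' must be a single positive number")
  }
  if (cfg$kmin > cfg$kmax) stop("config error: kmin > kmax")
  for (k in c("p_max", "rate_min", "homology_min")) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0 || cfg[[k]] > 1)
      stop("config error: '", k, "' must be in (0, 1]")
  }
  if (!all(sort(as.integer(cfg$haplotype_order)) == c(1L, 2L)))
    stop("config error: haplotype_order must be a permutation of 1:2")
  invisible(cfg)
}
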