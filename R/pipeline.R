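#' Run a workflow stage
#'
#' Wires the modules into the end-to-end workflow: `simulate` writes a
#' synthetic input set; `call-dcsr` calls DCSR and NDCSR pairs from a depth
#' table; `discover` tests k-mers per region scope; `annotate` aligns the
#' selected motifs to a TFBS collection; `validate` runs the peak
#' association chi-squared test; `all` chains every stage on the simulated
#' inputs. Each run writes its artifacts plus a machine-readable
#' `manifest.json` (package version, configuration echo, input checksums
#' and per-stage counts) under `out_dir`.
#'
#' @param stage one of `"simulate"`, `"call-dcsr"`, `"discover"`,
#'   `"annotate"`, `"validate"`, `"all"`.
#' @param inputs named list of input paths, as required per stage:
#'   `depths`, `genome`, `genes` (optional), `pairs`, `ndcsr_pairs`,
#'   `motifs`, `tfbs`, `expression` (optional), `peaks`.
#' @param out_dir output directory (created if needed).
#' @param config threshold configuration ([default_config()]).
#' @param sim simulation configuration ([sim_config()]), used by
#'   `simulate`/`all`.
#' @return invisibly, a list of stage outputs (also serialized into the
#'   manifest).
#' @export
run_stage <- function(stage = c("all", "simulate", "call-dcsr", "discover",
                                "annotate", "validate"),
                      inputs = list(), out_dir = tempfile("chromotif_run"),
                      config = default_config(), sim = sim_config()) {
  stage <- match.arg(stage)
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  outputs <- list()

  need <- function(key) {
    p <- inputs[[key]]
    if (is.null(p) || !file.exists(p))
      stop("missing input for stage '", stage, "': ", key,
           if (!is.null(p)) paste0(" (", p, ")"))
    p
  }

  if (stage %in% c("simulate", "all")) {
    simdat <- simulate_dataset(sim, dir = file.path(out_dir, "sim"))
    counts$simulated_snps <- nrow(simdat$snps)
    counts$planted_snps <- sum(simdat$truth$planted)
    outputs$sim <- simdat[c("fasta", "vcf", "depths_path", "truth_path")]
    if (stage == "all") {
      inputs$depths <- simdat$depths_path
      inputs$genome <- simdat$fasta
    }
  }

  if (stage %in% c("call-dcsr", "all")) {
    depths <- load_depth_table(need("depths"))
    genome <- read_genome(need("genome"))
    genes <- if (!is.null(inputs$genes)) read_gene_models(inputs$genes) else NULL
    dcsr <- call_pairs(depths, genome, genes, mode = "DCSR", config = config)
    ndcsr <- call_pairs(depths, genome, genes, mode = "NDCSR", config = config)
    write_pairs(dcsr, file.path(out_dir, "dcsr"))
    write_pairs(ndcsr, file.path(out_dir, "ndcsr"))
    by_region <- partition_by_region(dcsr)
    counts$dcsr_pairs <- vapply(by_region, nrow, integer(1))
    counts$ndcsr_pairs <- nrow(ndcsr)
    outputs$pairs <- file.path(out_dir, c("dcsr.pairs.tsv", "ndcsr.pairs.tsv"))
    if (stage == "all") inputs$pairs <- file.path(out_dir, "dcsr.pairs.tsv")
    if (stage == "all") inputs$ndcsr_pairs <- file.path(out_dir, "ndcsr.pairs.tsv")
  }

  if (stage %in% c("discover", "all")) {
    pairs <- read_pairs(need("pairs"))
    scopes <- partition_by_region(pairs)
    motif_counts <- integer(0)
    for (scope in names(scopes)) {
      sub <- scopes[[scope]]
      if (nrow(sub) < 2L) next
      res <- discover_motifs(sub, kmin = config$kmin, kmax = config$kmax,
                             p_max = config$p_max, rate_min = config$rate_min)
      write_motifs(res, file.path(out_dir, paste0("motifs.", scope, ".tsv")),
                   region_scope = scope)
      motif_counts[scope] <- nrow(res)
    }
    counts$motifs <- motif_counts
    outputs$motifs <- file.path(out_dir, "motifs.genome_wide.tsv")
    if (stage == "all") inputs$motifs <- outputs$motifs
  }

  if (stage %in% c("annotate", "all")) {
    motifs <- utils::read.table(need("motifs"), header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
    if (stage == "all" && is.null(inputs$tfbs)) {
      fix <- simulate_tfbs_fixture(dir = file.path(out_dir, "tfbs"))
      inputs$tfbs <- fix$fasta
      inputs$expression <- fix$expression_path
    }
    db <- load_tfbs(need("tfbs"), max_len = config$tfbs_max_len)
    expr <- if (!is.null(inputs$expression)) load_expression(inputs$expression)
    ann <- annotate_motifs(motifs, db, expression = expr,
                           fpkm_min = config$fpkm_min,
                           evalue_max = config$evalue_max,
                           homology_min = config$homology_min)
    utils::write.table(ann, file.path(out_dir, "annotations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    counts$annotated_fraction <- attr(ann, "annotated_fraction")
    outputs$annotations <- file.path(out_dir, "annotations.tsv")
  }

  if (stage %in% c("validate", "all")) {
    pairs <- read_pairs(need("pairs"))
    ndcsr <- read_pairs(need("ndcsr_pairs"))
    both <- rbind(pairs, ndcsr)
    if (stage == "all" && is.null(inputs$peaks)) {
      peaks <- simulate_peak_calls(both,
                                   bed_path = file.path(out_dir, "peaks.bed"))
    } else {
      peaks <- read_peaks(need("peaks"))
    }
    tab <- peak_association(both, peaks)
    counts$peak_table <- tab
    res <- tryCatch(chi2_test(tab), error = function(e) NULL)
    counts$peak_chi2_p <- if (is.null(res)) NA_real_ else res$p_value
    utils::write.table(as.data.frame(tab),
                       file.path(out_dir, "peak_association.tsv"),
                       sep = "\t", quote = FALSE)
    outputs$validation <- file.path(out_dir, "peak_association.tsv")
  }

  manifest <- list(
    package = "chromotif",
    version = as.character(utils::packageVersion("chromotif")),
    stage = stage,
    config = unclass(config),
    sim = if (stage %in% c("simulate", "all")) unclass(sim),
    inputs = lapply(Filter(is.character, inputs), function(p)
      if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_),
    counts = counts,
    outputs = outputs
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(list(counts = counts, outputs = outputs,
                 manifest = file.path(out_dir, "manifest.json")))
}
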