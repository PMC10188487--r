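#' Generate a genome fixture for the peak-to-gene enrichment test
#'
#' Lays `n_genes` genes on a regular grid along one chromosome, places one
#' chromatin peak just upstream of each gene of a random "target" subset (so
#' the closest-gene assignment is unambiguous), and draws differential
#' expression labels such that the probability that a DEG is peak-associated
#' equals `enrichment_factor` times the background target fraction (capped
#' at 1). The construction gives an exact expected overlap, making it the
#' calibration fixture for the two-proportion Z enrichment test.
#'
#' @param n_genes number of genes in the expressed universe.
#' @param n_peaks number of peaks, i.e. size of the target gene subset.
#' @param enrichment_factor fold enrichment of targets among DEGs (1 = null).
#' @param n_deg number of differentially expressed genes.
#' @param seed integer seed.
#' @return list with `peaks` (a `GRanges`), `genes` (data.frame with
#'   `gene_id, chrom, start, end, strand`; BED-style 0-based half-open
#'   coordinates), `degs` (data.frame `gene_id, log2fc, padj` covering every
#'   gene), `universe` (character vector), `target_genes` (character),
#'   `background_fraction`, `expected_deg_fraction` (the construction
#'   probability `q`) and `realized_deg_fraction` (the drawn fraction).
#' @export
make_genome_fixture <- function(n_genes = 1000, n_peaks = 100,
                                enrichment_factor = 1, n_deg = 150,
                                seed = NULL) {
  .assert(.is_num(n_genes) && n_genes >= 2, "n_genes must be >= 2")
  .assert(.is_num(n_peaks) && n_peaks >= 1 && n_peaks <= n_genes,
          "n_peaks must be in [1, n_genes]")
  .assert(.is_num(n_deg) && n_deg >= 1 && n_deg <= n_genes,
          "n_deg must be in [1, n_genes]")
  .assert(.is_num(enrichment_factor) && enrichment_factor >= 0,
          "enrichment_factor must be >= 0")
  n_genes <- as.integer(n_genes); n_peaks <- as.integer(n_peaks)
  n_deg <- as.integer(n_deg)

  bg_frac <- n_peaks / n_genes
  q <- enrichment_factor * bg_frac
  .assert(q <= 1, "infeasible enrichment: required DEG-target probability > 1")
  .assert(q * n_deg <= n_peaks,
          "infeasible enrichment: more target DEGs expected than targets exist")

  .with_seed(seed, {
    gene_len <- 2000L
    spacing <- 10000L
    ids <- sprintf("gene%04d", seq_len(n_genes))
    starts <- (seq_len(n_genes) - 1L) * spacing
    genes <- data.frame(
      gene_id = ids, chrom = "chr1",
      start = starts, end = starts + gene_len,
      strand = rep_len(c("+", "-"), n_genes),
      stringsAsFactors = FALSE
    )
    target_idx <- sort(sample.int(n_genes, n_peaks))
    # one peak shortly upstream of each target gene; nearer to it than to any
    # neighbor on the 10-kb grid
    peak_start <- starts[target_idx] - 600L
    peaks <- GenomicRanges::GRanges(
      seqnames = "chr1",
      ranges = IRanges::IRanges(start = peak_start + 1L, end = peak_start + 200L)
    )
    # each DEG is drawn from the target set with probability q (binomial
    # count), so the null (enrichment_factor = 1) retains its sampling
    # variability and the Z test can be calibrated against it
    n_deg_target <- min(stats::rbinom(1, n_deg, q), n_peaks)
    deg_idx <- c(
      sample(target_idx, n_deg_target),
      sample(setdiff(seq_len(n_genes), target_idx), n_deg - n_deg_target)
    )
    is_deg <- seq_len(n_genes) %in% deg_idx
    degs <- data.frame(
      gene_id = ids,
      log2fc = ifelse(is_deg, -stats::runif(n_genes, 1.2, 4), stats::rnorm(n_genes, 0, 0.3)),
      padj = ifelse(is_deg, stats::runif(n_genes, 1e-8, 0.01), stats::runif(n_genes, 0.2, 1)),
      stringsAsFactors = FALSE
    )
    list(
      peaks = peaks, genes = genes, degs = degs, universe = ids,
      target_genes = ids[target_idx],
      background_fraction = bg_frac,
      expected_deg_fraction = q,
      realized_deg_fraction = n_deg_target / n_deg
    )
  })
}
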