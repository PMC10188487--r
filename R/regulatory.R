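#' Concatenate two peak sets
#'
#' Multiset union of two `GRanges` peak lists, sorted by chromosome and
#' start; overlapping or duplicate peaks are kept as-is (concatenation, not
#' interval union, matching how the two chromatin profiles were combined).
#'
#' @param peaks_a,peaks_b `GRanges` objects in the same coordinate system.
#' @return sorted `GRanges`.
#' @export
concat_peaks <- function(peaks_a, peaks_b) {
  .assert(methods::is(peaks_a, "GRanges") && methods::is(peaks_b, "GRanges"),
          "peaks must be GRanges")
  BiocGenerics::sort(c(peaks_a, peaks_b), ignore.strand = TRUE)
}

# Genes table (BED-style 0-based half-open) -> GRanges (1-based closed).
.genes_to_granges <- function(genes) {
  need <- c("gene_id", "chrom", "start", "end")
  .assert(all(need %in% names(genes)), "genes need gene_id/chrom/start/end")
  .assert(!anyDuplicated(genes$gene_id), "gene_ids must be unique")
  .assert(all(genes$start >= 0 & genes$start < genes$end),
          "gene intervals must satisfy 0 <= start < end")
  GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    gene_id = genes$gene_id
  )
}

#' Assign each peak to its closest gene
#'
#' Distance is 0 when the peak overlaps the gene body and otherwise the gap
#' between the nearest interval ends; ties are broken deterministically by
#' the smaller gene start. Peaks on chromosomes without genes are reported
#' unassigned (`NA`).
#'
#' @param peaks `GRanges` of peaks.
#' @param genes gene table with `gene_id, chrom, start, end` (BED-style
#'   0-based half-open coordinates) and optionally `strand`.
#' @return data.frame with one row per peak: `peak_chrom`, `peak_start`,
#'   `peak_end` (0-based half-open), `gene_id`, `distance`.
#' @export
closest_gene <- function(peaks, genes) {
  .assert(methods::is(peaks, "GRanges"), "peaks must be GRanges")
  gr <- .genes_to_granges(genes)
  n <- length(peaks)
  out <- data.frame(
    peak_chrom = as.character(GenomicRanges::seqnames(peaks)),
    peak_start = GenomicRanges::start(peaks) - 1L,
    peak_end = GenomicRanges::end(peaks),
    gene_id = NA_character_,
    distance = NA_integer_
  )
  if (n == 0 || length(gr) == 0) return(out)
  # candidate nearest genes per peak: every overlapping gene plus the closest
  # gene on either side; distance ties are then broken by the smaller start
  # (distanceToNearest alone reports a single arbitrary gene on ties)
  # peaks on chromosomes absent from the gene set are simply unassigned;
  # suppress the disjoint-seqlevels warning that case triggers
  ov <- suppressWarnings(GenomicRanges::findOverlaps(peaks, gr, ignore.strand = TRUE))
  fw <- suppressWarnings(GenomicRanges::precede(peaks, gr, ignore.strand = TRUE))
  bw <- suppressWarnings(GenomicRanges::follow(peaks, gr, ignore.strand = TRUE))
  cand <- rbind(
    cbind(S4Vectors::queryHits(ov), S4Vectors::subjectHits(ov)),
    cbind(which(!is.na(fw)), fw[!is.na(fw)]),
    cbind(which(!is.na(bw)), bw[!is.na(bw)])
  )
  if (!nrow(cand)) return(out)
  cand <- unique(cand)
  dd <- GenomicRanges::distance(peaks[cand[, 1]], gr[cand[, 2]],
                                ignore.strand = TRUE)
  ord <- order(cand[, 1], dd, GenomicRanges::start(gr)[cand[, 2]])
  first <- !duplicated(cand[ord, 1])
  pick_q <- cand[ord, 1][first]
  pick_s <- cand[ord, 2][first]
  pick_d <- dd[ord][first]
  out$gene_id[pick_q] <- S4Vectors::mcols(gr)$gene_id[pick_s]
  out$distance[pick_q] <- pick_d
  out
}

#' Filter a differential-expression table to significant genes
#'
#' Keeps rows with `padj < padj_max` and `|log2fc| >= min_abs_log2fc`
#' (defaults 0.05 and 1), optionally
#' restricted to one direction (the peak-overlap comparison uses the
#' downregulated set).
#'
#' @param degs data.frame with `gene_id`, `log2fc`, `padj`.
#' @param padj_max adjusted-p cutoff (exclusive).
#' @param min_abs_log2fc absolute log2 fold-change cutoff (inclusive).
#' @param direction `"both"`, `"down"` (log2fc <= -cutoff) or `"up"`.
#' @return character vector of gene ids.
#' @export
filter_degs <- function(degs, padj_max = 0.05, min_abs_log2fc = 1,
                        direction = c("both", "down", "up")) {
  direction <- match.arg(direction)
  need <- c("gene_id", "log2fc", "padj")
  .assert(all(need %in% names(degs)), "degs need gene_id/log2fc/padj")
  .assert(all(degs$padj >= 0 & degs$padj <= 1, na.rm = TRUE), "padj must be in [0,1]")
  keep <- !is.na(degs$padj) & degs$padj < padj_max
  keep <- keep & switch(direction,
    both = abs(degs$log2fc) >= min_abs_log2fc,
    down = degs$log2fc <= -min_abs_log2fc,
    up = degs$log2fc >= min_abs_log2fc)
  degs$gene_id[keep]
}

#' Enrichment of peak-associated genes among DEGs
#'
#' Compares the fraction of differentially expressed genes that are
#' associated with a chromatin peak against the corresponding fraction in a
#' control set with a pooled two-proportion Z test. The control is the
#' whole expressed-gene universe by default, or the non-DEG remainder.
#'
#' @param deg_genes character vector of DEG ids.
#' @param target_genes character vector of peak-associated gene ids.
#' @param universe_genes character vector of all expressed genes (the
#'   background after low-count filtering).
#' @param control `"universe"` or `"non_deg"`.
#' @return list with `z`, `p`, `deg_fraction`, `control_fraction`, and the
#'   counts `x1, n1, x2, n2`; the full test object under `$test`.
#' @export
enrichment_test <- function(deg_genes, target_genes, universe_genes,
                            control = c("universe", "non_deg")) {
  control <- match.arg(control)
  .assert(length(universe_genes) > 0, "empty universe")
  deg <- intersect(unique(deg_genes), universe_genes)
  tgt <- intersect(unique(target_genes), universe_genes)
  .assert(length(deg) > 0, "empty DEG set after universe filtering")
  ctrl <- if (control == "universe") unique(universe_genes)
          else setdiff(universe_genes, deg)
  x1 <- length(intersect(deg, tgt)); n1 <- length(deg)
  x2 <- length(intersect(ctrl, tgt)); n2 <- length(ctrl)
  zt <- two_proportion_z(x1, n1, x2, n2)
  list(z = zt$statistic, p = zt$p_two_sided,
       deg_fraction = x1 / n1, control_fraction = x2 / n2,
       x1 = x1, n1 = n1, x2 = x2, n2 = n2, test = zt)
}
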