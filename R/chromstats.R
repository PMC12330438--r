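#' Sex-chromosome assembly window-coverage statistic
#'
#' Partitions the chromosome into fixed windows (default 1 Mbp) and
#' qualifies a window when (a) the union of contig alignment blocks covers
#' at least `min_align_fraction` (default 0.95) of the window's unmasked
#' length and (b) no more than `max_contigs` (default 3) distinct contigs
#' overlap it. Windows fully inside the exclusion mask (PARs, centromere,
#' chrY heterochromatin) are excluded from the denominator. The coverage
#' percent is qualified windows / assessable windows * 100.
#'
#' @param paf PAF data.frame (see [read_paf()]) for one target chromosome.
#' @param chrom chromosome being assessed.
#' @param chrom_length chromosome length (bp).
#' @param window window size (bp), default 1e6.
#' @param min_align_fraction default 0.95.
#' @param max_contigs default 3.
#' @param mask optional [exclusion_mask()].
#' @return list: `windows` data.frame (start, end, masked, covered_frac,
#'   n_contigs, qualified), `percent`.
#' @export
window_coverage <- function(paf, chrom, chrom_length, window = 1e6,
                            min_align_fraction = 0.95, max_contigs = 3,
                            mask = NULL) {
  paf <- paf[paf$tname == chrom, , drop = FALSE]
  starts <- seq(0, chrom_length - 1, by = window)
  ends <- pmin(starts + window, chrom_length)
  nw <- length(starts)

  mask_ir <- if (!is.null(mask) && nrow(mask)) {
    m <- mask[mask$chrom == chrom, , drop = FALSE]
    IRanges::reduce(IRanges::IRanges(start = m$start + 1, end = m$end))
  } else IRanges::IRanges()

  aln_by_contig <- split(IRanges::IRanges(start = paf$tstart + 1,
                                          end = paf$tend),
                         paf$qname)
  aln_union <- IRanges::reduce(IRanges::IRanges(start = paf$tstart + 1,
                                                end = paf$tend))

  masked <- covered <- numeric(nw)
  n_contigs <- integer(nw)
  for (w in seq_len(nw)) {
    win <- IRanges::IRanges(start = starts[w] + 1, end = ends[w])
    unmasked <- IRanges::setdiff(win, mask_ir)
    ulen <- sum(IRanges::width(unmasked))
    masked[w] <- ulen == 0
    if (ulen == 0) { covered[w] <- 0; next }
    cov <- sum(IRanges::width(IRanges::intersect(aln_union, unmasked)))
    covered[w] <- cov / ulen
    n_contigs[w] <- sum(vapply(aln_by_contig, function(ir)
      sum(IRanges::width(IRanges::intersect(ir, unmasked))) > 0, logical(1)))
  }
  assessable <- !masked
  if (!any(assessable)) stop("no assessable windows on ", chrom)
  qualified <- assessable & covered >= min_align_fraction &
    n_contigs <= max_contigs
  list(windows = data.frame(start = starts, end = ends,
                            masked = as.logical(masked),
                            covered_frac = covered, n_contigs = n_contigs,
                            qualified = qualified),
       percent = 100 * sum(qualified) / sum(assessable))
}

#' Haplotype-resolved CpG-island methylation skew
#'
#' For each CpG island, computes the mean methylated fraction per haplotype
#' over all CpG sites within the island plus `flank` bp on each side
#' (default 5,000). Islands with zero covered CpGs on either haplotype are
#' flagged and excluded from the chromosome summary. The chromosome summary
#' reports the mean hap1 - hap2 difference and the fraction of islands
#' favouring each haplotype.
#'
#' @param hap1,hap2 per-CpG methylation tables (chrom, start, end, frac in
#'   \[0,1\]), e.g. from [read_bedmethyl()].
#' @param cpg_islands data.frame (chrom, start, end), 0-based half-open.
#' @param flank flank size in bp, default 5000.
#' @return list of class `skew_result`: `islands` data.frame (chrom, start,
#'   end, mean_hap1, mean_hap2, diff, n_cpg_hap1, n_cpg_hap2, covered),
#'   `mean_diff`, `frac_hap1_higher`, `frac_hap2_higher`, `n_islands_used`.
#' @export
methylation_skew <- function(hap1, hap2, cpg_islands, flank = 5000) {
  stopifnot(flank >= 0)
  island_gr <- GenomicRanges::GRanges(
    cpg_islands$chrom,
    IRanges::IRanges(start = pmax(cpg_islands$start - flank, 0) + 1,
                     end = cpg_islands$end + flank))
  mean_in <- function(hap) {
    gr <- GenomicRanges::GRanges(hap$chrom,
                                 IRanges::IRanges(start = hap$start + 1,
                                                  end = pmax(hap$end, hap$start + 1)))
    hits <- GenomicRanges::findOverlaps(island_gr, gr)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    m <- rep(NA_real_, length(island_gr))
    n <- integer(length(island_gr))
    if (length(qi)) {
      sums <- tapply(hap$frac[si], qi, sum)
      cnts <- tapply(si, qi, length)
      idx <- as.integer(names(sums))
      m[idx] <- sums / cnts
      n[idx] <- cnts
    }
    list(mean = m, n = n)
  }
  m1 <- mean_in(hap1); m2 <- mean_in(hap2)
  covered <- m1$n > 0 & m2$n > 0
  if (!any(covered)) stop("no CpG island covered on both haplotypes")
  islands <- data.frame(chrom = cpg_islands$chrom, start = cpg_islands$start,
                        end = cpg_islands$end,
                        mean_hap1 = m1$mean, mean_hap2 = m2$mean,
                        diff = m1$mean - m2$mean,
                        n_cpg_hap1 = m1$n, n_cpg_hap2 = m2$n,
                        covered = covered)
  used <- islands[covered, , drop = FALSE]
  structure(list(islands = islands,
                 mean_diff = mean(used$diff),
                 frac_hap1_higher = mean(used$diff > 0),
                 frac_hap2_higher = mean(used$diff < 0),
                 n_islands_used = nrow(used)),
            class = "skew_result")
}

#' Call X-inactivation skew from a methylation skew result
#'
#' The chromosome is called skewed when the absolute mean haplotype
#' difference reaches `threshold` (default 0.25) and at least `agreement`
#' (default 80%) of covered islands agree in direction. Direction is mapped
#' to parental haplotypes via `hap1_parent`. Higher CpG-island methylation
#' marks the inactive X, so the more-methylated haplotype is the silenced
#' one.
#'
#' @param skew a [methylation_skew()] result.
#' @param threshold minimum |mean difference|, default 0.25.
#' @param agreement minimum fraction of islands agreeing in direction.
#' @param hap1_parent "maternal" or "paternal" label of haplotype 1.
#' @return one of "maternal_skewed", "paternal_skewed", "balanced".
#' @export
xci_call <- function(skew, threshold = 0.25, agreement = 0.8,
                     hap1_parent = "maternal") {
  stopifnot(hap1_parent %in% c("maternal", "paternal"))
  d <- skew$mean_diff
  frac_agree <- if (d >= 0) skew$frac_hap1_higher else skew$frac_hap2_higher
  if (abs(d) < threshold || frac_agree < agreement) return("balanced")
  hap2_parent <- setdiff(c("maternal", "paternal"), hap1_parent)
  silenced <- if (d > 0) hap1_parent else hap2_parent
  paste0(silenced, "_skewed")
}
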