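#' Build an annotation interval track
#'
#' Intervals are 0-based half-open. `class` drives the functional logic:
#' gene-model classes (`exon`, `utr`, `intron`) feed the primary class with
#' precedence Exon > UTR > Intron > Inter (the complement); flag classes set
#' independent flags. When `flag` is not given it defaults by class:
#' promoter/enhancer/tf_cluster -> REG, tr -> TR, segdup -> SegDup.
#'
#' @param name track name.
#' @param class one of exon, utr, intron, promoter, enhancer, tf_cluster,
#'   cpg_island, tr, segdup, custom.
#' @param intervals data.frame with chrom, start, end and optional `gene`
#'   (symbol) and `score` columns.
#' @param flag one of NDD, REG, brainREG, TR, SegDup or NA.
#' @return list of class `annotation_track`.
#' @export
annotation_track <- function(name, class, intervals, flag = NULL) {
  class <- match.arg(class, c("exon", "utr", "intron", "promoter", "enhancer",
                              "tf_cluster", "cpg_island", "tr", "segdup",
                              "custom"))
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)),
            all(intervals$start >= 0), all(intervals$end >= intervals$start))
  intervals <- intervals[order(intervals$chrom, intervals$start), , drop = FALSE]
  if (is.null(flag))
    flag <- switch(class, promoter = "REG", enhancer = "REG",
                   tf_cluster = "REG", tr = "TR", segdup = "SegDup",
                   NA_character_)
  structure(list(name = name, class = class, intervals = intervals,
                 flag = flag), class = "annotation_track")
}

track_granges <- function(track) {
  iv <- track$intervals
  if (nrow(iv) == 0) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(iv$chrom, IRanges::IRanges(start = iv$start + 1,
                                                    end = pmax(iv$end, iv$start + 1)))
}

#' Assign functional labels to SVs by interval intersection
#'
#' Each SV gets exactly one primary class by >= 1 bp overlap with gene-model
#' tracks, precedence Exon > UTR > Intron > Inter; flags (NDD, REG, brainREG,
#' TR, SegDup) are set independently per overlapping flag track; gene
#' symbols are collected from all overlapped gene-bearing intervals. DELs
#' intersect with their reference span, INS as a point at the insertion site.
#'
#' @param svs [sv_calls()] (or `sv_matrix$loci`) table.
#' @param tracks list of [annotation_track()]s.
#' @param utr_into_exon fold the UTR primary class into Exon (the grouping
#'   used for burden counting), default FALSE.
#' @return data.frame: locus_id, primary_class, logical flag columns NDD,
#'   REG, brainREG, TR, SegDup, and `genes` (comma-separated).
#' @export
annotate_sv <- function(svs, tracks, utr_into_exon = FALSE) {
  n <- nrow(svs)
  gr <- sv_granges(svs)
  prim_rank <- c(Exon = 1, UTR = 2, Intron = 3, Inter = 4)
  primary <- rep("Inter", n)
  flags <- matrix(FALSE, n, 5,
                  dimnames = list(NULL, c("NDD", "REG", "brainREG", "TR", "SegDup")))
  genes <- vector("list", n)
  for (tr in tracks) {
    hits <- GenomicRanges::findOverlaps(gr, track_granges(tr))
    qi <- S4Vectors::queryHits(hits)
    if (!length(qi)) next
    pc <- switch(tr$class, exon = "Exon", utr = "UTR", intron = "Intron", NULL)
    if (!is.null(pc)) {
      upd <- prim_rank[pc] < prim_rank[primary[qi]]
      primary[qi[upd]] <- pc
    }
    if (!is.na(tr$flag)) flags[unique(qi), tr$flag] <- TRUE
    if ("gene" %in% names(tr$intervals)) {
      si <- S4Vectors::subjectHits(hits)
      for (k in seq_along(qi))
        genes[[qi[k]]] <- c(genes[[qi[k]]], tr$intervals$gene[si[k]])
    }
  }
  if (utr_into_exon) primary[primary == "UTR"] <- "Exon"
  data.frame(locus_id = svs$id, primary_class = primary,
             as.data.frame(flags),
             genes = vapply(genes, function(g)
               paste(unique(g[!is.na(g)]), collapse = ","), character(1)),
             stringsAsFactors = FALSE)
}

#' Fractional gain in regulatory SVs from brain-derived tracks
#'
#' `(count(REG or brainREG) - count(REG)) / count(REG)` over a labeled SV
#' set: the relative increase in regulatory SVs contributed by the
#' brain-derived regulatory annotation on top of the general one.
#'
#' @param labels output of [annotate_sv()].
#' @return single fraction (0 when no SV is REG-labelled and none gained).
#' @export
reg_gain <- function(labels) {
  n_reg <- sum(labels$REG)
  n_both <- sum(labels$REG | labels$brainREG)
  if (n_reg == 0) {
    if (n_both == 0) return(0)
    return(Inf)
  }
  (n_both - n_reg) / n_reg
}
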