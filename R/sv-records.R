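#' Construct and validate a table of SV calls
#'
#' The package's working representation of SV records is a plain data.frame
#' with one row per call:
#' \describe{
#'   \item{id}{call identifier, unique within a callset}
#'   \item{sample}{sample identifier (may be NA for locus tables)}
#'   \item{chrom}{chromosome name}
#'   \item{pos}{1-based reference position (VCF convention)}
#'   \item{svtype}{"DEL" or "INS" — the only classes analysed here}
#'   \item{svlen}{positive length in bp, >= 50}
#'   \item{end}{1-based inclusive end: pos + svlen for DEL, pos for INS}
#'   \item{seq}{allele sequence or NA (INS: inserted bases; DEL: optional)}
#'   \item{qual}{non-negative quality}
#'   \item{callers}{comma-separated subset of assembly, aligner_a, aligner_b}
#'   \item{gt}{VCF-style genotype string}
#' }
#'
#' @param df data.frame carrying at least chrom, pos, svtype, svlen.
#' @param validate check invariants (default TRUE).
#' @return data.frame of class `sv_calls`.
#' @export
sv_calls <- function(df, validate = TRUE) {
  need <- c("chrom", "pos", "svtype", "svlen")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  n <- nrow(df)
  if (!"id" %in% names(df)) df$id <- sprintf("sv%06d", seq_len(n))
  if (!"sample" %in% names(df)) df$sample <- rep(NA_character_, n)
  if (!"end" %in% names(df))
    df$end <- ifelse(df$svtype == "DEL", df$pos + df$svlen, df$pos)
  if (!"seq" %in% names(df)) df$seq <- rep(NA_character_, n)
  if (!"qual" %in% names(df)) df$qual <- rep(0, n)
  if (!"callers" %in% names(df)) df$callers <- rep("", n)
  if (!"gt" %in% names(df)) df$gt <- rep("0/1", n)
  df <- df[, c("id", "sample", "chrom", "pos", "svtype", "svlen", "end",
               "seq", "qual", "callers", "gt",
               setdiff(names(df), c("id", "sample", "chrom", "pos", "svtype",
                                    "svlen", "end", "seq", "qual", "callers",
                                    "gt")))]
  if (validate && nrow(df)) {
    stopifnot(all(df$svtype %in% c("DEL", "INS")))
    if (any(df$svlen < 50))
      stop("svlen < 50: SVs are defined as events of at least 50 bp")
    bad_del <- df$svtype == "DEL" & df$end - df$pos != df$svlen
    bad_ins <- df$svtype == "INS" & df$end != df$pos
    if (any(bad_del | bad_ins)) stop("end/pos/svlen inconsistency")
    has_seq <- df$svtype == "INS" & !is.na(df$seq)
    if (any(has_seq & nchar(df$seq) != df$svlen))
      stop("INS seq length must equal svlen")
    if (any(df$qual < 0)) stop("negative qual")
  }
  rownames(df) <- NULL
  class(df) <- unique(c("sv_calls", class(df)))
  df
}

#' SV matching / collapsing parameters
#'
#' Mirrors the truvari flags by name: `pctseq` and `pctsize` are the minimum
#' sequence identity and reciprocal size ratio, `refdist` the maximum
#' breakpoint distance in bp, `sizemin`/`sizemax` the retained length range,
#' and `keep_rule` how a cluster representative is picked ("maxqual" for
#' within-sample collapse, "common" — most widely carried member — for the
#' cohort-level collapse).
#'
#' @param pctseq,pctsize reals in \[0,1\], default 0.90.
#' @param refdist bp, default 500.
#' @param sizemin,sizemax bp bounds, defaults 0 and 1,000,000.
#' @param keep_rule "maxqual" or "common".
#' @return list of class `merge_params`.
#' @export
merge_params <- function(pctseq = 0.90, pctsize = 0.90, refdist = 500,
                         sizemin = 0, sizemax = 1e6, keep_rule = "maxqual") {
  stopifnot(pctseq >= 0, pctseq <= 1, pctsize >= 0, pctsize <= 1,
            refdist >= 0, sizemin <= sizemax)
  keep_rule <- match.arg(keep_rule, c("maxqual", "common"))
  structure(list(pctseq = pctseq, pctsize = pctsize, refdist = refdist,
                 sizemin = sizemin, sizemax = sizemax, keep_rule = keep_rule),
            class = "merge_params")
}

sv_granges <- function(calls) {
  # DEL spans [pos, end]; INS is a point at its insertion site
  GenomicRanges::GRanges(
    calls$chrom,
    IRanges::IRanges(start = calls$pos,
                     end = ifelse(calls$svtype == "DEL", calls$end, calls$pos))
  )
}

#' Remove SVs overlapping an exclusion mask
#'
#' An SV is dropped when its reference footprint (`[pos-1, end)` for DEL, the
#' insertion point for INS) overlaps any mask interval by at least 1 bp.
#'
#' @param calls an [sv_calls()] table.
#' @param mask an [exclusion_mask()].
#' @return filtered `sv_calls` table.
#' @export
apply_mask <- function(calls, mask) {
  if (nrow(calls) == 0 || is.null(mask) || nrow(mask) == 0) return(calls)
  hits <- GenomicRanges::findOverlaps(sv_granges(calls), mask_granges(mask))
  drop <- unique(S4Vectors::queryHits(hits))
  if (length(drop)) calls <- calls[-drop, , drop = FALSE]
  rownames(calls) <- NULL
  calls
}
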