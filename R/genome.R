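#' Compact genome model used throughout the package
#'
#' A genome model carries chromosome lengths, pseudoautosomal regions (PARs)
#' on chrX/chrY, and the standing exclusion mask (assembly gaps, centromeres,
#' PARs, and the chrY heterochromatic block). Real analyses would load these
#' from reference annotation; the default model is a small synthetic genome
#' sized for fast simulation while preserving the autosome/X/Y structure the
#' sex-aware logic needs.
#'
#' @param lengths named integer vector of chromosome lengths (bp).
#' @param par data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) marking pseudoautosomal intervals on chrX and chrY.
#' @param mask optional [exclusion_mask()] of additional dropped regions.
#' @return an object of class `sv_genome`.
#' @export
sv_genome <- function(lengths, par, mask = NULL) {
  stopifnot(is.numeric(lengths), !is.null(names(lengths)), all(lengths > 0))
  stopifnot(is.data.frame(par), all(c("chrom", "start", "end") %in% names(par)))
  if (is.null(mask)) mask <- exclusion_mask(par$chrom, par$start, par$end, "PAR")
  structure(list(lengths = lengths, par = par, mask = mask),
            class = "sv_genome")
}

#' @rdname sv_genome
#' @details `default_genome()` returns a 5-chromosome model (three autosomes,
#' chrX with two PARs, chrY with two PARs plus a masked heterochromatic
#' region) totalling ~205 Mbp.
#' @export
default_genome <- function() {
  lengths <- c(chr1 = 60e6, chr2 = 50e6, chr3 = 40e6, chrX = 40e6, chrY = 15e6)
  par <- data.frame(
    chrom = c("chrX", "chrX", "chrY", "chrY"),
    start = c(0, 39e6, 0, 14e6),
    end   = c(1e6, 40e6, 1e6, 15e6)
  )
  # mask = PARs plus a Yq12-like heterochromatic block and small centromeres
  mask <- exclusion_mask(
    chrom = c(par$chrom, "chrY", "chr1", "chr2", "chr3", "chrX"),
    start = c(par$start, 10e6, 29.5e6, 24.5e6, 19.5e6, 19.5e6),
    end   = c(par$end,   12e6, 30.5e6, 25.5e6, 20.5e6, 20.5e6),
    name  = c(rep("PAR", 4), "Yq12", rep("centromere", 4))
  )
  sv_genome(lengths, par, mask)
}

#' Exclusion mask of genomic intervals
#'
#' Named interval set (0-based half-open) of regions removed from SV analysis:
#' gaps, telomeres, centromeres, PARs, chrY heterochromatin.
#'
#' @param chrom,start,end interval coordinates (0-based half-open).
#' @param name optional label per interval.
#' @return data.frame of class `exclusion_mask`, sorted per chromosome.
#' @export
exclusion_mask <- function(chrom, start, end, name = "masked") {
  stopifnot(length(start) == length(end))
  chrom <- rep_len(as.character(chrom), length(start))
  stopifnot(all(start >= 0), all(end >= start))
  m <- data.frame(chrom = chrom, start = as.numeric(start),
                  end = as.numeric(end), name = rep_len(name, length(chrom)))
  m <- m[order(m$chrom, m$start), , drop = FALSE]
  rownames(m) <- NULL
  class(m) <- c("exclusion_mask", "data.frame")
  m
}

mask_granges <- function(mask) {
  if (is.null(mask) || nrow(mask) == 0) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(mask$chrom,
                         IRanges::IRanges(start = mask$start + 1, end = mask$end))
}

#' Is a position inside a pseudoautosomal region?
#'
#' @param chrom,pos chromosome and 1-based position vectors.
#' @param genome an [sv_genome()].
#' @return logical vector.
#' @export
in_par <- function(chrom, pos, genome) {
  par <- genome$par
  out <- logical(length(chrom))
  for (i in seq_len(nrow(par))) {
    hit <- chrom == par$chrom[i] & pos > par$start[i] & pos <= par$end[i]
    out <- out | hit
  }
  out
}

#' Should a locus be hemizygous in a given sample?
#'
#' TRUE for non-PAR chrX and non-PAR chrY positions in males; FALSE elsewhere
#' (females never carry chrY loci in this model, see [classify_category()]).
#'
#' @inheritParams in_par
#' @param sex "male" or "female" (recycled).
#' @export
is_hemi_locus <- function(chrom, pos, sex, genome) {
  sex <- rep_len(sex, length(chrom))
  sex == "male" & chrom %in% c("chrX", "chrY") & !in_par(chrom, pos, genome)
}
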