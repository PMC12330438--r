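#' Genotype string utilities
#'
#' Genotypes are carried as VCF-style GT strings: diploid `"0/1"`, `"1|1"`,
#' `"./."`; hemizygous `"0"`, `"1"`, `"."`. These helpers parse them without
#' any per-locus context.
#'
#' @param gt character vector of GT strings.
#' @return `gt_alleles()` returns a list of integer vectors (NA for missing
#'   alleles); `gt_dosage()` the count of alt alleles (NA if all alleles
#'   missing); `gt_ploidy()` 1 or 2; `gt_missing()` logical (all alleles
#'   missing).
#' @export
gt_alleles <- function(gt) {
  lapply(strsplit(as.character(gt), "[/|]"), function(a) {
    a[a == "."] <- NA
    as.integer(a)
  })
}

#' @rdname gt_alleles
#' @export
gt_dosage <- function(gt) {
  vapply(gt_alleles(gt), function(a) {
    if (all(is.na(a))) NA_integer_ else sum(a > 0, na.rm = TRUE)
  }, integer(1))
}

#' @rdname gt_alleles
#' @export
gt_ploidy <- function(gt) {
  lengths(gt_alleles(gt))
}

#' @rdname gt_alleles
#' @export
gt_missing <- function(gt) {
  vapply(gt_alleles(gt), function(a) all(is.na(a)), logical(1))
}

#' @rdname gt_alleles
#' @param phased logical; `gt_phased()` reports whether the separator is `|`.
#' @export
gt_phased <- function(gt, phased) {
  grepl("|", as.character(gt), fixed = TRUE)
}

#' Coerce diploid male sex-chromosome genotypes to hemizygous
#'
#' Callers sometimes emit diploid genotypes on non-PAR chrX/chrY in males.
#' The rule applied here (the choice is ours; upstream tools do not define
#' one): any alt allele present collapses to `"1"`, otherwise `"0"`; fully
#' missing stays `"."`. A warning summarises how many calls were coerced.
#'
#' @param gt character GT vector.
#' @param chrom,pos locus coordinates (1-based).
#' @param sex sample sex, "male" or "female".
#' @param genome [sv_genome()] providing PAR intervals.
#' @param quiet suppress the coercion warning.
#' @return character GT vector with hemizygous male sex-chromosome calls.
#' @export
coerce_hemizygous <- function(gt, chrom, pos, sex, genome, quiet = FALSE) {
  gt <- as.character(gt)
  hemi <- is_hemi_locus(chrom, pos, rep_len(sex, length(gt)), genome)
  diploid <- gt_ploidy(gt) == 2
  fix <- hemi & diploid
  if (any(fix)) {
    dos <- gt_dosage(gt[fix])
    gt[fix] <- ifelse(is.na(dos), ".", ifelse(dos > 0, "1", "0"))
    if (!quiet)
      warning(sum(fix), " diploid male sex-chromosome genotype(s) coerced to hemizygous")
  }
  gt
}

#' Mendelian consistency of a child genotype given its parents
#'
#' Decides whether a child's genotype is drawable from the parental genotypes:
#' one allele from each parent on autosomes (and chrX in females), the single
#' allele from the mother on non-PAR chrX in males, and from the father on
#' chrY. A required parental genotype that is entirely missing yields
#' `"unknown"` (the call is routed to transmission curation rather than being
#' declared a violation).
#'
#' @param child_gt,father_gt,mother_gt GT strings (vectors recycled together).
#' @param chrom chromosome of each locus.
#' @param pos 1-based position (needed for PAR checks).
#' @param child_sex "male" or "female".
#' @param genome [sv_genome()].
#' @return character vector in `c("consistent", "violation", "unknown")`.
#' @export
mendelian_check <- function(child_gt, father_gt, mother_gt, chrom, pos,
                            child_sex, genome = default_genome()) {
  n <- max(length(child_gt), length(father_gt), length(mother_gt), length(chrom))
  child_gt <- rep_len(as.character(child_gt), n)
  father_gt <- rep_len(as.character(father_gt), n)
  mother_gt <- rep_len(as.character(mother_gt), n)
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(pos, n)
  child_sex <- rep_len(child_sex, n)

  ca <- gt_alleles(child_gt)
  fa <- gt_alleles(father_gt)
  ma <- gt_alleles(mother_gt)
  hemi <- is_hemi_locus(chrom, pos, child_sex, genome)

  out <- character(n)
  for (i in seq_len(n)) {
    c_i <- ca[[i]]; f_i <- fa[[i]]; m_i <- ma[[i]]
    if (all(is.na(c_i))) { out[i] <- "unknown"; next }
    if (hemi[i] && chrom[i] == "chrX") {
      # male X: single allele must come from the mother
      if (all(is.na(m_i))) { out[i] <- "unknown"; next }
      out[i] <- if (any(c_i[1] == m_i, na.rm = TRUE)) "consistent" else "violation"
    } else if (chrom[i] == "chrY") {
      if (all(is.na(f_i))) { out[i] <- "unknown"; next }
      out[i] <- if (any(c_i[1] == f_i, na.rm = TRUE)) "consistent" else "violation"
    } else {
      if (all(is.na(f_i)) || all(is.na(m_i))) { out[i] <- "unknown"; next }
      if (length(c_i) == 1L) c_i <- c(c_i, c_i)  # defensive: treat as hom
      ok <- (any(c_i[1] == f_i, na.rm = TRUE) && any(c_i[2] == m_i, na.rm = TRUE)) ||
            (any(c_i[1] == m_i, na.rm = TRUE) && any(c_i[2] == f_i, na.rm = TRUE))
      out[i] <- if (ok) "consistent" else "violation"
    }
  }
  out
}

# apply a gt-string summary over matrix columns, robust to 0-column and
# 1-row matrices (plain apply() drops dimensions or misfires on those)
gt_apply <- function(gt, f) {
  out <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                dimnames = dimnames(gt))
  for (j in seq_len(ncol(gt))) out[, j] <- f(gt[, j])
  out
}
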