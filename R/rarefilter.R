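#' Remove SVs present in a pangenome control panel
#'
#' A child locus is removed when it matches (under [sv_match()]) any control
#' locus carried by at least one control individual. On autosomes every
#' control counts; on chrX/chrY the comparison is sex-matched — only controls
#' of the child's sex count as carriers. A control locus whose genotypes are
#' all missing is not considered carried.
#'
#' @param child_loci [sv_calls()] table of one child's loci (with `gt`).
#' @param control_matrix `sv_matrix` of the control panel.
#' @param child_sex "male" or "female".
#' @param params [merge_params()] — must be the collapse parameters.
#' @param control_meta data.frame (sample, sex) for the control panel;
#'   required when any child locus is on chrX/chrY.
#' @return list with `rare` (retained loci), `removed`, and `matched_id`
#'   (control locus matched by each removed child locus).
#' @export
filter_common <- function(child_loci, control_matrix, child_sex,
                          params = merge_params(), control_meta = NULL) {
  if (nrow(control_matrix$loci) == 0 || length(control_matrix$samples) == 0) {
    warning("empty control panel: no SVs filtered; every locus passes")
    return(list(rare = child_loci,
                removed = child_loci[0, , drop = FALSE],
                matched_id = character(0)))
  }
  carried <- control_carriers(control_matrix, control_meta)
  cl <- control_matrix$loci
  keep <- logical(nrow(child_loci))
  matched_id <- character(0)
  for (i in seq_len(nrow(child_loci))) {
    chrom <- child_loci$chrom[i]
    carrier_set <- if (chrom %in% c("chrX", "chrY")) {
      if (is.null(control_meta))
        stop("control_meta with sexes required for sex-chromosome filtering")
      if (child_sex == "male") carried$male else carried$female
    } else carried$any
    cand <- which(cl$chrom == chrom & carrier_set &
                    abs(cl$pos - child_loci$pos[i]) <= params$refdist)
    hit <- FALSE
    for (j in cand) {
      if (match_against(child_loci[i, ], cl[j, , drop = FALSE], params)) {
        hit <- TRUE
        matched_id <- c(matched_id, cl$id[j])
        break
      }
    }
    keep[i] <- !hit
  }
  list(rare = child_loci[keep, , drop = FALSE],
       removed = child_loci[!keep, , drop = FALSE],
       matched_id = matched_id)
}

control_carriers <- function(control_matrix, control_meta) {
  gt <- control_matrix$gt
  dos <- gt_apply(gt, gt_dosage)
  carried_by <- !is.na(dos) & dos >= 1
  anyc <- rowSums(carried_by) >= 1
  male <- female <- anyc
  if (!is.null(control_meta)) {
    sex <- control_meta$sex[match(control_matrix$samples, control_meta$sample)]
    male <- rowSums(carried_by[, sex == "male", drop = FALSE]) >= 1
    female <- rowSums(carried_by[, sex == "female", drop = FALSE]) >= 1
  }
  list(any = anyc, male = male, female = female)
}

#' Assign the six-way rare-SV genotype category
#'
#' Autosome het -> `AUTO_HET`, autosome hom-alt -> `AUTO_HOM`; female chrX
#' het/hom -> `X_HET`/`X_HOM`; male non-PAR chrX alt -> `MALE_HEMI_X`; male
#' chrY alt -> `MALE_HEMI_Y`. Diploid PAR calls are classified
#' autosomal-style. The categories are mutually exclusive and exhaustive for
#' carried DEL/INS genotypes. A chrY call in a female is an error.
#'
#' @param chrom,pos locus coordinates.
#' @param gt genotype string(s), alt dosage >= 1.
#' @param sex child sex.
#' @param genome [sv_genome()].
#' @return character vector of categories.
#' @export
classify_category <- function(chrom, pos, gt, sex, genome = default_genome()) {
  n <- length(gt)
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n); sex <- rep_len(sex, n)
  dos <- gt_dosage(gt)
  pl <- gt_ploidy(gt)
  if (any(chrom == "chrY" & sex == "female" & !is.na(dos) & dos > 0))
    stop("chrY alt call in a female sample")
  if (any(is.na(dos) | dos < 1))
    stop("classify_category expects carried genotypes (alt dosage >= 1)")
  hemi <- is_hemi_locus(chrom, pos, sex, genome) & pl == 1
  out <- character(n)
  x_like <- chrom == "chrX" & !in_par(chrom, pos, genome)
  out[hemi & chrom == "chrX"] <- "MALE_HEMI_X"
  out[hemi & chrom == "chrY"] <- "MALE_HEMI_Y"
  diploid <- !hemi
  out[diploid & x_like & sex == "female" & dos == 1] <- "X_HET"
  out[diploid & x_like & sex == "female" & dos == 2] <- "X_HOM"
  auto <- diploid & !(x_like & sex == "female")
  out[auto & dos == 1] <- "AUTO_HET"
  out[auto & dos == 2] <- "AUTO_HOM"
  if (any(out == ""))
    stop("unclassifiable genotype/chromosome combination")
  out
}

#' Label private inherited SVs
#'
#' A rare SV in a child is private inherited when exactly one parent across
#' all cohort parents carries the allele and that parent is the child's own
#' parent (the child inherited it). Origin records the carrier side. Missing
#' parental genotypes count as non-carrier for this frequency-style rule.
#'
#' @param matrix cohort `sv_matrix` genotyped for children and parents.
#' @param pedigree pedigree data.frame.
#' @param rare data.frame with `locus_id`, `child` for each rare (SV, child).
#' @return `rare` with added `class` ("private_inherited" or "rare_other")
#'   and `origin` columns.
#' @export
extract_private_inherited <- function(matrix, pedigree, rare) {
  parents <- pedigree[pedigree$role %in% c("father", "mother"), , drop = FALSE]
  pcols <- intersect(parents$sample, matrix$samples)
  pdos <- gt_apply(matrix$gt[, pcols, drop = FALSE], gt_dosage)
  carrier <- !is.na(pdos) & pdos >= 1
  idx <- match(rare$locus_id, matrix$loci$id)
  rare$class <- "rare_other"
  rare$origin <- "unknown"
  for (i in seq_len(nrow(rare))) {
    li <- idx[i]
    if (is.na(li)) next
    carriers <- pcols[carrier[li, ]]
    if (length(carriers) != 1) next
    fam <- pedigree$family[pedigree$sample == rare$child[i]]
    role <- parents$role[parents$sample == carriers]
    in_family <- parents$family[parents$sample == carriers] == fam
    child_dos <- gt_dosage(matrix$gt[li, rare$child[i]])
    if (in_family && !is.na(child_dos) && child_dos >= 1) {
      rare$class[i] <- "private_inherited"
      rare$origin[i] <- if (role == "father") "paternal" else "maternal"
    }
  }
  rare
}

#' Label biparental homozygous SVs
#'
#' A rare SV is biparental homozygous for a child when the child is
#' homozygous alt, both parents are heterozygous, no matching control locus
#' is homozygous in any control, and that configuration occurs in exactly one
#' family in the cohort. Origin is "both" by construction.
#'
#' @inheritParams extract_private_inherited
#' @param control_matrix control panel `sv_matrix`.
#' @param params [merge_params()] used for control matching.
#' @return `rare` with `class` upgraded to "biparental_hom" where the rule
#'   holds (origin "both").
#' @export
extract_biparental_hom <- function(matrix, pedigree, rare, control_matrix,
                                   params = merge_params()) {
  if (!"class" %in% names(rare)) { rare$class <- "rare_other"; rare$origin <- "unknown" }
  idx <- match(rare$locus_id, matrix$loci$id)
  kids <- pedigree[pedigree$role %in% c("proband", "sibling"), , drop = FALSE]
  ctrl_hom <- control_hom_carriers(control_matrix)
  for (i in seq_len(nrow(rare))) {
    li <- idx[i]
    if (is.na(li)) next
    locus <- matrix$loci[li, , drop = FALSE]
    if (locus$chrom %in% c("chrX", "chrY")) next  # autosomal rule
    if (!biparental_config(matrix, pedigree, li, rare$child[i])) next
    # configuration must be unique to one family cohort-wide
    fams <- unique(vapply(seq_len(nrow(kids)), function(k)
      if (biparental_config(matrix, pedigree, li, kids$sample[k]))
        kids$family[k] else NA_character_, character(1)))
    if (sum(!is.na(fams)) != 1) next
    # never homozygous in any control
    cand <- which(control_matrix$loci$chrom == locus$chrom & ctrl_hom &
                    abs(control_matrix$loci$pos - locus$pos) <= params$refdist)
    hom_in_ctrl <- any(vapply(cand, function(j)
      isTRUE(match_against(locus, control_matrix$loci[j, , drop = FALSE],
                           params)), logical(1)))
    if (hom_in_ctrl) next
    rare$class[i] <- "biparental_hom"
    rare$origin[i] <- "both"
  }
  rare
}

control_hom_carriers <- function(control_matrix) {
  dos <- gt_apply(control_matrix$gt, gt_dosage)
  pl <- gt_apply(control_matrix$gt, gt_ploidy)
  rowSums(!is.na(dos) & dos == 2 & pl == 2) >= 1
}

biparental_config <- function(matrix, pedigree, li, child) {
  fam <- pedigree$family[pedigree$sample == child]
  fa <- pedigree$sample[pedigree$family == fam & pedigree$role == "father"]
  mo <- pedigree$sample[pedigree$family == fam & pedigree$role == "mother"]
  if (!all(c(child, fa, mo) %in% matrix$samples)) return(FALSE)
  cd <- gt_dosage(matrix$gt[li, child])
  fd <- gt_dosage(matrix$gt[li, fa])
  md <- gt_dosage(matrix$gt[li, mo])
  isTRUE(cd == 2) && gt_ploidy(matrix$gt[li, child]) == 2 &&
    isTRUE(fd == 1) && isTRUE(md == 1)
}
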