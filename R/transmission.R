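#' Callable-region transmission score
#'
#' A fixed, documented logistic rule over parental alignment evidence at an
#' SV locus: `score = logistic(w0 + w1*log1p(n_reads) + w2*(mean_mapq/60) -
#' w3*frac_clipped)`. The score is monotone non-decreasing in supporting
#' reads and mean mapping quality and non-increasing in the clipped-read
#' fraction; a score at or above the threshold (default 0.5) resolves the SV
#' as transmitted at this step. Weights are exposed so the rule can be
#' recalibrated.
#'
#' @param n_reads supporting read count at the locus in one parent.
#' @param mean_mapq mean mapping quality (0-60).
#' @param frac_clipped fraction of clipped reads in \[0,1\].
#' @param weights named vector w0, w1, w2, w3.
#' @param threshold decision threshold, default 0.5.
#' @return list with `score`, `threshold`, `transmitted`.
#' @export
callable_score <- function(n_reads, mean_mapq, frac_clipped,
                           weights = c(w0 = -2, w1 = 1.5, w2 = 1, w3 = 2),
                           threshold = 0.5) {
  z <- weights[["w0"]] + weights[["w1"]] * log1p(n_reads) +
    weights[["w2"]] * (mean_mapq / 60) - weights[["w3"]] * frac_clipped
  score <- 1 / (1 + exp(-z))
  list(score = unname(score), threshold = threshold,
       transmitted = unname(score >= threshold))
}

#' Read-support confidence tier
#'
#' At least 3 supporting parental reads give a moderate-confidence
#' transmission; 1 gives low confidence (2 reads, unstated upstream, are
#' assigned low as well); 0 gives none.
#'
#' @param n_reads integer read count(s).
#' @return character vector in `c("moderate", "low", "none")`.
#' @export
read_support_tier <- function(n_reads) {
  ifelse(n_reads >= 3, "moderate", ifelse(n_reads >= 1, "low", "none"))
}

#' Search parental raw callsets for a relaxed match
#'
#' Rescues inheritance information lost at callerset validation: the child's
#' SV is compared against the parents' pre-validation raw calls with the
#' relaxed thresholds (pctseq/pctsize 0.9, same refdist).
#'
#' @param sv single-row [sv_calls()] record (the child's SV).
#' @param parental_raw named list of raw `sv_calls` tables, names "father"
#'   and "mother".
#' @param params [merge_params()]; pctseq/pctsize are forced to 0.9.
#' @return list with `found`, `parent` ("father"/"mother"/NA), and
#'   `similarity` (size similarity of the best hit).
#' @export
relaxed_rematch <- function(sv, parental_raw, params = merge_params()) {
  relaxed <- merge_params(pctseq = 0.9, pctsize = 0.9,
                          refdist = params$refdist,
                          sizemin = params$sizemin, sizemax = params$sizemax)
  for (side in c("father", "mother")) {
    raw <- parental_raw[[side]]
    if (is.null(raw) || nrow(raw) == 0) next
    cand <- raw[raw$chrom == sv$chrom, , drop = FALSE]
    hits <- match_against(sv, cand, relaxed)
    if (any(hits)) {
      j <- which(hits)[1]
      return(list(found = TRUE, parent = side,
                  similarity = min(sv$svlen, cand$svlen[j]) /
                    max(sv$svlen, cand$svlen[j])))
    }
  }
  list(found = FALSE, parent = NA_character_, similarity = NA_real_)
}

#' Parental genotyper support
#'
#' A parental re-genotyped alt call at the SV resolves it as transmitted.
#'
#' @param sv_id locus identifier.
#' @param genotyper data.frame (sv_id, sample, gt) of re-genotyped parental
#'   calls, or NULL when unavailable.
#' @param father,mother parental sample ids.
#' @return list with `found` and `parent`.
#' @export
genotyper_support <- function(sv_id, genotyper, father, mother) {
  if (is.null(genotyper)) return(list(found = FALSE, parent = NA_character_))
  for (side in c("father", "mother")) {
    s <- if (side == "father") father else mother
    row <- genotyper[genotyper$sv_id == sv_id & genotyper$sample == s, , drop = FALSE]
    if (nrow(row) && isTRUE(gt_dosage(row$gt[1]) >= 1))
      return(list(found = TRUE, parent = side))
  }
  list(found = FALSE, parent = NA_character_)
}

#' Compare tandem-repeat allele lengths between child and parents
#'
#' For SVs inside tandem repeats, transmission is assessed on genotyped
#' allele lengths: inherited when some parental allele is within
#' `max(tol_bp, tol_frac * child_al)` of the child's allele; expanded de novo
#' when the child allele exceeds every parental allele by more than the
#' tolerance; unresolved otherwise (e.g. child allele far *below* all
#' parental alleles).
#'
#' @param child_al child allele length (bp).
#' @param parental_al numeric vector of parental allele lengths.
#' @param tol_bp absolute tolerance, default 10 bp.
#' @param tol_frac relative tolerance, default 0.1.
#' @return one of "inherited", "expanded_de_novo", "unresolved".
#' @export
tr_allele_compare <- function(child_al, parental_al, tol_bp = 10,
                              tol_frac = 0.1) {
  if (!length(parental_al) || all(is.na(parental_al))) return("unresolved")
  tol <- max(tol_bp, tol_frac * child_al)
  if (any(abs(parental_al - child_al) <= tol, na.rm = TRUE)) return("inherited")
  if (child_al > max(parental_al, na.rm = TRUE) + tol) return("expanded_de_novo")
  "unresolved"
}

#' Stepwise transmission curation of rare SVs
#'
#' For each rare (SV, child) pair: a Mendelian-consistent genotype is a
#' high-confidence transmission. Otherwise the chain applies, in order:
#' (1) relaxed rematch against parental raw callsets; (2) callable-region
#' score per parent at threshold 0.5; (3) parental genotyper support;
#' (4) tandem-repeat allele-length comparison (TR-flagged loci only);
#' (5) parental read support — >= 3 reads is a moderate transmission, 1-2
#' reads low confidence, 0 reads in both parents leaves the SV with no
#' parental support anywhere, hence de novo. Steps 1-4 resolve to status
#' "moderate"; `decided_by` records the first resolving step. The read count
#' used by steps 2 and 5 is the per-parent value from `bundle$read_support`
#' (a pair absent from the table counts as 0 reads).
#'
#' @param matrix cohort `sv_matrix`.
#' @param pedigree pedigree data.frame.
#' @param rare data.frame (locus_id, child) of rare SV assignments.
#' @param bundle list of evidence: `raw_calls` (sv_calls with `sample` for
#'   parental raw callsets), `read_support` (sv_id, sample, n_reads,
#'   mean_mapq, frac_clipped), optional `genotyper` (sv_id, sample, gt),
#'   optional `tr` (sv_id, sample, allele_len), optional `tr_flag`
#'   (character vector of TR-overlapping locus ids), `weights`, `threshold`,
#'   `tol_bp`, `tol_frac`.
#' @param params [merge_params()].
#' @param genome [sv_genome()].
#' @return data.frame of verdicts: locus_id, child, status
#'   (high_confidence / moderate / low_confidence / de_novo / unresolved),
#'   decided_by, origin, evidence.
#' @export
curate <- function(matrix, pedigree, rare, bundle = list(),
                   params = merge_params(), genome = default_genome()) {
  weights <- bundle$weights %||% c(w0 = -2, w1 = 1.5, w2 = 1, w3 = 2)
  threshold <- bundle$threshold %||% 0.5
  tol_bp <- bundle$tol_bp %||% 10
  tol_frac <- bundle$tol_frac %||% 0.1
  out <- vector("list", nrow(rare))
  for (i in seq_len(nrow(rare))) {
    child <- rare$child[i]
    li <- match(rare$locus_id[i], matrix$loci$id)
    locus <- matrix$loci[li, , drop = FALSE]
    fam <- pedigree$family[pedigree$sample == child]
    fa <- pedigree$sample[pedigree$family == fam & pedigree$role == "father"]
    mo <- pedigree$sample[pedigree$family == fam & pedigree$role == "mother"]
    sex <- pedigree$sex[pedigree$sample == child]
    verdict <- curate_one(matrix, locus, li, child, fa, mo, sex, bundle,
                          params, genome, weights, threshold, tol_bp, tol_frac)
    out[[i]] <- data.frame(locus_id = rare$locus_id[i], child = child,
                           status = verdict$status,
                           decided_by = verdict$decided_by,
                           origin = verdict$origin,
                           evidence = verdict$evidence,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

curate_one <- function(matrix, locus, li, child, fa, mo, sex, bundle,
                       params, genome, weights, threshold, tol_bp, tol_frac) {
  mc <- mendelian_check(matrix$gt[li, child], matrix$gt[li, fa],
                        matrix$gt[li, mo], locus$chrom, locus$pos, sex, genome)
  if (mc == "consistent")
    return(list(status = "high_confidence", decided_by = "mendelian",
                origin = parental_origin(matrix, li, fa, mo),
                evidence = "mendelian_consistent"))

  # step 1: relaxed rematch against parental raw callsets
  raw <- bundle$raw_calls
  if (!is.null(raw) && nrow(raw)) {
    rr <- relaxed_rematch(locus, list(
      father = raw[raw$sample == fa, , drop = FALSE],
      mother = raw[raw$sample == mo, , drop = FALSE]), params)
    if (rr$found)
      return(list(status = "moderate", decided_by = "relaxed_rematch",
                  origin = side_label(rr$parent),
                  evidence = sprintf("size_sim=%.3f", rr$similarity)))
  }

  # step 2: callable-region score per parent
  rs <- support_rows(bundle$read_support, locus$id, c(fa, mo))
  scores <- vapply(seq_len(nrow(rs)), function(k)
    callable_score(rs$n_reads[k], rs$mean_mapq[k], rs$frac_clipped[k],
                   weights, threshold)$score, numeric(1))
  if (length(scores) && any(scores >= threshold)) {
    k <- which.max(scores)
    return(list(status = "moderate", decided_by = "callable_score",
                origin = side_label(if (rs$sample[k] == fa) "father" else "mother"),
                evidence = sprintf("score=%.3f", scores[k])))
  }

  # step 3: genotyper support
  gs <- genotyper_support(locus$id, bundle$genotyper, fa, mo)
  if (gs$found)
    return(list(status = "moderate", decided_by = "genotyper",
                origin = side_label(gs$parent), evidence = "genotyper_alt"))

  # step 4: TR allele-length comparison (flagged loci only)
  tr_flag <- bundle$tr_flag
  if (!is.null(bundle$tr) && locus$id %in% (tr_flag %||% bundle$tr$sv_id)) {
    ca <- bundle$tr[bundle$tr$sv_id == locus$id & bundle$tr$sample == child, ]
    pa <- bundle$tr[bundle$tr$sv_id == locus$id &
                      bundle$tr$sample %in% c(fa, mo), ]
    if (nrow(ca)) {
      tr_res <- tr_allele_compare(ca$allele_len[1], pa$allele_len,
                                  tol_bp, tol_frac)
      if (tr_res == "inherited")
        return(list(status = "moderate", decided_by = "tr_allele",
                    origin = "unknown",
                    evidence = sprintf("child_al=%d", ca$allele_len[1])))
    }
  }

  # step 5: read support tier
  n_max <- if (nrow(rs)) max(rs$n_reads) else 0L
  tier <- read_support_tier(n_max)
  if (tier == "moderate")
    return(list(status = "moderate", decided_by = "read_support",
                origin = "unknown", evidence = sprintf("n_reads=%d", n_max)))
  if (tier == "low")
    return(list(status = "low_confidence", decided_by = "read_support",
                origin = "unknown", evidence = sprintf("n_reads=%d", n_max)))
  list(status = "de_novo", decided_by = "read_support", origin = "none",
       evidence = "no_parental_support")
}

support_rows <- function(read_support, sv_id, parents) {
  if (is.null(read_support))
    return(data.frame(sample = parents, n_reads = 0L, mean_mapq = 0,
                      frac_clipped = 0))
  rows <- read_support[read_support$sv_id == sv_id &
                         read_support$sample %in% parents, , drop = FALSE]
  missing <- setdiff(parents, rows$sample)
  if (length(missing))
    rows <- rbind(rows[, c("sample", "n_reads", "mean_mapq", "frac_clipped")],
                  data.frame(sample = missing, n_reads = 0L, mean_mapq = 0,
                             frac_clipped = 0))
  rows
}

side_label <- function(parent) {
  if (is.na(parent)) return("unknown")
  if (parent == "father") "paternal" else "maternal"
}

parental_origin <- function(matrix, li, fa, mo) {
  fd <- gt_dosage(matrix$gt[li, fa])
  md <- gt_dosage(matrix$gt[li, mo])
  fc <- isTRUE(fd >= 1); mc <- isTRUE(md >= 1)
  if (fc && mc) "both" else if (fc) "paternal" else if (mc) "maternal" else "none"
}
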