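#' Decide whether two SV calls represent the same allele
#'
#' Two calls match when all of the following hold: same `svtype`; breakpoint
#' distance `|pos_a - pos_b| <= refdist`; reciprocal size similarity
#' `min(svlen)/max(svlen) >= pctsize`; and, when both calls carry an allele
#' sequence, sequence similarity `1 - edit_distance / max(len) >= pctseq`
#' (Levenshtein distance). When either sequence is absent the sequence test
#' is skipped — DEL records frequently omit the deleted sequence. The
#' predicate is symmetric.
#'
#' @param a,b single-row [sv_calls()] records (or lists with the same fields)
#'   on the same chromosome.
#' @param params [merge_params()].
#' @return list with `matched`, `breakpoint_distance`, `size_similarity`,
#'   `seq_similarity` (NA when not computed).
#' @export
sv_match <- function(a, b, params = merge_params()) {
  if (a$chrom != b$chrom)
    stop("sv_match compares calls on one chromosome; bucket by chromosome first")
  dist <- abs(a$pos - b$pos)
  size_sim <- min(a$svlen, b$svlen) / max(a$svlen, b$svlen)
  seq_sim <- NA_real_
  matched <- a$svtype == b$svtype && dist <= params$refdist &&
    size_sim >= params$pctsize
  if (matched && !is.na(a$seq) && !is.na(b$seq) && params$pctseq > 0) {
    seq_sim <- seq_similarity(a$seq, b$seq)
    matched <- seq_sim >= params$pctseq
  }
  list(matched = matched, breakpoint_distance = dist,
       size_similarity = size_sim, seq_similarity = seq_sim)
}

#' Sequence similarity of two allele sequences
#'
#' `1 - levenshtein(a, b) / max(nchar(a), nchar(b))`, the edit-distance
#' similarity normalised by the longer sequence.
#'
#' @param a,b nucleotide strings.
#' @return real in \[0, 1\].
#' @export
seq_similarity <- function(a, b) {
  if (identical(a, b)) return(1)
  1 - as.numeric(utils::adist(a, b)) / max(nchar(a), nchar(b))
}

# Threshold test `seq_similarity(a, b) >= pctseq` with cheap bounds before the
# exact DP distance: |len(a) - len(b)| lower-bounds the edit distance, and for
# equal-length sequences the Hamming distance upper-bounds it.
seq_passes <- function(a, b, pctseq) {
  if (identical(a, b)) return(TRUE)
  la <- nchar(a); lb <- nchar(b)
  mx <- max(la, lb)
  budget <- (1 - pctseq) * mx
  if (abs(la - lb) > budget) return(FALSE)
  if (la == lb) {
    hamming <- sum(charToRaw(a) != charToRaw(b))
    if (hamming <= budget) return(TRUE)
  }
  seq_similarity(a, b) >= pctseq
}

# Vectorised match of one call against a candidate table (same chromosome).
# Returns a logical vector over rows of cand.
match_against <- function(call, cand, params) {
  if (nrow(cand) == 0) return(logical(0))
  ok <- cand$svtype == call$svtype &
    abs(cand$pos - call$pos) <= params$refdist &
    (pmin(cand$svlen, call$svlen) / pmax(cand$svlen, call$svlen)) >= params$pctsize
  if (params$pctseq > 0 && !is.na(call$seq) && any(ok)) {
    idx <- which(ok & !is.na(cand$seq))
    for (j in idx) {
      if (!seq_passes(call$seq, cand$seq[j], params$pctseq)) ok[j] <- FALSE
    }
  }
  ok
}

#' Validate assembly-based calls against alignment-based callsets
#'
#' A call from the assembly-based caller is kept when it matches at least one
#' call in at least one alignment-based callset from the same sample; output
#' records keep the assembly coordinates (the assembly callset is the merge
#' base). Caller provenance is recorded in the `callers` column.
#'
#' @param assembly_calls [sv_calls()] from the assembly caller, one sample.
#' @param aligner_callsets list of `sv_calls` tables from alignment-based
#'   callers (names become caller labels).
#' @param params [merge_params()].
#' @return list with `validated` and `rejected` `sv_calls` tables.
#' @export
validate_callerset <- function(assembly_calls, aligner_callsets,
                               params = merge_params()) {
  if (nrow(assembly_calls) == 0)
    return(list(validated = assembly_calls, rejected = assembly_calls))
  if (is.null(names(aligner_callsets)))
    names(aligner_callsets) <- paste0("aligner_", seq_along(aligner_callsets))
  supported <- matrix(FALSE, nrow(assembly_calls), length(aligner_callsets))
  for (k in seq_along(aligner_callsets)) {
    al <- aligner_callsets[[k]]
    for (i in seq_len(nrow(assembly_calls))) {
      cand <- al[al$chrom == assembly_calls$chrom[i], , drop = FALSE]
      supported[i, k] <- any(match_against(assembly_calls[i, ], cand, params))
    }
  }
  keep <- rowSums(supported) > 0
  validated <- assembly_calls[keep, , drop = FALSE]
  if (nrow(validated)) {
    extra <- apply(supported[keep, , drop = FALSE], 1, function(s)
      paste(names(aligner_callsets)[s], collapse = ","))
    validated$callers <- ifelse(nzchar(validated$callers),
                                paste(validated$callers, extra, sep = ","),
                                paste("assembly", extra, sep = ","))
  }
  rejected <- assembly_calls[!keep, , drop = FALSE]
  rownames(validated) <- rownames(rejected) <- NULL
  list(validated = validated, rejected = rejected)
}

#' Collapse calls into a nonredundant genotype matrix
#'
#' Greedy single-linkage clustering in (chrom, pos) sort order: each call
#' joins the first existing cluster whose founding call it matches under
#' [sv_match()]; otherwise it founds a new cluster. The output representative
#' of each cluster is chosen by `params$keep_rule`: `"maxqual"` takes the
#' highest-quality member (ties: leftmost pos, then lexicographic id);
#' `"common"` the member carried by the most samples (ties: highest quality).
#' Genotypes of collapsed members transfer to the representative locus per
#' sample; a sample contributing two distinct member calls to one cluster
#' becomes homozygous alt (hemizygous loci stay `"1"`).
#'
#' @param calls [sv_calls()] with `sample` and `gt` filled, sorted by
#'   (chrom, pos).
#' @param params [merge_params()].
#' @param samples optional sample ordering for the genotype matrix columns.
#' @param meta optional data.frame (sample, sex) enabling sex-aware reference
#'   genotypes on chrX/chrY for non-carriers.
#' @param genome [sv_genome()] used with `meta`.
#' @return object of class `sv_matrix`: list with `loci` (representative
#'   `sv_calls`), `gt` (loci x samples character matrix), `samples`,
#'   `provenance` (locus_id, sample, member_id), `params`.
#' @export
collapse <- function(calls, params = merge_params(), samples = NULL,
                     meta = NULL, genome = default_genome()) {
  if (nrow(calls)) {
    o <- order(calls$chrom, calls$pos)
    if (!identical(o, seq_len(nrow(calls))))
      stop("calls must be sorted by (chrom, pos)")
  }
  if (is.null(samples)) {
    samples <- sort(unique(calls$sample[!is.na(calls$sample)]))
    if (!length(samples)) samples <- "sample1"
  }
  cluster <- integer(nrow(calls))
  n_clust <- 0L
  for (chrom in unique(calls$chrom)) {
    idx <- which(calls$chrom == chrom)
    rep_pos <- numeric(0)   # founder positions on this chromosome
    rep_row <- integer(0)   # founder row in `calls`
    rep_cl <- integer(0)    # founder cluster id
    for (i in idx) {
      cand <- which(abs(rep_pos - calls$pos[i]) <= params$refdist)
      hit <- 0L
      for (j in cand) {      # founding order = first-match order
        if (match_against(calls[i, ], calls[rep_row[j], , drop = FALSE], params)) {
          hit <- j
          break
        }
      }
      if (hit > 0L) {
        cluster[i] <- rep_cl[hit]
      } else {
        n_clust <- n_clust + 1L
        cluster[i] <- n_clust
        rep_pos <- c(rep_pos, calls$pos[i])
        rep_row <- c(rep_row, i)
        rep_cl <- c(rep_cl, n_clust)
      }
    }
  }
  build_matrix(calls, cluster, params, samples, meta, genome)
}

build_matrix <- function(calls, cluster, params, samples, meta, genome) {
  n_clust <- if (length(cluster)) max(cluster) else 0L
  loci_rows <- integer(n_clust)
  prov <- vector("list", n_clust)
  gt <- matrix("0/0", nrow = n_clust, ncol = length(samples),
               dimnames = list(NULL, samples))
  for (cl in seq_len(n_clust)) {
    members <- which(cluster == cl)
    m <- calls[members, , drop = FALSE]
    rep_i <- if (params$keep_rule == "common") {
      # member whose exact (pos, svlen) representation is carried by the most
      # samples; ties broken by quality, then leftmost pos, then id
      key <- paste(m$pos, m$svlen)
      ns <- vapply(seq_len(nrow(m)), function(k)
        length(unique(m$sample[key == key[k]])), integer(1))
      order(-ns, -m$qual, m$pos, m$id)[1]
    } else {
      order(-m$qual, m$pos, m$id)[1]
    }
    loci_rows[cl] <- members[rep_i]
    prov[[cl]] <- data.frame(locus_id = m$id[rep_i], sample = m$sample,
                             member_id = m$id, stringsAsFactors = FALSE)
    for (s in unique(m$sample[!is.na(m$sample)])) {
      ms <- m[!is.na(m$sample) & m$sample == s, , drop = FALSE]
      g <- if (nrow(ms) >= 2) {
        if (any(gt_ploidy(ms$gt) == 1)) "1" else "1/1"
      } else ms$gt[1]
      if (is.na(g) || !nzchar(g)) g <- "0/1"
      gt[cl, s] <- g
    }
  }
  loci <- calls[loci_rows, , drop = FALSE]
  loci$sample <- NULL
  loci$gt <- NULL
  # sex-aware reference genotypes for non-carriers
  if (!is.null(meta) && n_clust) {
    for (s in samples) {
      sex <- meta$sex[match(s, meta$sample)]
      if (is.na(sex)) next
      hemi <- is_hemi_locus(loci$chrom, loci$pos, sex, genome)
      refg <- gt[, s] == "0/0"
      gt[hemi & refg, s] <- "0"
      if (sex == "female") gt[loci$chrom == "chrY", s] <- "."
    }
  }
  o <- order(loci$chrom, loci$pos)
  structure(list(loci = sv_calls(loci[o, , drop = FALSE], validate = FALSE),
                 gt = gt[o, , drop = FALSE],
                 samples = samples,
                 provenance = do.call(rbind, prov),
                 params = params),
            class = "sv_matrix")
}

#' @export
print.sv_matrix <- function(x, ...) {
  cat("sv_matrix:", nrow(x$loci), "nonredundant loci x", length(x$samples),
      "samples\n")
  invisible(x)
}

#' Per-trio Mendelian concordance of a genotype matrix
#'
#' For each child with both parents genotyped in the matrix, the fraction of
#' child-carried loci (alt dosage >= 1) whose genotype is producible from the
#' parental genotypes under sex-aware Mendelian rules. Loci where a required
#' parental genotype is missing are excluded from the denominator.
#'
#' @param matrix an [collapse()] result.
#' @param pedigree pedigree data.frame (see [read_pedigree()]).
#' @param genome [sv_genome()].
#' @return list with `per_trio` data.frame (child, n_carried, n_checked,
#'   concordance) and `mean_rate`.
#' @export
mendelian_concordance <- function(matrix, pedigree, genome = default_genome()) {
  kids <- pedigree[pedigree$role %in% c("proband", "sibling"), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(kids))) {
    child <- kids$sample[i]
    fam <- pedigree[pedigree$family == kids$family[i], , drop = FALSE]
    fa <- fam$sample[fam$role == "father"]
    mo <- fam$sample[fam$role == "mother"]
    if (!length(fa) || !length(mo) ||
        !all(c(child, fa, mo) %in% matrix$samples)) {
      warning("child ", child, " lacks genotyped parents; trio skipped")
      next
    }
    cg <- matrix$gt[, child]
    carried <- !is.na(gt_dosage(cg)) & gt_dosage(cg) >= 1
    if (!any(carried)) {
      rows[[child]] <- data.frame(child = child, n_carried = 0L,
                                  n_checked = 0L, concordance = NA_real_)
      next
    }
    verdict <- mendelian_check(cg[carried], matrix$gt[carried, fa],
                               matrix$gt[carried, mo],
                               matrix$loci$chrom[carried],
                               matrix$loci$pos[carried],
                               kids$sex[i], genome)
    checked <- verdict != "unknown"
    rows[[child]] <- data.frame(
      child = child, n_carried = sum(carried), n_checked = sum(checked),
      concordance = if (any(checked)) mean(verdict[checked] == "consistent")
                    else NA_real_)
  }
  per_trio <- do.call(rbind, rows)
  rownames(per_trio) <- NULL
  list(per_trio = per_trio,
       mean_rate = mean(per_trio$concordance, na.rm = TRUE))
}
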