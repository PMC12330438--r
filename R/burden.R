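#' Tabulate rare-SV burden per child and stratum
#'
#' Counts each rare (SV, child) pair once per combination of genotype
#' category, transmission class, functional primary class/flags, and parental
#' origin. Children are annotated with affected status and sex so strata can
#' be compared proband-versus-sibling (and, on chrX, per sex).
#'
#' @param rare_table data.frame with one row per rare (SV, child):
#'   `locus_id`, `child`, `category`, `class`, `origin` (extra columns are
#'   kept as strata).
#' @param labels optional [annotate_sv()] output merged in by `locus_id`.
#' @param pedigree pedigree data.frame.
#' @return data.frame of class `burden_table`: child, affected, sex, one
#'   column per stratum, `n`.
#' @export
count_burden <- function(rare_table, labels = NULL, pedigree) {
  if (!is.null(labels))
    rare_table <- merge(rare_table, labels, by = "locus_id", all.x = TRUE,
                        sort = FALSE)
  strata <- setdiff(names(rare_table), c("locus_id", "child", "genes"))
  if (nrow(rare_table) == 0) {
    out <- data.frame(child = character(), affected = logical(),
                      sex = character(), n = integer())
    class(out) <- c("burden_table", "data.frame")
    return(out)
  }
  agg <- stats::aggregate(list(n = rare_table$locus_id),
                          rare_table[, c("child", strata), drop = FALSE],
                          FUN = length)
  agg$affected <- as.logical(pedigree$affected[match(agg$child, pedigree$sample)])
  agg$sex <- pedigree$sex[match(agg$child, pedigree$sample)]
  agg <- agg[, c("child", "affected", "sex", strata, "n")]
  class(agg) <- c("burden_table", "data.frame")
  agg
}

#' Rate-ratio chi-square test on event counts per group
#'
#' Compares per-individual event rates between two groups (e.g. k1 de novo
#' SVs among n1 probands versus k2 among n2 siblings). The reported
#' `rate_ratio` is `(k1/n1)/(k2/n2)` — the per-individual rate ratio, which
#' is what the headline "OR" of this analysis corresponds to; the classical
#' 2x2 odds ratio is also returned as `odds_ratio`. The chi-square statistic
#' is computed on the 2x2 table `(k1, n1-k1; k2, n2-k2)` with Yates
#' continuity correction, so `k` must not exceed `n`.
#'
#' @param k1,n1 event count and group size for group 1.
#' @param k2,n2 event count and group size for group 2.
#' @return list: rate_ratio, odds_ratio, chi2, p, infinite_ratio flag.
#' @export
chisq_rate_test <- function(k1, n1, k2, n2) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k2 >= 0)
  if (k1 > n1 || k2 > n2)
    stop("chisq_rate_test requires k <= n (at most one event per individual); ",
         "use mwu_counts for per-child count comparisons")
  infinite <- k2 == 0
  rate_ratio <- if (infinite) Inf else (k1 / n1) / (k2 / n2)
  odds_ratio <- if (k2 == 0 || n1 == k1) NA_real_ else
    (k1 * (n2 - k2)) / ((n1 - k1) * k2)
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  list(rate_ratio = rate_ratio, odds_ratio = odds_ratio,
       chi2 = unname(ct$statistic), p = unname(ct$p.value),
       infinite_ratio = infinite)
}

#' Mann-Whitney U test on per-child counts
#'
#' Two-sided test using the normal approximation with tie-corrected variance
#' and no continuity correction. The sign convention is probands minus
#' siblings: Z > 0 means the first group's counts rank higher.
#'
#' @param x per-child counts, group 1 (probands).
#' @param y per-child counts, group 2 (siblings).
#' @return list: U (group-1 statistic), Z, p.
#' @export
mwu_counts <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 > 0, n2 > 0)
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  nn <- n1 + n2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
  if (sigma2 <= 0) return(list(U = u1, Z = 0, p = 1))
  z <- (u1 - mu) / sqrt(sigma2)
  list(U = u1, Z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)` across the family of strata tested in one run.
#'
#' @param p numeric vector of nominal p values.
#' @param m family size (defaults to `length(p)`).
#' @return adjusted p values.
#' @export
bonferroni <- function(p, m = length(p)) {
  pmin(1, stats::p.adjust(p, method = "bonferroni", n = m))
}

#' Cumulative SV discovery curve and rare-pool shrinkage
#'
#' For k = 1..N control samples (in `sample_order`), counts the nonredundant
#' loci carried by at least one of the first k samples. Optionally, given
#' per-child locus tables, also reports each child's rare-SV count after
#' filtering against the first k controls (sex-matched on chrX/chrY) — the
#' shrinkage curve of the rare pool as the panel grows. Both curves follow
#' directly from per-locus first-carrier indices, so the rare counts are
#' monotone non-increasing in k.
#'
#' @param control_matrix control `sv_matrix`.
#' @param sample_order order in which controls are added (default: matrix
#'   column order).
#' @param control_meta data.frame (sample, sex); needed for sex-matched
#'   child filtering.
#' @param child_loci optional named list of [sv_calls()] per child.
#' @param child_sex named character vector of child sexes.
#' @param params [merge_params()].
#' @param strata optional named list of sample subsets; a discovery curve is
#'   computed within each subset (in `sample_order` order).
#' @return list: `curve` (k, n_loci), `rare` (k, child, n_rare) or NULL,
#'   `strata` (named list of per-stratum curves) or NULL.
#' @export
discovery_curve <- function(control_matrix, sample_order = NULL,
                            control_meta = NULL, child_loci = NULL,
                            child_sex = NULL, params = merge_params(),
                            strata = NULL) {
  if (is.null(sample_order)) sample_order <- control_matrix$samples
  stopifnot(all(sample_order %in% control_matrix$samples))
  gt <- control_matrix$gt[, sample_order, drop = FALSE]
  dos <- gt_apply(gt, gt_dosage)
  carried <- !is.na(dos) & dos >= 1

  first_idx <- function(cols) {
    # per locus: index (within sample_order) of first carrier among `cols`
    apply(carried[, cols, drop = FALSE], 1, function(v) {
      w <- which(v)
      if (length(w)) w[1] else Inf
    })
  }
  n <- length(sample_order)
  fc_any <- first_idx(seq_len(n))
  curve <- data.frame(k = seq_len(n),
                      n_loci = vapply(seq_len(n), function(k)
                        sum(fc_any <= k), integer(1)))

  strata_curves <- NULL
  if (!is.null(strata)) {
    strata_curves <- lapply(strata, function(ss) {
      cols <- which(sample_order %in% ss)
      fc <- first_idx(cols)
      data.frame(k = seq_along(cols),
                 n_loci = vapply(seq_along(cols), function(k)
                   sum(fc <= k), integer(1)))
    })
  }

  rare <- NULL
  if (!is.null(child_loci)) {
    sex_of <- if (!is.null(control_meta))
      control_meta$sex[match(sample_order, control_meta$sample)] else
        rep(NA_character_, n)
    # per control locus: first carrier index overall / among each sex
    fc_sex <- list(male = first_idx(which(sex_of == "male")),
                   female = first_idx(which(sex_of == "female")))
    # map per-sex positions back to global k
    for (s in c("male", "female")) {
      pos <- which(sex_of == s)
      fc_sex[[s]] <- ifelse(is.finite(fc_sex[[s]]), pos[fc_sex[[s]]], Inf)
    }
    cl <- control_matrix$loci
    rows <- list()
    for (child in names(child_loci)) {
      loci <- child_loci[[child]]
      csex <- if (!is.null(child_sex)) child_sex[[child]] else NA_character_
      # earliest k at which each child locus is matched by a carried control
      kill_k <- vapply(seq_len(nrow(loci)), function(i) {
        sexchrom <- loci$chrom[i] %in% c("chrX", "chrY")
        fc <- if (sexchrom && !is.na(csex)) fc_sex[[csex]] else fc_any
        cand <- which(cl$chrom == loci$chrom[i] & is.finite(fc) &
                        abs(cl$pos - loci$pos[i]) <= params$refdist)
        hit <- cand[match_against(loci[i, ], cl[cand, , drop = FALSE], params)]
        if (length(hit)) min(fc[hit]) else Inf
      }, numeric(1))
      rows[[child]] <- data.frame(k = seq_len(n), child = child,
                                  n_rare = vapply(seq_len(n), function(k)
                                    sum(kill_k > k), integer(1)))
    }
    rare <- do.call(rbind, rows)
    rownames(rare) <- NULL
  }
  list(curve = curve, rare = rare, strata = strata_curves)
}
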