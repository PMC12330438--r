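# Independent brute-force oracles used to verify the package's fast paths.
# Everything here is written from first principles (dynamic programming,
# quadratic scans, exhaustive enumeration) and must stay independent of the
# implementation code paths it checks.

# Levenshtein distance by full dynamic programming. The row update is
# vectorised: deletions/substitutions first, then the left-to-right insertion
# chain via the standard cummin identity
#   cur[j] = min_{k <= j} (cand[k] + (j - k))  with cand[0] = i.
oracle_edit_distance <- function(a, b) {
  x <- utf8ToInt(a); y <- utf8ToInt(b)
  n <- length(x); m <- length(y)
  if (m == 0) return(n)
  prev <- 0:m
  j <- seq_len(m)
  for (i in seq_len(n)) {
    cost <- as.integer(x[i] != y)
    cand <- pmin(prev[-1] + 1L, prev[-(m + 1)] + cost)
    run <- cummin(c(i, cand - j))
    prev <- c(i, run[-1] + j)
  }
  prev[m + 1]
}

# Pairwise SV match predicate, recomputed from the stated rule.
oracle_match <- function(a, b, params) {
  if (a$chrom != b$chrom) return(FALSE)
  if (a$svtype != b$svtype) return(FALSE)
  if (abs(a$pos - b$pos) > params$refdist) return(FALSE)
  if (min(a$svlen, b$svlen) / max(a$svlen, b$svlen) < params$pctsize)
    return(FALSE)
  if (params$pctseq > 0 && !is.na(a$seq) && !is.na(b$seq)) {
    sim <- 1 - oracle_edit_distance(a$seq, b$seq) / max(nchar(a$seq),
                                                        nchar(b$seq))
    if (sim < params$pctseq) return(FALSE)
  }
  TRUE
}

# Transitive closure of the pairwise match relation: connected components.
oracle_cluster_count <- function(calls, params) {
  n <- nrow(calls)
  if (n == 0) return(0L)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (calls$chrom[i] != calls$chrom[j]) next
      if (oracle_match(calls[i, ], calls[j, ], params)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# Quadratic per-pair interval overlap scan (0-based half-open intervals).
oracle_mask_overlap <- function(calls, mask) {
  keep <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    s <- calls$pos[i] - 1
    e <- if (calls$svtype[i] == "DEL") calls$end[i] else calls$pos[i]
    hit <- FALSE
    for (j in seq_len(nrow(mask))) {
      if (calls$chrom[i] != mask$chrom[j]) next
      if (s < mask$end[j] && mask$start[j] < e) { hit <- TRUE; break }
    }
    keep[i] <- !hit
  }
  keep
}

# Yates-corrected chi-square on a 2x2 table, textbook formula with the
# standard cap so the corrected deviation never goes negative.
oracle_chisq_yates <- function(k1, n1, k2, n2) {
  o <- c(k1, n1 - k1, k2, n2 - k2)
  nn <- sum(o)
  rs <- c(k1 + n1 - k1, k2 + n2 - k2)
  cs <- c(k1 + k2, (n1 - k1) + (n2 - k2))
  e <- outer(rs, cs) / nn
  om <- matrix(o, 2, byrow = TRUE)
  dev <- pmax(0, abs(om - e) - 0.5)
  stat <- sum(dev^2 / e)
  list(chi2 = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

# Exact distribution of the Mann-Whitney U statistic by enumeration of all
# group-1 index subsets (feasible for n1 + n2 <= 12 or so).
oracle_mwu_exact_u <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  all_idx <- utils::combn(n1 + n2, n1)
  us <- apply(all_idx, 2, function(id) sum(r[id]) - n1 * (n1 + 1) / 2)
  obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  list(obs = obs, dist = us, max = max(us))
}

# Per-base window coverage recomputation.
oracle_window_coverage <- function(paf, chrom, chrom_length, window,
                                   min_frac, max_contigs, mask = NULL) {
  paf <- paf[paf$tname == chrom, , drop = FALSE]
  covered <- rep(FALSE, chrom_length)
  by_contig <- list()
  for (i in seq_len(nrow(paf))) {
    span <- (paf$tstart[i] + 1):paf$tend[i]
    covered[span] <- TRUE
    q <- paf$qname[i]
    by_contig[[q]] <- union(by_contig[[q]], span)
  }
  masked_base <- rep(FALSE, chrom_length)
  if (!is.null(mask)) {
    m <- mask[mask$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(m)))
      if (m$end[i] > m$start[i])
        masked_base[(m$start[i] + 1):m$end[i]] <- TRUE
  }
  starts <- seq(0, chrom_length - 1, by = window)
  qualified <- masked <- logical(length(starts))
  for (w in seq_along(starts)) {
    span <- (starts[w] + 1):min(starts[w] + window, chrom_length)
    un <- span[!masked_base[span]]
    if (!length(un)) { masked[w] <- TRUE; next }
    frac <- mean(covered[un])
    nc <- sum(vapply(by_contig, function(s) any(s %in% un), logical(1)))
    qualified[w] <- frac >= min_frac && nc <= max_contigs
  }
  list(qualified = qualified, masked = masked,
       percent = 100 * sum(qualified) / sum(!masked))
}

# Exact expectation of the observed concordance for one trio at autosomal
# HWE loci with allele frequency p and the het<->hom swap channel at rate e.
expected_concordance_enum <- function(afs, e) {
  gts <- 0:2   # dosage
  hwe <- function(p) c((1 - p)^2, 2 * p * (1 - p), p^2)
  # transmission: P(child dosage | fa, mo)
  trans <- function(f, m) {
    pf <- c(0, 0.5, 1)[f + 1]   # P(transmit alt)
    pm <- c(0, 0.5, 1)[m + 1]
    c((1 - pf) * (1 - pm), pf * (1 - pm) + (1 - pf) * pm, pf * pm)
  }
  err <- function(d) {
    # returns matrix: P(observed dosage | true dosage d)
    if (d == 0) c(1, 0, 0)
    else if (d == 1) c(0, 1 - e, e)
    else c(0, e, 1 - e)
  }
  consistent <- function(c_, f_, m_) {
    # child dosage c_ producible from parents with dosages f_, m_
    fa_all <- list(`0` = 0, `1` = 0:1, `2` = 1)[[as.character(f_)]]
    mo_all <- list(`0` = 0, `1` = 0:1, `2` = 1)[[as.character(m_)]]
    any(outer(fa_all, mo_all, "+") == c_)
  }
  num <- den <- 0
  for (p in afs) {
    hf <- hwe(p)
    for (f in gts) for (m in gts) {
      pt <- trans(f, m)
      for (ct in gts) {
        base <- hf[f + 1] * hf[m + 1] * pt[ct + 1]
        if (base == 0) next
        for (co in gts) for (fo in gts) for (mo in gts) {
          pr <- base * err(ct)[co + 1] * err(f)[fo + 1] * err(m)[mo + 1]
          if (pr == 0 || co == 0) next   # only carried child loci counted
          den <- den + pr
          if (consistent(co, fo, mo)) num <- num + pr
        }
      }
    }
  }
  num / den
}
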