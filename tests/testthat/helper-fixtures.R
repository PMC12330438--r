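# Small in-code fixtures shared across test files.

mk_call <- function(chrom = "chr1", pos = 10000, svtype = "DEL", svlen = 100,
                    seq = NA_character_, qual = 50, id = "c1", sample = "s1",
                    gt = "0/1") {
  sv_calls(data.frame(id = id, sample = sample, chrom = chrom, pos = pos,
                      svtype = svtype, svlen = svlen, seq = seq, qual = qual,
                      gt = gt, stringsAsFactors = FALSE))
}

mk_trio_ped <- function(fam = "fam01", child_sex = "male") {
  data.frame(
    sample = paste0(fam, c("_fa", "_mo", "_p1")),
    family = fam,
    role = c("father", "mother", "proband"),
    sex = c("male", "female", child_sex),
    affected = c(FALSE, FALSE, TRUE),
    superpop = "non-AFR",
    stringsAsFactors = FALSE)
}

# A tiny genotype matrix for three samples (trio) at the given loci.
mk_matrix <- function(loci, gt, samples) {
  structure(list(loci = loci, gt = gt, samples = samples),
            class = "sv_matrix")
}

random_calls <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e6,
                         with_seq = FALSE) {
  svtype <- sample(c("DEL", "INS"), n, replace = TRUE)
  svlen <- sample(50:2000, n, replace = TRUE)
  seqs <- rep(NA_character_, n)
  if (with_seq) {
    for (i in which(svtype == "INS"))
      seqs[i] <- paste(sample(c("A", "C", "G", "T"), svlen[i],
                              replace = TRUE), collapse = "")
  }
  df <- data.frame(id = sprintf("r%04d", seq_len(n)),
                   sample = sample(paste0("s", 1:4), n, replace = TRUE),
                   chrom = sample(chroms, n, replace = TRUE),
                   pos = sample(1000:max_pos, n, replace = TRUE),
                   svtype = svtype, svlen = svlen, seq = seqs,
                   qual = round(runif(n, 1, 60), 1), gt = "0/1",
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos), ]
  rownames(df) <- NULL
  sv_calls(df)
}

# Jittered copies of well-separated true loci: constructed so that members of
# one locus always match each other pairwise and members of different loci
# never match -> greedy clustering is order-independent and must equal the
# transitive closure.
planted_cluster_calls <- function(n_true = 10, copies_range = 2:6,
                                  refdist = 500) {
  jmax <- floor((refdist - 1) / 2)
  rows <- list()
  for (t in seq_len(n_true)) {
    base_pos <- 10000 + t * 5000
    svlen <- sample(100:900, 1)
    k <- sample(copies_range, 1)
    rows[[t]] <- data.frame(
      id = sprintf("t%02d_%02d", t, seq_len(k)),
      sample = paste0("s", seq_len(k)),
      chrom = "chr1",
      pos = base_pos + sample(-jmax:jmax, k, replace = TRUE),
      svtype = "DEL",
      svlen = pmax(50, svlen + sample(-2:2, k, replace = TRUE)),
      seq = NA_character_, qual = round(runif(k, 1, 60), 1), gt = "0/1",
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$chrom, df$pos), ]
  rownames(df) <- NULL
  list(calls = sv_calls(df), n_true = n_true)
}
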