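small_cfg <- function(seed = 5, ...) {
  sim_config(seed = seed, n_controls = 30, n_common_sv = 800,
             families = list(list(type = "quad", proband_sex = "male",
                                  sibling_sex = "female"),
                             list(type = "trio", proband_sex = "female")),
             ...)
}

test_that("configuration validation rejects truth-breaking settings", {
  expect_error(sim_config(breakpoint_jitter_sd = 600), "refdist")
  expect_error(sim_config(seq_divergence = 0.2), "pctseq")
  expect_error(sim_config(genotype_error_rate = 1.5))
})

test_that("panel generation is deterministic and ledger-complete", {
  cfg <- small_cfg()
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1$matrix$gt, p2$matrix$gt)
  expect_identical(p1$ledger, p2$ledger)
  # byte-identical serialisation
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_matrix(p1$matrix, f1); write_matrix(p2$matrix, f2)
  expect_identical(readLines(f1), readLines(f2))
  # every matrix locus has exactly one ledger entry
  expect_setequal(p1$matrix$loci$id, p1$ledger$locus_id)
})

test_that("a fixed allele frequency of 1 puts the allele in every control", {
  loci <- data.frame(chrom = c("chr1", "chrX", "chrY"), pos = c(5e6, 5e6, 5e6))
  set.seed(1)
  al <- svsieve:::draw_alleles(loci, af = rep(1, 3), sexes = rep(c("male", "female"), 10),
                     superpops = rep("non-AFR", 20), afr_boost = 1.5)
  gt <- svsieve:::alleles_to_gt(al$a1, al$a2)
  dim(gt) <- dim(al$a1)
  expect_true(all(gt[1, ] == "1/1"))
  males <- rep(c(TRUE, FALSE), 10)
  expect_true(all(gt[2, males] == "1"))
  expect_true(all(gt[2, !males] == "1/1"))
  expect_true(all(gt[3, males] == "1"))
  expect_true(all(gt[3, !males] == "."))   # chrY absent in females
})

test_that("allele frequencies follow the configured Beta distribution", {
  cfg <- sim_config(seed = 9, n_controls = 5, n_common_sv = 10000,
                    af_beta = c(0.3, 2))
  p <- simulate_panel(cfg)
  ks <- suppressWarnings(stats::ks.test(p$ledger$af, stats::pbeta, 0.3, 2))
  expect_gt(ks$p.value, 0.001)
})

test_that("control genotypes satisfy Hardy-Weinberg at simulated n", {
  cfg <- sim_config(seed = 31, n_controls = 200, n_common_sv = 600,
                    afr_fraction = 0)   # single population: plain HWE
  p <- simulate_panel(cfg)
  auto <- p$matrix$loci$chrom %in% c("chr1", "chr2", "chr3")
  af <- p$ledger$af[auto]
  use <- which(auto)[af > 0.2 & af < 0.8]
  pvals <- vapply(use, function(i) {
    gt <- p$matrix$gt[i, ]
    obs <- c(sum(gt == "0/0"), sum(gt == "0/1"), sum(gt == "1/1"))
    q <- p$ledger$af[match(p$matrix$loci$id[i], p$ledger$locus_id)]
    expct <- c((1 - q)^2, 2 * q * (1 - q), q^2) * length(gt)
    suppressWarnings(stats::chisq.test(obs, p = expct / sum(expct))$p.value)
  }, numeric(1))
  # p values approximately uniform: ~5% rejections at alpha = 0.05
  expect_lt(mean(pvals < 0.05), 0.12)
  expect_gt(mean(pvals), 0.3)
})

test_that("AFR controls carry more SVs than non-AFR controls", {
  cfg <- sim_config(seed = 13, n_controls = 120, n_common_sv = 2000,
                    afr_fraction = 0.5)
  p <- simulate_panel(cfg)
  dos <- apply(p$matrix$gt, 2, function(g) sum(gt_dosage(g), na.rm = TRUE))
  afr <- p$meta$superpop == "AFR"
  expect_gt(mean(dos[afr]), mean(dos[!afr]))
})

test_that("family simulation plants the configured events and is Mendelian-clean otherwise", {
  cfg <- small_cfg(seed = 6, genotype_error_rate = 0,
                   caller_sensitivity = c(assembly = 1, aligner_a = 1,
                                          aligner_b = 1))
  panel <- simulate_panel(cfg)
  cohort <- simulate_families(cfg, panel)
  ped <- cohort$pedigree
  children <- ped$sample[ped$role %in% c("proband", "sibling")]

  planted <- cohort$ledger$loci[cohort$ledger$loci$planted, ]
  dn <- planted[planted$planted_class == "de_novo", ]
  expect_equal(as.integer(table(dn$planted_child)[children]),
               rep(cfg$n_denovo_per_child, length(children)))

  # every non-de-novo child-carried locus passes the Mendelian check
  loci <- cohort$truth$loci
  gt <- cohort$truth$gt
  for (ch in children) {
    fam <- ped$family[ped$sample == ch]
    fa <- ped$sample[ped$family == fam & ped$role == "father"]
    mo <- ped$sample[ped$family == fam & ped$role == "mother"]
    sex <- ped$sex[ped$sample == ch]
    dos <- gt_dosage(gt[, ch])
    carried <- which(!is.na(dos) & dos >= 1)
    verdict <- mendelian_check(gt[carried, ch], gt[carried, fa],
                               gt[carried, mo], loci$chrom[carried],
                               loci$pos[carried], sex)
    is_dn <- loci$id[carried] %in% dn$locus_id[dn$planted_child == ch]
    expect_true(all(verdict[is_dn] == "violation"))
    expect_true(all(verdict[!is_dn] == "consistent"))
  }

  # ledger completeness both ways at sensitivity 1
  expect_true(all(cohort$callsets$truth_id %in% cohort$ledger$loci$locus_id))
  for (ch in children) {
    dos <- gt_dosage(gt[, ch])
    carried <- loci$id[!is.na(dos) & dos >= 1]
    asm <- cohort$callsets[cohort$callsets$sample == ch &
                             cohort$callsets$caller == "assembly", ]
    expect_setequal(asm$truth_id, carried)
  }
})

test_that("planted biparental and private events have the stated genotype configurations", {
  cfg <- small_cfg(seed = 8)
  panel <- simulate_panel(cfg)
  cohort <- simulate_families(cfg, panel)
  ped <- cohort$pedigree
  gt <- cohort$truth$gt
  loci <- cohort$truth$loci
  planted <- cohort$ledger$loci[cohort$ledger$loci$planted, ]

  bp <- planted[planted$planted_class == "biparental_hom", ]
  expect_equal(nrow(bp), cfg$n_biparental_hom)
  for (i in seq_len(nrow(bp))) {
    li <- match(bp$locus_id[i], loci$id)
    ch <- bp$planted_child[i]
    fam <- ped$family[ped$sample == ch]
    fa <- ped$sample[ped$family == fam & ped$role == "father"]
    mo <- ped$sample[ped$family == fam & ped$role == "mother"]
    expect_equal(unname(gt[li, ch]), "1/1")
    expect_equal(unname(gt[li, fa]), "0/1")
    expect_equal(unname(gt[li, mo]), "0/1")
    # never homozygous in a control by construction (absent from panel)
    expect_false(bp$locus_id[i] %in% panel$matrix$loci$id)
  }

  pr <- planted[planted$planted_class == "private_inherited", ]
  parents <- ped$sample[ped$role %in% c("father", "mother")]
  for (i in seq_len(nrow(pr))) {
    li <- match(pr$locus_id[i], loci$id)
    carriers <- parents[gt_dosage(gt[li, parents]) >= 1]
    expect_length(carriers, 1)
    expect_gte(gt_dosage(gt[li, pr$planted_child[i]]), 1)
  }
})

test_that("jitter stays within the pairwise refdist bound and sequences stay matchable", {
  cfg <- small_cfg(seed = 10)
  panel <- simulate_panel(cfg)
  cohort <- simulate_families(cfg, panel)
  calls <- cohort$callsets
  truth_pos <- cohort$truth$loci$pos[match(calls$truth_id,
                                           cohort$truth$loci$id)]
  expect_true(all(abs(calls$pos - truth_pos) <= cfg$jitter_bound))
  # emitted INS sequences stay within the similarity budget of the truth
  ins <- which(calls$svtype == "INS" & !is.na(calls$seq))
  pick <- sample(ins, 25)
  truth_seq <- cohort$truth$loci$seq[match(calls$truth_id[pick],
                                           cohort$truth$loci$id)]
  for (k in seq_along(pick))
    expect_gte(seq_similarity(calls$seq[pick[k]], truth_seq[k]), 0.95)
})

test_that("read support follows the configured Poisson model", {
  cfg <- small_cfg(seed = 12)
  panel <- simulate_panel(cfg)
  cohort <- simulate_families(cfg, panel)
  rs0 <- simulate_read_support(cohort, lambda_carrier = 10, lambda_noise = 0)
  rs0b <- simulate_read_support(cohort, lambda_carrier = 10, lambda_noise = 0)
  expect_identical(rs0, rs0b)   # fixed seed reproducibility

  # true de novo events: zero parental support at lambda_noise = 0
  dn <- cohort$ledger$loci$locus_id[cohort$ledger$loci$planted &
    cohort$ledger$loci$planted_class == "de_novo"]
  expect_true(all(rs0$n_reads[rs0$sv_id %in% dn] == 0))

  # carrier parents: P(>= 3 reads) matches the Poisson tail
  parents <- cohort$pedigree$sample[cohort$pedigree$role %in%
                                      c("father", "mother")]
  gt <- cohort$truth$gt
  carrier <- mapply(function(id, s) {
    li <- match(id, cohort$truth$loci$id)
    isTRUE(gt_dosage(gt[li, s]) >= 1)
  }, rs0$sv_id, rs0$sample)
  frac <- mean(rs0$n_reads[carrier] >= 3)
  tail <- 1 - stats::ppois(2, 10)
  se <- sqrt(tail * (1 - tail) / sum(carrier))
  expect_lt(abs(frac - tail), 4 * se)
})

test_that("simulated methylation reproduces the configured skew", {
  islands <- data.frame(chrom = "chrX", start = (1:20) * 50000,
                        end = (1:20) * 50000 + 1000)
  m0 <- simulate_methylation(islands, skew = 0, noise_sd = 0.05, seed = 3)
  sk0 <- methylation_skew(m0$hap1, m0$hap2, islands)
  expect_lt(abs(sk0$mean_diff), 0.05)

  m8 <- simulate_methylation(islands, skew = 0.8, noise_sd = 0, seed = 3)
  sk8 <- methylation_skew(m8$hap1, m8$hap2, islands)
  expect_true(all(abs(sk8$islands$diff - 0.8) < 1e-12))
})

test_that("simulated alignments give a priori known window qualification", {
  # single full-length contig: every window qualified
  paf <- simulate_alignments(1, 5e6, chrom = "chrX", seed = 2)
  cov <- window_coverage(paf, "chrX", 5e6)
  expect_equal(cov$percent, 100)

  # four contigs overlapping one window: that window disqualified
  paf4 <- data.frame(qname = paste0("c", 1:4), qlen = 4e5, qstart = 0,
                     qend = 4e5, strand = "+", tname = "chrX", tlen = 5e6,
                     tstart = c(0, 1e6, 2.1e6, 2.2e6),
                     tend = c(2.15e6, 2.3e6, 5e6, 2.9e6),
                     nmatch = 4e5, alnlen = 4e5, mapq = 60)
  cov4 <- window_coverage(paf4, "chrX", 5e6)
  expect_false(cov4$windows$qualified[3])   # window [2e6, 3e6): 4 contigs
  expect_true(cov4$windows$qualified[1])
})
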