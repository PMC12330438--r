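test_that("sv_match applies the distance, size and sequence thresholds exactly", {
  p <- merge_params()
  a <- mk_call(pos = 10000, svlen = 500)
  expect_true(sv_match(a, a, p)$matched)
  expect_equal(sv_match(a, a, p)$size_similarity, 1)

  # breakpoint distance boundary: 500 matches, 501 does not
  b500 <- mk_call(pos = 10500, svlen = 500, id = "b")
  b501 <- mk_call(pos = 10501, svlen = 500, id = "b")
  expect_true(sv_match(a, b500, p)$matched)
  expect_false(sv_match(a, b501, p)$matched)
  expect_equal(sv_match(a, b501, p)$breakpoint_distance, 501)

  # size-similarity boundary: 90/100 matches, 89/100 does not
  a100 <- mk_call(svlen = 100)
  expect_true(sv_match(a100, mk_call(svlen = 90, id = "b"), p)$matched)
  expect_false(sv_match(a100, mk_call(svlen = 89, id = "b"), p)$matched)
  expect_equal(sv_match(a100, mk_call(svlen = 89, id = "b"), p)$size_similarity,
               0.89)

  expect_error(sv_match(a, mk_call(chrom = "chr2", id = "b"), p), "chromosome")
})

test_that("sequence similarity is edit-distance based and matches the DP oracle", {
  set.seed(11)
  base <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                collapse = "")
  mut <- strsplit(base, "")[[1]]
  idx <- sample(300, 35)
  for (i in idx) mut[i] <- setdiff(c("A", "C", "G", "T"), mut[i])[1]
  mut <- paste(mut, collapse = "")

  sim <- seq_similarity(base, mut)
  expect_equal(sim, 1 - oracle_edit_distance(base, mut) / 300)
  expect_lt(sim, 0.90)

  a <- mk_call(svtype = "INS", svlen = 300, seq = base)
  b <- mk_call(svtype = "INS", svlen = 300, seq = mut, id = "b")
  expect_false(sv_match(a, b, merge_params())$matched)
  # with either sequence absent the test is skipped
  b$seq <- NA_character_
  expect_true(sv_match(a, b, merge_params())$matched)

  # random pairs: exact similarity agrees with the oracle, incl. the fast path
  for (k in 1:20) {
    la <- sample(50:120, 1); lb <- sample(50:120, 1)
    sa <- paste(sample(c("A", "C", "G", "T"), la, TRUE), collapse = "")
    sb <- paste(sample(c("A", "C", "G", "T"), lb, TRUE), collapse = "")
    expect_equal(seq_similarity(sa, sb),
                 1 - oracle_edit_distance(sa, sb) / max(la, lb))
  }
})

test_that("sv_match is symmetric and monotone in its thresholds", {
  set.seed(21)
  calls <- random_calls(60, with_seq = TRUE)
  p <- merge_params()
  for (k in 1:120) {
    ij <- sample(nrow(calls), 2)
    a <- calls[ij[1], ]; b <- calls[ij[2], ]
    if (a$chrom != b$chrom) next
    expect_identical(sv_match(a, b, p)$matched, sv_match(b, a, p)$matched)
  }
  # relaxing thresholds never decreases cluster sizes
  pc <- planted_cluster_calls(8)
  strict <- collapse(pc$calls, merge_params(pctsize = 0.95, refdist = 200))
  loose <- collapse(pc$calls, merge_params(pctsize = 0.80, refdist = 800))
  expect_gte(nrow(strict$loci), nrow(loose$loci))
})

test_that("callerset validation keeps assembly calls matched by >= 1 aligner", {
  asm <- rbind(mk_call(pos = 1000, id = "a1"),
               mk_call(pos = 9000, id = "a2"),
               mk_call(pos = 20000, id = "a3"))
  al_a <- mk_call(pos = 1050, id = "x1")        # matches a1
  al_b <- mk_call(pos = 20400, id = "y1")       # matches a3
  v <- validate_callerset(asm, list(aligner_a = al_a, aligner_b = al_b))
  expect_setequal(v$validated$id, c("a1", "a3"))
  expect_equal(v$rejected$id, "a2")
  expect_equal(v$validated$pos[v$validated$id == "a1"], 1000)  # assembly coords
  expect_true(grepl("aligner_a", v$validated$callers[1]))

  empty <- asm[0, ]
  expect_equal(nrow(validate_callerset(empty, list(al_a))$validated), 0)
})

test_that("validated fraction matches the 1-(1-s)^2 closed form", {
  cfg <- sim_config(seed = 301, n_controls = 10, n_common_sv = 2000,
                    families = list(list(type = "trio", proband_sex = "male")),
                    caller_sensitivity = c(assembly = 1, aligner_a = 0.8,
                                           aligner_b = 0.8))
  panel <- simulate_panel(cfg)
  cohort <- simulate_families(cfg, panel)
  calls <- cohort$callsets
  s <- cohort$pedigree$sample[1]
  asm <- calls[calls$sample == s & calls$caller == "assembly", ]
  al <- lapply(c("aligner_a", "aligner_b"), function(cl)
    calls[calls$sample == s & calls$caller == cl, ])
  v <- validate_callerset(asm, al)
  frac <- nrow(v$validated) / nrow(asm)
  expect_gt(nrow(asm), 100)
  se <- sqrt(0.96 * 0.04 / nrow(asm))
  expect_lt(abs(frac - 0.96), 4 * se)
})

test_that("collapse builds one locus per allele and transfers genotypes", {
  calls <- sv_calls(data.frame(
    id = c("a", "b", "c"), sample = c("s1", "s2", "s3"),
    chrom = "chr1", pos = c(1000, 1100, 1200), svtype = "DEL", svlen = 200,
    qual = c(10, 60, 30), gt = c("0/1", "1/1", "0/1"),
    stringsAsFactors = FALSE))
  m <- collapse(calls, merge_params())
  expect_equal(nrow(m$loci), 1)
  expect_equal(m$loci$id, "b")   # maxqual representative
  expect_equal(unname(m$gt[1, ]), c("0/1", "1/1", "0/1"))

  far <- sv_calls(data.frame(
    id = c("a", "b"), sample = c("s1", "s2"), chrom = "chr1",
    pos = c(1000, 1600), svtype = "DEL", svlen = 200,
    stringsAsFactors = FALSE))
  expect_equal(nrow(collapse(far, merge_params())$loci), 2)  # 600 bp apart

  expect_error(collapse(far[c(2, 1), ], merge_params()), "sorted")

  # a sample with two distinct member calls becomes homozygous alt
  two <- sv_calls(data.frame(
    id = c("a", "b"), sample = "s1", chrom = "chr1", pos = c(1000, 1010),
    svtype = "DEL", svlen = 200, gt = "0/1", stringsAsFactors = FALSE))
  m2 <- collapse(two, merge_params())
  expect_equal(unname(m2$gt[1, "s1"]), "1/1")
})

test_that("greedy collapse equals the transitive-closure oracle on order-independent instances", {
  set.seed(77)
  for (rep in 1:40) {
    pc <- planted_cluster_calls(n_true = sample(5:12, 1))
    m <- collapse(pc$calls, merge_params())
    expect_equal(nrow(m$loci), pc$n_true)
    expect_equal(nrow(m$loci), oracle_cluster_count(pc$calls, merge_params()))
    # conservation: every input call assigned to exactly one cluster
    expect_equal(nrow(m$provenance), nrow(pc$calls))
    expect_setequal(m$provenance$member_id, pc$calls$id)
  }
})

test_that("collapse output is nonredundant and idempotent", {
  set.seed(99)
  pc <- planted_cluster_calls(10)
  m <- collapse(pc$calls, merge_params())
  loci <- m$loci
  for (i in seq_len(nrow(loci) - 1)) {
    for (j in (i + 1):nrow(loci)) {
      if (loci$chrom[i] != loci$chrom[j]) next
      expect_false(sv_match(loci[i, ], loci[j, ], merge_params())$matched)
    }
  }
  # collapsing the collapsed representatives changes nothing
  again <- loci
  again$sample <- "s1"
  again$gt <- "0/1"
  m2 <- collapse(sv_calls(again), merge_params())
  expect_equal(nrow(m2$loci), nrow(loci))
  expect_equal(m2$loci$pos, loci$pos)
})

test_that("Mendelian concordance is 1 on error-free trios and flags violations", {
  loci <- sv_calls(data.frame(
    id = c("v1", "v2", "v3"), chrom = "chr1", pos = c(1000, 2000, 3000),
    svtype = "DEL", svlen = 100, stringsAsFactors = FALSE))
  loci$sample <- NULL; loci$gt <- NULL
  ped <- mk_trio_ped()
  gt <- matrix(c("0/1", "0/1", "0/0",     # v1: child het, father het -> ok
                 "1/1", "0/1", "0/1",     # v2: both parents het -> ok
                 "1/1", "0/0", "0/1"),    # v3: father lacks the allele
               nrow = 3, byrow = TRUE,
               dimnames = list(NULL, c("fam01_p1", "fam01_fa", "fam01_mo")))
  m <- mk_matrix(loci, gt, c("fam01_p1", "fam01_fa", "fam01_mo"))
  res <- mendelian_concordance(m, ped)
  expect_equal(res$per_trio$n_carried, 3L)
  expect_equal(res$per_trio$concordance, 2 / 3)

  # trio with a missing parent is skipped with a warning
  ped2 <- rbind(ped, data.frame(sample = "fam02_p1", family = "fam02",
                                role = "proband", sex = "male",
                                affected = TRUE, superpop = "non-AFR"))
  ped2 <- rbind(ped2, data.frame(sample = "fam02_fa", family = "fam02",
                                 role = "father", sex = "male",
                                 affected = FALSE, superpop = "non-AFR"))
  ped2 <- rbind(ped2, data.frame(sample = "fam02_mo", family = "fam02",
                                 role = "mother", sex = "female",
                                 affected = FALSE, superpop = "non-AFR"))
  expect_warning(mendelian_concordance(m, ped2), "skipped")
})

test_that("concordance under the genotype-error channel matches enumeration", {
  # The error channel swaps carried diploid genotypes het <-> hom-alt with
  # probability e. Expected concordance over HWE trios is computed here by
  # exact enumeration over parental genotype pairs, transmission, and the
  # 2^3 error states, then compared to the simulated pipeline measurement.
  e <- 0.10
  cfg <- sim_config(seed = 402, n_controls = 5, n_common_sv = 4000,
                    families = list(list(type = "trio", proband_sex = "female")),
                    n_denovo_per_child = 0, n_private_inherited = 0,
                    n_biparental_hom = 0, genotype_error_rate = e,
                    afr_fraction = 0,
                    caller_sensitivity = c(assembly = 1, aligner_a = 1,
                                           aligner_b = 1))
  panel <- simulate_panel(cfg)
  cohort <- simulate_families(cfg, panel)
  ped <- cohort$pedigree
  m <- mk_matrix(
    sv_calls(cbind(cohort$truth$loci, sample = NA, gt = NA), validate = FALSE),
    cohort$observed_gt, ped$sample)
  auto <- cohort$truth$loci$chrom %in% c("chr1", "chr2", "chr3")
  m$loci <- m$loci[auto, ]; m$gt <- m$gt[auto, ]
  res <- mendelian_concordance(m, ped)$per_trio
  obs <- res$concordance

  af <- cohort$ledger$loci$af[auto]
  expected <- expected_concordance_enum(af, e)
  se <- sqrt(expected * (1 - expected) / res$n_checked)
  expect_lt(abs(obs - expected), 4 * se)
  expect_lt(expected, 1)   # the channel must actually degrade concordance
})
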