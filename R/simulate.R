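#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions the generator emulates: a control panel with
#' a Beta-distributed allele-frequency spectrum and Hardy-Weinberg genotypes
#' (AFR samples get a frequency boost so they carry more SVs), a bimodal SV
#' size distribution (Alu-like mode near 300 bp, LINE-like mode near 6 kbp,
#' log-normal background), trio/quad families with Mendelian transmission and
#' planted de novo / private-inherited / biparental-homozygous events, sex
#' chromosomes with male hemizygosity, per-caller breakpoint jitter and
#' sequence divergence, and an optional genotype-error channel.
#'
#' Breakpoint jitter is truncated at `floor((refdist - 1) / 2)` so that any
#' two independently jittered representations of one true allele stay within
#' `refdist` of each other; for the same reason the per-representation
#' substitution rate may not exceed `(1 - pctseq) / 2`. Configurations that
#' break these bounds are rejected, because they would break the planted
#' truth semantics.
#'
#' @param seed integer seed; a fixed seed makes every generator output
#'   byte-identical across runs.
#' @param n_controls control panel size.
#' @param afr_fraction fraction of AFR samples (controls and families).
#' @param families list of family descriptors:
#'   `list(type = "quad", proband_sex =, sibling_sex =)` or
#'   `list(type = "trio", proband_sex =)`.
#' @param n_common_sv number of panel loci.
#' @param af_beta shape parameters of the Beta allele-frequency spectrum.
#' @param afr_boost multiplicative AF boost for AFR samples.
#' @param size_mixture list: `weights` (alu, line, background), `alu` /
#'   `line` (mean, sd of the normal modes), `background` (meanlog, sdlog).
#' @param n_denovo_per_child planted de novo SVs per child (exact count).
#' @param n_private_inherited planted private-inherited SVs per child.
#' @param n_biparental_hom planted biparental-homozygous SVs (cohort total).
#' @param breakpoint_jitter_sd per-caller breakpoint jitter SD (bp).
#' @param seq_divergence per-base substitution rate between representations
#'   of the same insertion allele.
#' @param genotype_error_rate probability that a carried diploid genotype is
#'   swapped het/hom in the emitted callsets.
#' @param caller_sensitivity named per-caller detection probabilities.
#' @param params [merge_params()] the analysis will use.
#' @param genome [sv_genome()].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_controls = 100,
                       afr_fraction = 0.3,
                       families = default_families(),
                       n_common_sv = 5000,
                       af_beta = c(0.15, 3),
                       afr_boost = 1.5,
                       size_mixture = list(
                         weights = c(alu = 0.5, line = 0.1, background = 0.4),
                         alu = c(mean = 300, sd = 50),
                         line = c(mean = 6000, sd = 800),
                         background = c(meanlog = log(500), sdlog = 1)),
                       n_denovo_per_child = 2,
                       n_private_inherited = 5,
                       n_biparental_hom = 3,
                       breakpoint_jitter_sd = 30,
                       seq_divergence = 0.01,
                       genotype_error_rate = 0,
                       caller_sensitivity = c(assembly = 1,
                                              aligner_a = 0.8,
                                              aligner_b = 0.8),
                       params = merge_params(),
                       genome = default_genome()) {
  stopifnot(seed == round(seed), n_controls >= 0, n_common_sv >= 0,
            afr_fraction >= 0, afr_fraction <= 1,
            genotype_error_rate >= 0, genotype_error_rate <= 1,
            all(caller_sensitivity >= 0), all(caller_sensitivity <= 1),
            all(af_beta > 0))
  jitter_bound <- floor((params$refdist - 1) / 2)
  if (breakpoint_jitter_sd >= params$refdist)
    stop("breakpoint_jitter_sd >= refdist would break planted truth semantics")
  if (seq_divergence > (1 - params$pctseq) / 2)
    stop("seq_divergence above (1 - pctseq)/2 would break planted truth semantics")
  structure(list(seed = as.integer(seed), n_controls = n_controls,
                 afr_fraction = afr_fraction, families = families,
                 n_common_sv = n_common_sv, af_beta = af_beta,
                 afr_boost = afr_boost, size_mixture = size_mixture,
                 n_denovo_per_child = n_denovo_per_child,
                 n_private_inherited = n_private_inherited,
                 n_biparental_hom = n_biparental_hom,
                 breakpoint_jitter_sd = breakpoint_jitter_sd,
                 jitter_bound = jitter_bound,
                 seq_divergence = seq_divergence,
                 genotype_error_rate = genotype_error_rate,
                 caller_sensitivity = caller_sensitivity,
                 params = params, genome = genome),
            class = "sim_config")
}

#' @rdname sim_config
#' @details `default_families()` returns the default cohort structure:
#' four quads and two trios with mixed child sexes.
#' @export
default_families <- function() {
  list(list(type = "quad", proband_sex = "male", sibling_sex = "female"),
       list(type = "quad", proband_sex = "female", sibling_sex = "female"),
       list(type = "quad", proband_sex = "male", sibling_sex = "male"),
       list(type = "quad", proband_sex = "female", sibling_sex = "male"),
       list(type = "trio", proband_sex = "male"),
       list(type = "trio", proband_sex = "female"))
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  bases <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(bases)) < rate)
  if (length(hit)) {
    for (i in hit)
      bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1)
    seq <- paste(bases, collapse = "")
  }
  seq
}

draw_sizes <- function(n, mix) {
  w <- mix$weights / sum(mix$weights)
  comp <- sample(names(w), n, replace = TRUE, prob = w)
  out <- numeric(n)
  out[comp == "alu"] <- stats::rnorm(sum(comp == "alu"),
                                     mix$alu[["mean"]], mix$alu[["sd"]])
  out[comp == "line"] <- stats::rnorm(sum(comp == "line"),
                                      mix$line[["mean"]], mix$line[["sd"]])
  out[comp == "background"] <- stats::rlnorm(sum(comp == "background"),
                                             mix$background[["meanlog"]],
                                             mix$background[["sdlog"]])
  pmin(pmax(round(out), 50), 50000)
}

# Grid of candidate locus positions: spaced widely enough that two distinct
# loci can never satisfy the refdist test, outside masked regions, with a
# margin below each chromosome end for DEL spans.
locus_grid <- function(genome, spacing = 2000, margin = 60000) {
  rows <- list()
  for (chrom in names(genome$lengths)) {
    pos <- seq(spacing, genome$lengths[[chrom]] - margin, by = spacing)
    m <- genome$mask[genome$mask$chrom == chrom, , drop = FALSE]
    keep <- rep(TRUE, length(pos))
    for (i in seq_len(nrow(m)))
      keep <- keep & !(pos > m$start[i] - margin & pos <= m$end[i] + spacing)
    rows[[chrom]] <- data.frame(chrom = chrom, pos = pos[keep])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

trunc_jitter <- function(n, sd, bound) {
  if (sd <= 0 || bound <= 0) return(integer(n))
  j <- round(stats::rnorm(n, 0, sd))
  pmin(pmax(j, -bound), bound)
}

alleles_to_gt <- function(a1, a2) {
  ifelse(is.na(a1) & is.na(a2), ".",
  ifelse(is.na(a2), as.character(a1),
         paste(pmin(a1, a2), pmax(a1, a2), sep = "/")))
}

# Draw alleles for unrelated individuals at the given loci under
# Hardy-Weinberg, sex-aware: non-PAR chrX in males and chrY are haploid
# (a2 = NA); chrY in females is absent (both NA).
draw_alleles <- function(loci, af, sexes, superpops, afr_boost) {
  nl <- nrow(loci); ns <- length(sexes)
  boost <- ifelse(superpops == "AFR", afr_boost, 1)
  a1 <- a2 <- matrix(NA_integer_, nl, ns)
  for (j in seq_len(ns)) {
    p <- pmin(af * boost[j], 1)
    auto <- !(loci$chrom %in% c("chrX", "chrY"))
    a1[auto, j] <- stats::rbinom(sum(auto), 1, p[auto])
    a2[auto, j] <- stats::rbinom(sum(auto), 1, p[auto])
    xr <- loci$chrom == "chrX"
    yr <- loci$chrom == "chrY"
    if (sexes[j] == "female") {
      a1[xr, j] <- stats::rbinom(sum(xr), 1, p[xr])
      a2[xr, j] <- stats::rbinom(sum(xr), 1, p[xr])
      # chrY absent in females
    } else {
      a1[xr, j] <- stats::rbinom(sum(xr), 1, p[xr])
      a1[yr, j] <- stats::rbinom(sum(yr), 1, p[yr])
    }
  }
  list(a1 = a1, a2 = a2)
}

#' Simulate a pangenome control panel
#'
#' Draws `n_common_sv` loci with Beta-distributed population allele
#' frequencies and control genotypes under Hardy-Weinberg (AFR samples get a
#' configurable AF boost; chrX/chrY genotypes are sex-consistent). Returns
#' the panel as a nonredundant `sv_matrix` (the shape a collapsed control
#' callset takes), control metadata, and the truth ledger.
#'
#' @param config [sim_config()].
#' @return list of class `sv_panel`: `matrix`, `meta` (sample, sex,
#'   superpop), `ledger` (per-locus truth with AF and class), `config`.
#' @export
simulate_panel <- function(config) {
  genome <- config$genome
  with_seed(config$seed, {
    n <- config$n_controls
    meta <- data.frame(
      sample = sprintf("ctrl%03d", seq_len(max(n, 0))),
      sex = ifelse(stats::runif(n) < 0.5, "male", "female"),
      superpop = ifelse(stats::runif(n) < config$afr_fraction, "AFR", "non-AFR"),
      stringsAsFactors = FALSE)

    grid <- locus_grid(genome)
    take <- sample(nrow(grid), config$n_common_sv)
    loci <- grid[take, , drop = FALSE]
    o <- order(loci$chrom, loci$pos)
    loci <- loci[o, , drop = FALSE]
    nl <- nrow(loci)
    loci$svtype <- sample(c("DEL", "INS"), nl, replace = TRUE)
    loci$svlen <- draw_sizes(nl, config$size_mixture)
    loci$id <- sprintf("pan%05d", seq_len(nl))
    loci$seq <- NA_character_
    ins <- which(loci$svtype == "INS")
    for (i in ins) loci$seq[i] <- random_seq(loci$svlen[i])
    loci$qual <- round(stats::runif(nl, 30, 60), 1)
    af <- stats::rbeta(nl, config$af_beta[1], config$af_beta[2])

    al <- draw_alleles(loci, af, meta$sex, meta$superpop, config$afr_boost)
    gt <- matrix(alleles_to_gt(al$a1, al$a2), nl, nrow(meta),
                 dimnames = list(NULL, meta$sample))

    loci_df <- sv_calls(data.frame(
      id = loci$id, chrom = loci$chrom, pos = loci$pos, svtype = loci$svtype,
      svlen = loci$svlen, seq = loci$seq, qual = loci$qual,
      stringsAsFactors = FALSE))
    loci_df$sample <- NULL; loci_df$gt <- NULL
    ledger <- data.frame(locus_id = loci$id, chrom = loci$chrom,
                         pos = loci$pos, svtype = loci$svtype,
                         svlen = loci$svlen, af = af, class = "common",
                         tr_flag = stats::runif(nl) < 0.1,
                         stringsAsFactors = FALSE)
    structure(list(
      matrix = structure(list(loci = loci_df, gt = gt, samples = meta$sample),
                         class = "sv_matrix"),
      meta = meta, ledger = ledger, config = config),
      class = "sv_panel")
  })
}

#' Simulate family cohorts with planted events and per-caller callsets
#'
#' Parents draw genotypes from the panel allele frequencies; children inherit
#' under Mendelian transmission (sex-aware on chrX/chrY). Planted on top:
#' de novo SVs (one child each, absent everywhere else), private-inherited
#' SVs (exactly one carrier parent cohort-wide, transmitted to the designated
#' child), and biparental-homozygous SVs (both parents of one family het,
#' designated child hom-alt, never hom in controls). Each caller then emits
#' each carried SV with its sensitivity, with truncated-normal breakpoint
#' jitter and substitution divergence on insertion sequences; the optional
#' genotype-error channel swaps carried diploid genotypes het/hom.
#'
#' The ledger records, for every (locus, child) pair that is truly rare
#' against the panel (sex-matched presence), the *realized* class — a panel
#' locus that happens to end up with exactly one carrier parent cohort-wide
#' is labelled private-inherited, because that is what it truly is in the
#' realized cohort.
#'
#' @param config [sim_config()].
#' @param panel [simulate_panel()] output.
#' @return list of class `sv_cohort`: `pedigree`, `truth` (loci + allele
#'   matrices + `gt` string matrix, pre-error), `observed_gt` (post-error),
#'   `callsets` (one [sv_calls()] table, columns include `caller` and
#'   `truth_id`), `ledger` (list: `loci`, `events`, `errors`), `config`.
#' @export
simulate_families <- function(config, panel) {
  genome <- config$genome
  with_seed(config$seed + 1L, {
    ped <- build_pedigree(config)
    parents <- ped[ped$role %in% c("father", "mother"), , drop = FALSE]
    children <- ped[ped$role %in% c("proband", "sibling"), , drop = FALSE]

    pl <- panel$matrix$loci
    af <- panel$ledger$af[match(pl$id, panel$ledger$locus_id)]

    # planted loci occupy grid slots not used by the panel
    grid <- locus_grid(genome)
    free <- grid[!paste(grid$chrom, grid$pos) %in% paste(pl$chrom, pl$pos), ]
    free <- free[free$chrom %in% c("chr1", "chr2", "chr3"), , drop = FALSE]
    n_planted <- nrow(children) * (config$n_denovo_per_child +
                                     config$n_private_inherited) +
      config$n_biparental_hom
    take <- free[sample(nrow(free), n_planted), , drop = FALSE]
    planted <- make_planted_loci(take, config)

    loci <- rbind(pl[, c("id", "chrom", "pos", "svtype", "svlen", "seq", "qual")],
                  planted[, c("id", "chrom", "pos", "svtype", "svlen", "seq", "qual")])
    o <- order(loci$chrom, loci$pos)
    loci <- loci[o, , drop = FALSE]
    rownames(loci) <- NULL
    nl <- nrow(loci)
    af_all <- c(af, rep(0, nrow(planted)))[o]
    is_planted <- c(rep(FALSE, nrow(pl)), rep(TRUE, nrow(planted)))[o]

    # parental alleles at panel loci; zero at planted loci until assigned
    fam_superpop <- draw_family_superpop(ped, config)
    ped$superpop <- fam_superpop[ped$family]
    a1 <- a2 <- matrix(NA_integer_, nl, nrow(ped),
                       dimnames = list(NULL, ped$sample))
    pal <- draw_alleles(loci, af_all, parents$sex,
                        fam_superpop[parents$family], config$afr_boost)
    a1[, parents$sample] <- pal$a1
    a2[, parents$sample] <- pal$a2

    # children inherit
    for (k in seq_len(nrow(children))) {
      ch <- children[k, ]
      fa <- ped$sample[ped$family == ch$family & ped$role == "father"]
      mo <- ped$sample[ped$family == ch$family & ped$role == "mother"]
      inh <- inherit_alleles(loci, a1, a2, fa, mo, ch$sex, genome)
      a1[, ch$sample] <- inh$a1
      a2[, ch$sample] <- inh$a2
    }

    # overwrite genotypes at planted loci
    events <- assign_planted(planted, loci, a1, a2, ped, config)
    a1 <- events$a1; a2 <- events$a2; planted <- events$planted

    truth_gt <- matrix(alleles_to_gt(a1, a2), nl, nrow(ped),
                       dimnames = list(NULL, ped$sample))

    # genotype-error channel: swap carried diploid genotypes het <-> hom-alt
    err <- inject_errors(a1, a2, config$genotype_error_rate)
    obs_gt <- matrix(alleles_to_gt(err$a1, err$a2), nl, nrow(ped),
                     dimnames = list(NULL, ped$sample))

    callsets <- emit_callsets(loci, err$a1, err$a2, obs_gt, ped, config)

    ledger_loci <- data.frame(
      locus_id = loci$id, chrom = loci$chrom, pos = loci$pos,
      svtype = loci$svtype, svlen = loci$svlen, af = af_all,
      planted = is_planted,
      planted_class = planted$class[match(loci$id, planted$id)],
      planted_child = planted$child[match(loci$id, planted$id)],
      tr_flag = c(panel$ledger$tr_flag,
                  rep(FALSE, nrow(planted)))[o],
      stringsAsFactors = FALSE)
    realized <- realize_events(loci, a1, a2, ped, panel, planted, genome)

    structure(list(pedigree = ped,
                   truth = list(loci = loci, a1 = a1, a2 = a2, gt = truth_gt),
                   observed_gt = obs_gt,
                   callsets = callsets,
                   ledger = list(loci = ledger_loci, events = realized,
                                 errors = err$errors),
                   config = config),
              class = "sv_cohort")
  })
}

build_pedigree <- function(config) {
  rows <- list()
  for (i in seq_along(config$families)) {
    f <- config$families[[i]]
    fam <- sprintf("fam%02d", i)
    rows[[i]] <- data.frame(
      sample = paste0(fam, c("_fa", "_mo", "_p1",
                             if (f$type == "quad") "_s1")),
      family = fam,
      role = c("father", "mother", "proband",
               if (f$type == "quad") "sibling"),
      sex = c("male", "female", f$proband_sex,
              if (f$type == "quad") f$sibling_sex),
      affected = c(FALSE, FALSE, TRUE, if (f$type == "quad") FALSE),
      superpop = NA_character_,
      stringsAsFactors = FALSE)
  }
  ped <- do.call(rbind, rows)
  rownames(ped) <- NULL
  ped
}

draw_family_superpop <- function(ped, config) {
  fams <- unique(ped$family)
  sp <- ifelse(stats::runif(length(fams)) < config$afr_fraction,
               "AFR", "non-AFR")
  names(sp) <- fams
  sp
}

inherit_alleles <- function(loci, a1, a2, fa, mo, sex, genome) {
  nl <- nrow(loci)
  pick <- function(x1, x2) {
    # one random allele per locus from a (possibly haploid) parent
    ifelse(is.na(x2), x1, ifelse(stats::runif(length(x1)) < 0.5, x1, x2))
  }
  from_fa <- pick(a1[, fa], a2[, fa])
  from_mo <- pick(a1[, mo], a2[, mo])
  c1 <- c2 <- rep(NA_integer_, nl)
  auto <- !(loci$chrom %in% c("chrX", "chrY"))
  c1[auto] <- from_fa[auto]; c2[auto] <- from_mo[auto]
  xr <- loci$chrom == "chrX"; yr <- loci$chrom == "chrY"
  if (sex == "male") {
    c1[xr] <- from_mo[xr]          # X from mother, haploid
    c1[yr] <- a1[yr, fa]           # Y from father
  } else {
    c1[xr] <- a1[xr, fa]           # father's single X
    c2[xr] <- from_mo[xr]
  }
  list(a1 = c1, a2 = c2)
}

make_planted_loci <- function(take, config) {
  n <- nrow(take)
  if (n == 0)
    return(data.frame(id = character(), chrom = character(), pos = numeric(),
                      svtype = character(), svlen = numeric(),
                      seq = character(), qual = numeric(), class = character(),
                      child = character(), family = character(),
                      origin = character(), stringsAsFactors = FALSE))
  df <- data.frame(id = sprintf("plt%04d", seq_len(n)),
                   chrom = take$chrom, pos = take$pos,
                   svtype = sample(c("DEL", "INS"), n, replace = TRUE),
                   svlen = draw_sizes(n, config$size_mixture),
                   seq = NA_character_,
                   qual = round(stats::runif(n, 30, 60), 1),
                   class = NA_character_, child = NA_character_,
                   family = NA_character_, origin = NA_character_,
                   stringsAsFactors = FALSE)
  for (i in which(df$svtype == "INS")) df$seq[i] <- random_seq(df$svlen[i])
  df
}

# Distribute the planted loci over children/families and set their alleles.
assign_planted <- function(planted, loci, a1, a2, ped, config) {
  children <- ped[ped$role %in% c("proband", "sibling"), , drop = FALSE]
  li <- match(planted$id, loci$id)
  cursor <- 0L
  nxt <- function(n) { out <- cursor + seq_len(n); cursor <<- cursor + n; out }

  for (k in seq_len(nrow(children))) {
    ch <- children[k, ]
    fam <- ped[ped$family == ch$family, ]
    fa <- fam$sample[fam$role == "father"]
    mo <- fam$sample[fam$role == "mother"]
    sib <- setdiff(fam$sample[fam$role %in% c("proband", "sibling")], ch$sample)

    for (i in nxt(config$n_denovo_per_child)) {
      planted$class[i] <- "de_novo"; planted$child[i] <- ch$sample
      planted$family[i] <- ch$family; planted$origin[i] <- "none"
      a1[li[i], ch$sample] <- 1L   # everyone else is ref by construction
    }
    for (i in nxt(config$n_private_inherited)) {
      side <- if (i %% 2 == 0) fa else mo
      planted$class[i] <- "private_inherited"; planted$child[i] <- ch$sample
      planted$family[i] <- ch$family
      planted$origin[i] <- if (side == fa) "paternal" else "maternal"
      a1[li[i], ch$sample] <- 1L
      a1[li[i], side] <- 1L
      # the carrier parent's other children stay on the ref allele so the
      # planted per-child count is exactly recoverable
      if (length(sib)) a1[li[i], sib] <- 0L
    }
  }
  # biparental homozygous: round-robin over families, proband homozygous
  fams <- unique(ped$family)
  for (b in seq_len(config$n_biparental_hom)) {
    i <- cursor + b
    fam <- fams[((b - 1) %% length(fams)) + 1]
    fm <- ped[ped$family == fam, ]
    fa <- fm$sample[fm$role == "father"]; mo <- fm$sample[fm$role == "mother"]
    pr <- fm$sample[fm$role == "proband"]
    sib <- fm$sample[fm$role == "sibling"]
    planted$class[i] <- "biparental_hom"; planted$child[i] <- pr
    planted$family[i] <- fam
    a1[li[i], c(fa, mo)] <- 0L; a2[li[i], c(fa, mo)] <- 1L
    a1[li[i], pr] <- 1L; a2[li[i], pr] <- 1L
    if (length(sib)) { a1[li[i], sib] <- 0L; a2[li[i], sib] <- 1L }
  }
  list(a1 = a1, a2 = a2, planted = planted)
}

inject_errors <- function(a1, a2, rate) {
  errors <- data.frame(row = integer(), sample = character())
  if (rate > 0) {
    diploid_carrier <- !is.na(a1) & !is.na(a2) & (a1 + a2 >= 1)
    hit <- diploid_carrier & matrix(stats::runif(length(a1)) < rate,
                                    nrow(a1), ncol(a1))
    idx <- which(hit, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      if (a1[i, j] + a2[i, j] == 1L) { a1[i, j] <- 1L; a2[i, j] <- 1L }
      else { a1[i, j] <- 0L; a2[i, j] <- 1L }
    }
    if (nrow(idx))
      errors <- data.frame(row = idx[, 1], sample = colnames(a1)[idx[, 2]])
  }
  list(a1 = a1, a2 = a2, errors = errors)
}

emit_callsets <- function(loci, a1, a2, obs_gt, ped, config) {
  out <- list()
  jb <- config$jitter_bound
  for (s in ped$sample) {
    dos <- ifelse(is.na(a1[, s]) & is.na(a2[, s]), NA_integer_,
                  ifelse(is.na(a2[, s]), a1[, s],
                         a1[, s] + a2[, s]))
    carried <- which(!is.na(dos) & dos >= 1)
    for (caller in names(config$caller_sensitivity)) {
      emit <- carried[stats::runif(length(carried)) <
                        config$caller_sensitivity[[caller]]]
      if (!length(emit)) next
      jit <- trunc_jitter(length(emit), config$breakpoint_jitter_sd, jb)
      seqs <- loci$seq[emit]
      if (config$seq_divergence > 0) {
        for (q in seq_along(seqs))
          if (!is.na(seqs[q]))
            seqs[q] <- mutate_seq(seqs[q], config$seq_divergence)
      }
      df <- data.frame(
        id = paste(loci$id[emit], s, caller, sep = "."),
        sample = s, chrom = loci$chrom[emit],
        pos = loci$pos[emit] + jit,
        svtype = loci$svtype[emit], svlen = loci$svlen[emit],
        end = ifelse(loci$svtype[emit] == "DEL",
                     loci$pos[emit] + jit + loci$svlen[emit],
                     loci$pos[emit] + jit),
        seq = seqs,
        qual = round(stats::runif(length(emit), 30, 60), 1),
        callers = caller, gt = obs_gt[emit, s],
        truth_id = loci$id[emit],
        caller = caller, stringsAsFactors = FALSE)
      out[[paste(s, caller)]] <- df
    }
  }
  calls <- do.call(rbind, out)
  calls <- calls[order(calls$chrom, calls$pos, calls$sample, calls$caller), ]
  rownames(calls) <- NULL
  class(calls) <- c("sv_calls", class(calls))
  calls
}

# Realized per-(locus, child) truth: which pairs are rare against the panel
# (sex-matched presence) and what class each one truly is.
realize_events <- function(loci, a1, a2, ped, panel, planted, genome) {
  children <- ped[ped$role %in% c("proband", "sibling"), , drop = FALSE]
  parents <- ped[ped$role %in% c("father", "mother"), , drop = FALSE]
  pan_gt <- panel$matrix$gt
  pan_ids <- panel$matrix$loci$id
  pan_dos <- gt_apply(pan_gt, gt_dosage)
  carried_by <- !is.na(pan_dos) & pan_dos >= 1
  sexes <- panel$meta$sex[match(panel$matrix$samples, panel$meta$sample)]
  pan_any <- rowSums(carried_by) >= 1
  pan_male <- rowSums(carried_by[, sexes == "male", drop = FALSE]) >= 1
  pan_female <- rowSums(carried_by[, sexes == "female", drop = FALSE]) >= 1
  pl2 <- gt_apply(pan_gt, gt_ploidy)
  pan_hom <- rowSums(!is.na(pan_dos) & pan_dos == 2 & pl2 == 2) >= 1

  dos_of <- function(s) ifelse(is.na(a1[, s]) & is.na(a2[, s]), NA_integer_,
                               ifelse(is.na(a2[, s]), a1[, s], a1[, s] + a2[, s]))
  pdos <- vapply(parents$sample, dos_of, integer(nrow(loci)))

  pan_row <- match(loci$id, pan_ids)   # NA for planted loci
  rows <- list()
  for (k in seq_len(nrow(children))) {
    ch <- children[k, ]
    cdos <- dos_of(ch$sample)
    seen <- ifelse(loci$chrom %in% c("chrX", "chrY"),
                   if (ch$sex == "male") pan_male[pan_row] else pan_female[pan_row],
                   pan_any[pan_row])
    seen[is.na(seen)] <- FALSE
    rare <- which(!is.na(cdos) & cdos >= 1 & !seen)
    if (!length(rare)) next
    fam <- ped[ped$family == ch$family, ]
    fa <- fam$sample[fam$role == "father"]
    mo <- fam$sample[fam$role == "mother"]
    cls <- character(length(rare)); org <- character(length(rare))
    for (q in seq_along(rare)) {
      i <- rare[q]
      pc <- planted$class[match(loci$id[i], planted$id)]
      if (!is.na(pc) && pc == "de_novo" &&
          planted$child[match(loci$id[i], planted$id)] == ch$sample) {
        cls[q] <- "de_novo"; org[q] <- "none"; next
      }
      carriers <- parents$sample[!is.na(pdos[i, ]) & pdos[i, ] >= 1]
      if (length(carriers) == 1 && carriers %in% c(fa, mo)) {
        cls[q] <- "private_inherited"
        org[q] <- if (carriers == fa) "paternal" else "maternal"
        next
      }
      hom_child <- !is.na(a2[i, ch$sample]) && a1[i, ch$sample] == 1L &&
        a2[i, ch$sample] == 1L
      auto <- !(loci$chrom[i] %in% c("chrX", "chrY"))
      if (auto && hom_child && both_parents_het(a1, a2, i, fa, mo) &&
          !isTRUE(pan_hom[pan_row[i]]) &&
          unique_biparental_family(loci, a1, a2, ped, i)) {
        cls[q] <- "biparental_hom"; org[q] <- "both"; next
      }
      cls[q] <- "rare_other"; org[q] <- "unknown"
    }
    rows[[ch$sample]] <- data.frame(
      locus_id = loci$id[rare], child = ch$sample, class = cls, origin = org,
      category = true_category(loci$chrom[rare], loci$pos[rare], cdos[rare],
                               is.na(a2[rare, ch$sample]), ch$sex, genome),
      stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, rows)
  rownames(ev) <- NULL
  ev
}

both_parents_het <- function(a1, a2, i, fa, mo) {
  het <- function(s) !is.na(a1[i, s]) && !is.na(a2[i, s]) &&
    a1[i, s] + a2[i, s] == 1L
  het(fa) && het(mo)
}

unique_biparental_family <- function(loci, a1, a2, ped, i) {
  kids <- ped[ped$role %in% c("proband", "sibling"), , drop = FALSE]
  fams <- character(0)
  for (k in seq_len(nrow(kids))) {
    s <- kids$sample[k]
    if (is.na(a1[i, s]) || is.na(a2[i, s]) ||
        a1[i, s] + a2[i, s] != 2L) next
    fam <- kids$family[k]
    fa <- ped$sample[ped$family == fam & ped$role == "father"]
    mo <- ped$sample[ped$family == fam & ped$role == "mother"]
    if (both_parents_het(a1, a2, i, fa, mo)) fams <- c(fams, fam)
  }
  length(unique(fams)) == 1
}

true_category <- function(chrom, pos, dos, haploid, sex, genome) {
  out <- character(length(chrom))
  xr <- chrom == "chrX"; yr <- chrom == "chrY"
  out[!xr & !yr & dos == 1] <- "AUTO_HET"
  out[!xr & !yr & dos == 2] <- "AUTO_HOM"
  out[xr & sex == "female" & dos == 1] <- "X_HET"
  out[xr & sex == "female" & dos == 2] <- "X_HOM"
  out[xr & sex == "male" & haploid] <- "MALE_HEMI_X"
  out[yr & sex == "male" & haploid] <- "MALE_HEMI_Y"
  out
}

#' Simulate a parental read-support table
#'
#' For every locus carried by at least one child of a family, the family's
#' two parents each get a supporting-read count: Poisson(`lambda_carrier`)
#' when the parent truly carries the allele, Poisson(`lambda_noise`)
#' otherwise (so true de novo events have noise-level parental support; with
#' `lambda_noise = 0` exactly zero). A mapping-quality summary and clipped
#' fraction accompany each row for the callable-region score.
#'
#' @param cohort [simulate_families()] output.
#' @param lambda_carrier Poisson mean for carrier parents, default 10.
#' @param lambda_noise Poisson mean for non-carrier parents, default 0.
#' @param seed seed (defaults to the cohort seed + 2).
#' @return data.frame: sv_id, sample, n_reads, mean_mapq, frac_clipped.
#' @export
simulate_read_support <- function(cohort, lambda_carrier = 10,
                                  lambda_noise = 0, seed = NULL) {
  if (is.null(seed)) seed <- cohort$config$seed + 2L
  with_seed(seed, {
    ped <- cohort$pedigree
    loci <- cohort$truth$loci
    a1 <- cohort$truth$a1; a2 <- cohort$truth$a2
    dos_of <- function(s) ifelse(is.na(a1[, s]) & is.na(a2[, s]), NA_integer_,
                                 ifelse(is.na(a2[, s]), a1[, s],
                                        a1[, s] + a2[, s]))
    rows <- list()
    for (fam in unique(ped$family)) {
      fm <- ped[ped$family == fam, ]
      kids <- fm$sample[fm$role %in% c("proband", "sibling")]
      pars <- fm$sample[fm$role %in% c("father", "mother")]
      kdos <- vapply(kids, dos_of, integer(nrow(loci)))
      cand <- which(rowSums(!is.na(kdos) & kdos >= 1) > 0)
      for (p in pars) {
        pdos <- dos_of(p)[cand]
        lam <- ifelse(!is.na(pdos) & pdos >= 1, lambda_carrier, lambda_noise)
        rows[[paste(fam, p)]] <- data.frame(
          sv_id = loci$id[cand], sample = p,
          n_reads = stats::rpois(length(cand), lam),
          mean_mapq = pmin(60, pmax(0, stats::rnorm(length(cand), 58, 1.5))),
          frac_clipped = stats::rbeta(length(cand), 1, 19),
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate contig-to-reference PAF alignments
#'
#' Cuts a chromosome into `n_contigs` alignment blocks at random breakpoints.
#' `break_model` controls the realised structure: `gap_frac` removes that
#' fraction from the end of each block (uncovered sequence), `overlap_bp`
#' extends each block into its right neighbour (extra overlapping contigs),
#' and `extra_contigs` adds that many short spurious contigs at random
#' positions.
#'
#' @param n_contigs number of primary contigs.
#' @param chrom_length chromosome length (bp).
#' @param break_model list(gap_frac = 0, overlap_bp = 0, extra_contigs = 0,
#'   extra_len = 50000).
#' @param chrom target name, default "chrX".
#' @param seed random seed.
#' @return PAF-shaped data.frame (see [read_paf()]).
#' @export
simulate_alignments <- function(n_contigs, chrom_length,
                                break_model = list(), chrom = "chrX",
                                seed = 1) {
  bm <- utils::modifyList(list(gap_frac = 0, overlap_bp = 0,
                               extra_contigs = 0, extra_len = 50000),
                          break_model)
  with_seed(seed, {
    cuts <- if (n_contigs > 1)
      sort(sample(seq(1e5, chrom_length - 1e5, by = 1e4), n_contigs - 1))
    else numeric(0)
    starts <- c(0, cuts)
    ends <- c(cuts, chrom_length)
    ends_eff <- starts + (ends - starts) * (1 - bm$gap_frac)
    ends_eff <- pmin(ends_eff + bm$overlap_bp, chrom_length)
    paf <- data.frame(
      qname = sprintf("contig%03d", seq_len(n_contigs)),
      qlen = round(ends_eff - starts), qstart = 0,
      qend = round(ends_eff - starts), strand = "+",
      tname = chrom, tlen = chrom_length,
      tstart = round(starts), tend = round(ends_eff),
      nmatch = round(ends_eff - starts),
      alnlen = round(ends_eff - starts), mapq = 60,
      stringsAsFactors = FALSE)
    if (bm$extra_contigs > 0) {
      st <- sample(seq(0, chrom_length - bm$extra_len, by = 1e4),
                   bm$extra_contigs)
      paf <- rbind(paf, data.frame(
        qname = sprintf("extra%03d", seq_len(bm$extra_contigs)),
        qlen = bm$extra_len, qstart = 0, qend = bm$extra_len, strand = "+",
        tname = chrom, tlen = chrom_length, tstart = st,
        tend = st + bm$extra_len, nmatch = bm$extra_len,
        alnlen = bm$extra_len, mapq = 60, stringsAsFactors = FALSE))
    }
    paf
  })
}

#' Simulate haplotype-resolved CpG methylation pileups
#'
#' Generates per-CpG methylated fractions inside each island: haplotype 1 at
#' `base + skew/2`, haplotype 2 at `base - skew/2`, plus independent normal
#' noise per CpG, clipped to \[0, 1\].
#'
#' @param cpg_islands data.frame (chrom, start, end), 0-based half-open.
#' @param skew haplotype mean separation in \[0, 1\].
#' @param noise_sd per-CpG noise SD.
#' @param base baseline methylation, default 0.5.
#' @param spacing CpG spacing within islands (bp), default 150.
#' @param seed random seed.
#' @return list with `hap1` and `hap2` pileup data.frames (chrom, start,
#'   end, frac).
#' @export
simulate_methylation <- function(cpg_islands, skew, noise_sd = 0,
                                 base = 0.5, spacing = 150, seed = 1) {
  with_seed(seed, {
    rows1 <- rows2 <- list()
    for (i in seq_len(nrow(cpg_islands))) {
      pos <- seq(cpg_islands$start[i], cpg_islands$end[i] - 1, by = spacing)
      f1 <- pmin(1, pmax(0, base + skew / 2 + stats::rnorm(length(pos), 0, noise_sd)))
      f2 <- pmin(1, pmax(0, base - skew / 2 + stats::rnorm(length(pos), 0, noise_sd)))
      rows1[[i]] <- data.frame(chrom = cpg_islands$chrom[i], start = pos,
                               end = pos + 1, frac = f1)
      rows2[[i]] <- data.frame(chrom = cpg_islands$chrom[i], start = pos,
                               end = pos + 1, frac = f2)
    }
    list(hap1 = do.call(rbind, rows1), hap2 = do.call(rbind, rows2))
  })
}
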