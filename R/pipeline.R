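#' Run the full rare-SV discovery pipeline on a synthetic cohort
#'
#' Executes the stages in order: simulate control panel and family cohort;
#' validate each sample's assembly-based calls against the alignment-based
#' callsets; collapse all validated calls into a nonredundant cohort
#' genotype matrix; compute per-trio Mendelian concordance; filter each
#' child's loci against the control panel (sex-matched on chrX/chrY);
#' classify the six rare-SV genotype categories; curate transmission for
#' every rare (SV, child) pair; label private-inherited and
#' biparental-homozygous classes; optionally annotate with interval tracks;
#' tabulate burden and run the proband-sibling tests; and compute the
#' pangenome discovery / rare-pool shrinkage curves. All randomness derives
#' from `config$seed`, so a rerun with the same config reproduces every
#' output exactly.
#'
#' @param config [sim_config()].
#' @param tracks optional list of [annotation_track()]s.
#' @param outdir optional directory: writes controls.vcf, cohort_matrix.vcf,
#'   pedigree.tsv, rare.tsv, burden.tsv, curve.tsv, manifest.tsv.
#' @param curve compute the discovery/shrinkage curves (default TRUE).
#' @return list of class `svsieve_run`: `panel`, `cohort`, `matrix`,
#'   `concordance`, `rare` (per rare (SV, child): category, class, origin,
#'   status, decided_by), `labels`, `burden`, `curve`, `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), tracks = NULL, outdir = NULL,
                         curve = TRUE) {
  params <- config$params
  panel <- simulate_panel(config)
  cohort <- simulate_families(config, panel)
  ped <- cohort$pedigree
  calls <- cohort$callsets

  # stage: callerset validation per sample
  validated <- list()
  n_raw <- nrow(calls)
  for (s in ped$sample) {
    asm <- calls[calls$sample == s & calls$caller == "assembly", , drop = FALSE]
    aligners <- lapply(
      setdiff(names(config$caller_sensitivity), "assembly"),
      function(cl) calls[calls$sample == s & calls$caller == cl, , drop = FALSE])
    names(aligners) <- setdiff(names(config$caller_sensitivity), "assembly")
    validated[[s]] <- validate_callerset(asm, aligners, params)$validated
  }
  vcalls <- do.call(rbind, validated)
  vcalls <- vcalls[order(vcalls$chrom, vcalls$pos), , drop = FALSE]
  rownames(vcalls) <- NULL

  # stage: inter-sample collapse (representative = most common member)
  cparams <- merge_params(pctseq = params$pctseq, pctsize = params$pctsize,
                          refdist = params$refdist, sizemin = params$sizemin,
                          sizemax = params$sizemax, keep_rule = "common")
  mat <- collapse(vcalls, cparams, samples = ped$sample, meta = ped,
                  genome = config$genome)

  conc <- mendelian_concordance(mat, ped, config$genome)

  # stage: pangenome filtering per child
  children <- ped[ped$role %in% c("proband", "sibling"), , drop = FALSE]
  child_loci <- list()
  rare_rows <- list()
  n_carried <- integer(nrow(children))
  for (k in seq_len(nrow(children))) {
    ch <- children[k, ]
    dos <- gt_dosage(mat$gt[, ch$sample])
    carried <- which(!is.na(dos) & dos >= 1)
    n_carried[k] <- length(carried)
    loci <- mat$loci[carried, , drop = FALSE]
    loci$sample <- ch$sample
    loci$gt <- mat$gt[carried, ch$sample]
    child_loci[[ch$sample]] <- loci
    flt <- filter_common(loci, panel$matrix, ch$sex, params, panel$meta)
    if (nrow(flt$rare))
      rare_rows[[ch$sample]] <- data.frame(
        locus_id = flt$rare$id, child = ch$sample,
        category = classify_category(flt$rare$chrom, flt$rare$pos,
                                     flt$rare$gt, ch$sex, config$genome),
        stringsAsFactors = FALSE)
  }
  rare <- do.call(rbind, rare_rows)
  rownames(rare) <- NULL

  # stage: transmission curation
  support <- simulate_read_support(cohort)
  parents <- ped$sample[ped$role %in% c("father", "mother")]
  bundle <- list(raw_calls = calls[calls$sample %in% parents, , drop = FALSE],
                 read_support = remap_support_ids(support, mat),
                 tr = NULL)
  verdicts <- curate(mat, ped, rare, bundle, params, config$genome)

  # stage: rare-SV classes
  rare <- extract_private_inherited(mat, ped, rare)
  rare <- extract_biparental_hom(mat, ped, rare, panel$matrix, params)
  rare$status <- verdicts$status
  rare$decided_by <- verdicts$decided_by
  denovo <- rare$status == "de_novo"
  rare$class[denovo] <- "de_novo"
  rare$origin[denovo] <- "none"

  labels <- if (!is.null(tracks)) annotate_sv(mat$loci, tracks) else NULL

  # stage: burden
  btab <- count_burden(rare[, c("locus_id", "child", "category", "class",
                                "origin")],
                       labels, ped)
  per_child <- tapply(rare$child, rare$child, length)
  counts <- setNames(rep(0L, nrow(children)), children$sample)
  counts[names(per_child)] <- as.integer(per_child)
  prob <- children$sample[children$role == "proband"]
  sib <- children$sample[children$role == "sibling"]
  mwu <- if (length(prob) && length(sib))
    mwu_counts(counts[prob], counts[sib]) else NULL
  dn_children <- tapply(rare$child[denovo], rare$child[denovo], length)
  k1 <- sum(prob %in% names(dn_children))
  k2 <- sum(sib %in% names(dn_children))
  chisq <- if (length(prob) && length(sib))
    chisq_rate_test(k1, length(prob), k2, length(sib)) else NULL

  curves <- if (curve)
    discovery_curve(panel$matrix, control_meta = panel$meta,
                    child_loci = child_loci,
                    child_sex = setNames(children$sex, children$sample),
                    params = params) else NULL

  manifest <- build_manifest(panel, cohort, n_raw, vcalls, mat, conc,
                             n_carried, rare, children)
  run <- structure(list(panel = panel, cohort = cohort, matrix = mat,
                        concordance = conc, rare = rare, labels = labels,
                        burden = list(table = btab, per_child = counts,
                                      mwu = mwu, chisq = chisq),
                        curve = curves, manifest = manifest,
                        config = config),
                   class = "svsieve_run")
  if (!is.null(outdir)) write_run(run, outdir)
  run
}

# Read support is keyed by true locus ids; the collapsed matrix keys loci by
# representative call ids carrying the truth id as a column. Translate.
remap_support_ids <- function(support, mat) {
  if (!"truth_id" %in% names(mat$loci)) return(support)
  map <- setNames(mat$loci$id, mat$loci$truth_id)
  hit <- support$sv_id %in% names(map)
  support$sv_id[hit] <- unname(map[support$sv_id[hit]])
  support
}

build_manifest <- function(panel, cohort, n_raw, vcalls, mat, conc,
                           n_carried, rare, children) {
  cat_counts <- table(factor(rare$category,
                             levels = c("AUTO_HET", "AUTO_HOM", "X_HET",
                                        "X_HOM", "MALE_HEMI_X", "MALE_HEMI_Y")))
  class_counts <- table(factor(rare$class,
                               levels = c("de_novo", "private_inherited",
                                          "biparental_hom", "rare_other")))
  status_counts <- table(factor(rare$status,
                                levels = c("high_confidence", "moderate",
                                           "low_confidence", "de_novo",
                                           "unresolved")))
  rare_per_child <- nrow(rare) / nrow(children)
  vals <- c(n_controls = length(panel$matrix$samples),
            n_panel_loci = nrow(panel$matrix$loci),
            n_family_samples = nrow(cohort$pedigree),
            n_raw_calls = n_raw,
            n_validated_calls = nrow(vcalls),
            n_nonredundant_loci = nrow(mat$loci),
            mean_mendelian_concordance = conc$mean_rate,
            mean_carried_per_child = mean(n_carried),
            n_rare_pairs = nrow(rare),
            mean_rare_per_child = rare_per_child,
            mean_frac_filtered = 1 - rare_per_child / mean(n_carried),
            setNames(as.numeric(cat_counts),
                     paste0("category_", names(cat_counts))),
            setNames(as.numeric(class_counts),
                     paste0("class_", names(class_counts))),
            setNames(as.numeric(status_counts),
                     paste0("status_", names(status_counts))))
  data.frame(key = names(vals), value = unname(vals),
             stringsAsFactors = FALSE)
}

write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  genome <- run$config$genome
  write_matrix(run$panel$matrix, file.path(outdir, "controls.vcf"),
               genome = genome)
  write_matrix(run$matrix, file.path(outdir, "cohort_matrix.vcf"),
               genome = genome)
  write_pedigree(run$cohort$pedigree, file.path(outdir, "pedigree.tsv"))
  utils::write.table(run$rare, file.path(outdir, "rare.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(run$burden$table, file.path(outdir, "burden.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(run$curve))
    utils::write.table(run$curve$curve, file.path(outdir, "curve.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(run$manifest, file.path(outdir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}

#' @export
print.svsieve_run <- function(x, ...) {
  cat("svsieve run:\n")
  m <- x$manifest
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %-28s %s\n", m$key[i], format(m$value[i])))
  invisible(x)
}
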