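#' Read structural variants from a VCF
#'
#' Parses DEL/INS records from a (possibly multi-sample) VCF. Symbolic ALTs
#' (`<DEL>`, `<INS>`) require an `SVLEN` INFO field (sign is normalised, so
#' `SVLEN=-874` yields a 874 bp DEL); explicit REF/ALT alleles derive type and
#' length from the allele size difference. Multi-allelic records are split
#' into one record per alt allele. Records outside `[sizemin, sizemax]` (and
#' always below 50 bp) are dropped; SV types other than DEL/INS are rejected
#' with a warning. Malformed records are reported with their record number
#' and skipped. When `sample_sex` is given, diploid male genotypes on non-PAR
#' chrX/chrY are coerced to hemizygous with a warning.
#'
#' @param path VCF file (plain or bgzipped).
#' @param sample_sex optional named character vector, sample -> "male"/"female".
#' @param genome [sv_genome()] for PAR-aware coercion.
#' @param sizemin,sizemax retained SV length range in bp.
#' @return an `sv_matrix`-shaped list: `loci` ([sv_calls()] without sample
#'   columns), `gt` (loci x samples genotype matrix), `samples`.
#' @export
read_sv_vcf <- function(path, sample_sex = NULL, genome = default_genome(),
                        sizemin = 50, sizemax = 1e6) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  gt_raw <- vcf@gt
  samples <- if (!is.null(gt_raw) && ncol(gt_raw) > 1)
    colnames(gt_raw)[-1] else character(0)

  rows <- list(); gts <- list()
  for (r in seq_len(nrow(fix))) {
    rec <- tryCatch(parse_sv_record(fix[r, ], gt_raw, r, samples),
                    error = function(e) {
                      if (inherits(e, "svsieve_missing_svlen"))
                        stop("record ", r, ": ", conditionMessage(e),
                             call. = FALSE)
                      warning("record ", r, " skipped: ", conditionMessage(e))
                      NULL
                    })
    if (is.null(rec)) next
    rows[[length(rows) + 1L]] <- rec$loci
    gts[[length(gts) + 1L]] <- rec$gt
  }
  if (!length(rows)) {
    loci <- sv_calls(data.frame(chrom = character(), pos = integer(),
                                svtype = character(), svlen = integer()),
                     validate = FALSE)
    return(structure(list(loci = loci,
                          gt = matrix("", 0, length(samples),
                                      dimnames = list(NULL, samples)),
                          samples = samples), class = "sv_matrix"))
  }
  loci <- do.call(rbind, rows)
  gt <- do.call(rbind, gts)
  colnames(gt) <- samples

  bad_type <- !loci$svtype %in% c("DEL", "INS")
  if (any(bad_type)) {
    warning(sum(bad_type), " non-DEL/INS record(s) rejected (",
            paste(unique(loci$svtype[bad_type]), collapse = ","), ")")
  }
  keep <- !bad_type & loci$svlen >= max(50, sizemin) & loci$svlen <= sizemax
  loci <- loci[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]

  if (!is.null(sample_sex) && nrow(loci)) {
    for (s in intersect(samples, names(sample_sex))) {
      gt[, s] <- coerce_hemizygous(gt[, s], loci$chrom, loci$pos,
                                   sample_sex[[s]], genome)
    }
  }
  structure(list(loci = sv_calls(loci, validate = FALSE), gt = gt,
                 samples = samples),
            class = "sv_matrix")
}

parse_sv_record <- function(fx, gt_raw, r, samples) {
  info <- info_fields(fx[["INFO"]])
  alts <- strsplit(fx[["ALT"]], ",", fixed = TRUE)[[1]]
  svtypes <- split_info(info[["SVTYPE"]], length(alts))
  svlens <- split_info(info[["SVLEN"]], length(alts))
  seqs <- split_info(info[["SEQ"]], length(alts))
  pos <- as.integer(fx[["POS"]])
  ref <- fx[["REF"]]
  loci <- list(); gts <- list()
  for (k in seq_along(alts)) {
    alt <- alts[k]
    if (grepl("^<", alt)) {
      svtype <- if (!is.na(svtypes[k])) svtypes[k] else gsub("[<>]", "", alt)
      if (is.na(svlens[k]))
        stop(errorCondition("symbolic ALT without SVLEN",
                            class = "svsieve_missing_svlen"))
      svlen <- abs(as.integer(svlens[k]))
    } else {
      svtype <- if (nchar(alt) > nchar(ref)) "INS" else "DEL"
      svlen <- abs(nchar(alt) - nchar(ref))
      if (is.na(seqs[k]) && svtype == "INS" && nchar(ref) == 1)
        seqs[k] <- substring(alt, 2)
    }
    seq_k <- seqs[k]
    if (!is.na(seq_k) && svtype == "INS" && nchar(seq_k) != svlen)
      seq_k <- NA_character_
    loci[[k]] <- data.frame(
      id = if (is.na(fx[["ID"]]) || fx[["ID"]] == ".")
        sprintf("rec%d_%d", r, k) else if (length(alts) > 1)
          paste0(fx[["ID"]], "_", k) else fx[["ID"]],
      sample = NA_character_, chrom = fx[["CHROM"]], pos = pos,
      svtype = svtype, svlen = svlen,
      end = if (svtype == "DEL") pos + svlen else pos,
      seq = seq_k,
      qual = if (is.na(fx[["QUAL"]])) 0 else as.numeric(fx[["QUAL"]]),
      callers = if (!is.null(info[["CALLERS"]])) info[["CALLERS"]] else "",
      gt = NA_character_, stringsAsFactors = FALSE)
    if (length(samples)) {
      g <- vapply(samples, function(s) {
        raw <- gt_raw[r, s]
        if (is.na(raw)) return(".")
        strsplit(raw, ":", fixed = TRUE)[[1]][1]
      }, character(1))
      gts[[k]] <- remap_alt_gt(g, k)
    } else gts[[k]] <- character(0)
  }
  list(loci = do.call(rbind, loci), gt = do.call(rbind, gts))
}

info_fields <- function(info) {
  if (is.na(info) || info == ".") return(list())
  kv <- strsplit(strsplit(info, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  out <- lapply(kv, function(x) if (length(x) > 1) x[2] else TRUE)
  names(out) <- vapply(kv, `[`, character(1), 1)
  out
}

split_info <- function(x, n) {
  if (is.null(x)) return(rep(NA_character_, n))
  v <- strsplit(x, ",", fixed = TRUE)[[1]]
  rep_len(v, n)
}

# For alt allele k of a multi-allelic record: alleles equal to k become 1,
# other alleles 0, missing stays missing.
remap_alt_gt <- function(gt, k) {
  vapply(gt, function(g) {
    sep <- if (grepl("|", g, fixed = TRUE)) "|" else "/"
    a <- strsplit(g, "[/|]")[[1]]
    a <- ifelse(a == ".", ".", ifelse(a == as.character(k), "1", "0"))
    paste(a, collapse = sep)
  }, character(1), USE.NAMES = FALSE)
}

#' Write a genotype matrix (or per-sample callset) as VCF
#'
#' `write_matrix()` serialises an `sv_matrix` as a multi-sample VCF v4.2 with
#' symbolic ALTs and `SVTYPE`/`SVLEN`/`END`/`SEQ`/`CALLERS` INFO fields
#' (`SVLEN` is written negative for DEL, per convention); `read_matrix()` is
#' the inverse. The round trip is lossless for loci and genotypes. Genotype
#' columns follow `matrix$samples`.
#'
#' @param matrix an `sv_matrix` (from [collapse()] or [read_sv_vcf()]).
#' @param path output path (plain text; `.vcf`).
#' @param meta optional sample metadata checked against `matrix$samples`.
#' @param genome [sv_genome()] whose contigs are declared in the header.
#' @export
write_matrix <- function(matrix, path, meta = NULL, genome = default_genome()) {
  if (!is.null(meta) && !setequal(meta$sample, matrix$samples))
    stop("sample mismatch between matrix and metadata")
  loci <- matrix$loci
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(genome$lengths),
            as.integer(genome$lengths)),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##INFO=<ID=SEQ,Number=1,Type=String,Description=\"Allele sequence\">",
    "##INFO=<ID=CALLERS,Number=1,Type=String,Description=\"Supporting callers\">",
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=INS,Description=\"Insertion\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(matrix$samples)) c("FORMAT", matrix$samples)),
          collapse = "\t"))
  body <- character(nrow(loci))
  for (i in seq_len(nrow(loci))) {
    info <- sprintf("SVTYPE=%s;SVLEN=%d;END=%d", loci$svtype[i],
                    if (loci$svtype[i] == "DEL") -loci$svlen[i] else loci$svlen[i],
                    as.integer(loci$end[i]))
    if (!is.na(loci$seq[i])) info <- paste0(info, ";SEQ=", loci$seq[i])
    if (nzchar(loci$callers[i])) info <- paste0(info, ";CALLERS=", loci$callers[i])
    fields <- c(loci$chrom[i], loci$pos[i], loci$id[i], "N",
                paste0("<", loci$svtype[i], ">"),
                format(loci$qual[i], trim = TRUE, scientific = FALSE), "PASS",
                info)
    if (length(matrix$samples))
      fields <- c(fields, "GT", matrix$gt[i, matrix$samples])
    body[i] <- paste(fields, collapse = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_matrix
#' @param ... passed to [read_sv_vcf()].
#' @export
read_matrix <- function(path, ...) read_sv_vcf(path, ...)

#' Write a single-sample callset as VCF
#'
#' @param calls [sv_calls()] rows for one sample (`sample`/`gt` columns used).
#' @param path output path.
#' @param sample sample name for the genotype column (default: from `calls`).
#' @param genome [sv_genome()].
#' @export
write_sv_vcf <- function(calls, path, sample = NULL, genome = default_genome()) {
  if (is.null(sample)) {
    sample <- unique(calls$sample[!is.na(calls$sample)])
    if (length(sample) != 1) stop("calls must carry exactly one sample")
  }
  o <- order(calls$chrom, calls$pos)
  calls <- calls[o, , drop = FALSE]
  m <- structure(list(loci = calls,
                      gt = matrix(calls$gt, ncol = 1,
                                  dimnames = list(NULL, sample)),
                      samples = sample), class = "sv_matrix")
  write_matrix(m, path, genome = genome)
}

#' Read / write a pedigree table
#'
#' Tab-separated with header: `sample`, `family`, `role` (father, mother,
#' proband, sibling), `sex` (male, female), `affected` (0/1), `superpop`
#' (AFR, non-AFR). Validation enforces one male father and one female mother
#' per family with children, affected probands and unaffected siblings.
#'
#' @param path TSV path.
#' @return pedigree data.frame.
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  validate_pedigree(ped)
  ped
}

#' @rdname read_pedigree
#' @param ped pedigree data.frame.
#' @export
write_pedigree <- function(ped, path) {
  utils::write.table(ped, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_pedigree
#' @export
validate_pedigree <- function(ped) {
  stopifnot(all(c("sample", "family", "role", "sex", "affected", "superpop")
                %in% names(ped)))
  stopifnot(all(ped$role %in% c("father", "mother", "proband", "sibling")),
            all(ped$sex %in% c("male", "female")))
  for (f in unique(ped$family)) {
    fam <- ped[ped$family == f, ]
    if (any(fam$role %in% c("proband", "sibling"))) {
      if (sum(fam$role == "father" & fam$sex == "male") != 1 ||
          sum(fam$role == "mother" & fam$sex == "female") != 1)
        stop("family ", f, ": children need exactly one father and one mother")
    }
    if (any(fam$role == "proband" & !as.logical(fam$affected)))
      stop("family ", f, ": probands must be affected")
    if (any(fam$role == "sibling" & as.logical(fam$affected)))
      stop("family ", f, ": siblings must be unaffected")
  }
  invisible(ped)
}

#' Read PAF alignment records
#'
#' Reads the 12 mandatory PAF columns (coordinates 0-based half-open).
#'
#' @param path PAF file.
#' @return data.frame with qname, qlen, qstart, qend, strand, tname, tlen,
#'   tstart, tend, nmatch, alnlen, mapq.
#' @export
read_paf <- function(path) {
  paf <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           fill = TRUE)[, 1:12]
  names(paf) <- c("qname", "qlen", "qstart", "qend", "strand", "tname",
                  "tlen", "tstart", "tend", "nmatch", "alnlen", "mapq")
  paf
}

#' @rdname read_paf
#' @param paf PAF data.frame.
#' @export
write_paf <- function(paf, path) {
  utils::write.table(paf, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED interval track
#'
#' 0-based half-open intervals; optional 4th (name) and 5th (score) columns.
#'
#' @param path BED file.
#' @return data.frame with chrom, start, end and, when present, name, score.
#' @export
read_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(bed)[1:3] <- c("chrom", "start", "end")
  if (ncol(bed) >= 4) names(bed)[4] <- "name"
  if (ncol(bed) >= 5) names(bed)[5] <- "score"
  bed
}

#' @rdname read_bed
#' @param bed data.frame with chrom, start, end (+ extra columns).
#' @export
write_bed <- function(bed, path) {
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-CpG methylation pileup (bedMethyl-like)
#'
#' Accepts either a minimal 4-column BED (`chrom start end fraction`, with the
#' methylated fraction in \[0,1\]) or a >= 11-column bedMethyl pileup whose
#' 11th column is the percent of modified calls.
#'
#' @param path BED path.
#' @return data.frame with chrom, start, end, frac.
#' @export
read_bedmethyl <- function(path) {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(bed) >= 11) {
    out <- bed[, c(1:3, 11)]
    names(out) <- c("chrom", "start", "end", "frac")
    out$frac <- out$frac / 100
  } else {
    out <- bed[, 1:4]
    names(out) <- c("chrom", "start", "end", "frac")
  }
  out
}
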