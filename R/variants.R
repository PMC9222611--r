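# Population variant handling: VCF I/O, GATK-style hard filtering, accession
# merging, substitution typing, minor allele frequency, Ts/Tv summary.
#
# Organelle genotypes are treated as haploid. Diploid-encoded homozygous
# calls collapse to a single allele; heterozygous calls (heteroplasmy or
# mapping noise) are resolved per `het` policy, default the site's major
# allele.

#' Read variants from a VCF
#'
#' Parses a VCF 4.x file into the package's tidy variant table: one row per
#' site with the QUAL and INFO annotations the hard filter consumes (QD, FS,
#' MQ) and a list-column of haploid per-sample allele indices (0 = reference,
#' 1+ = alternate, NA = missing).
#'
#' @param path VCF file (plain or bgzipped).
#' @param het How to collapse heterozygous diploid-encoded calls:
#'   `"major"` (site-level major allele, default), `"first"` (first allele of
#'   the call), or `"missing"`.
#' @return Tibble with columns `chrom`, `pos`, `ref`, `alt` (list of
#'   character vectors), `qual`, `qd`, `fs`, `mq`, `genotypes` (list of
#'   integer vectors, named by sample); attribute `samples`.
#' @export
read_vcf_variants <- function(path, het = c("major", "first", "missing")) {
  het <- match.arg(het)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  n <- nrow(fix)
  if (is.null(n) || n == 0) {
    out <- tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = list(), qual = double(), qd = double(), fs = double(),
                  mq = double(), genotypes = list())
    attr(out, "samples") <- character()
    return(out)
  }
  info_num <- function(key) {
    suppressWarnings(as.numeric(vcfR::extract.info(v, element = key)))
  }
  gt <- if (ncol(v@gt) > 1) vcfR::extract.gt(v, element = "GT") else NULL
  samples <- if (is.null(gt)) character() else colnames(gt)
  genotypes <- lapply(seq_len(n), function(i) {
    if (is.null(gt)) return(integer())
    parse_gt_row(gt[i, ], het = het)
  })
  out <- tibble(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = strsplit(fix[, "ALT"], ",", fixed = TRUE),
    qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
    qd = info_num("QD"), fs = info_num("FS"), mq = info_num("MQ"),
    genotypes = genotypes)
  attr(out, "samples") <- samples
  out
}

# collapse one row of GT strings to haploid integer allele indices
parse_gt_row <- function(gts, het = "major") {
  alleles <- strsplit(gts, "[/|]")
  first <- vapply(alleles, function(a) {
    a <- a[a != "."]
    if (length(a) == 0) return(NA_integer_)
    u <- unique(as.integer(a))
    if (length(u) == 1) u else -1L  # -1 marks heterozygous
  }, integer(1))
  hets <- which(!is.na(first) & first == -1L)
  if (length(hets) > 0) {
    if (het == "missing") {
      first[hets] <- NA_integer_
    } else if (het == "first") {
      first[hets] <- vapply(alleles[hets],
                            function(a) as.integer(a[a != "."][1]), integer(1))
    } else {
      hom <- first[-hets]
      counts <- table(hom[!is.na(hom)])
      inform(sprintf("%d heterozygous call(s) collapsed to major allele",
                     length(hets)))
      first[hets] <- vapply(alleles[hets], function(a) {
        u <- unique(as.integer(a[a != "."]))
        cnt <- counts[as.character(u)]
        cnt[is.na(cnt)] <- 0
        u[order(-cnt, u)][1]
      }, integer(1))
    }
  }
  sn <- names(gts)
  if (!is.null(sn)) names(first) <- sn
  first
}

#' Apply GATK-style hard-filter criteria
#'
#' A variant fails when any of QUAL < `qual`, QD < `qd`, FS > `fs`,
#' MQ < `mq` holds (strict inequalities: a variant sitting exactly on a
#' threshold passes). Defaults are the strict organelle criteria
#' QUAL < 60, QD < 20.0, FS > 10.0, MQ < 30.0. Missing annotations are
#' fail-closed by default.
#'
#' @param variants Variant tibble (needs `qual`, `qd`, `fs`, `mq`).
#' @param qual,qd,fs,mq Thresholds.
#' @param missing `"fail"` (default) or `"pass"`: treatment of absent
#'   QUAL/QD/FS/MQ annotations.
#' @return `variants` with logical `pass_filter` and character
#'   `filter_reasons` (`NA` for passing variants) added.
#' @export
hard_filter <- function(variants, qual = 60, qd = 20, fs = 10, mq = 30,
                        missing = c("fail", "pass")) {
  missing <- match.arg(missing)
  miss_fails <- missing == "fail"
  chk <- function(x, bad, label) {
    r <- ifelse(is.na(x), miss_fails, bad)
    ifelse(r, ifelse(is.na(x), paste0(label, "_missing"), label), NA_character_)
  }
  reasons <- cbind(
    chk(variants$qual, variants$qual < qual, "LowQual"),
    chk(variants$qd, variants$qd < qd, "LowQD"),
    chk(variants$fs, variants$fs > fs, "HighFS"),
    chk(variants$mq, variants$mq < mq, "LowMQ"))
  reason_str <- apply(reasons, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) == 0) NA_character_ else paste(r, collapse = ";")
  })
  if (nrow(variants) == 0) reason_str <- character()
  variants |>
    mutate(pass_filter = is.na(reason_str), filter_reasons = reason_str)
}

#' Transition or transversion?
#'
#' @param ref,alt Single-base character vectors.
#' @return `"TRANSITION"` for A<->G and C<->T, `"TRANSVERSION"` otherwise.
#'   Identical bases are an error.
#' @export
classify_substitution <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(nchar(ref) != 1 | nchar(alt) != 1)) abort("single bases required")
  if (any(ref == alt)) abort("ref and alt are identical")
  purine <- c("A", "G")
  ifelse((ref %in% purine) == (alt %in% purine), "TRANSITION", "TRANSVERSION")
}

#' Minor allele frequency of one site
#'
#' Allele frequencies are computed over the non-missing sampled accessions
#' only — the reference genome is not a sample. The MAF is the frequency of
#' the second most frequent allele, so a site where every accession carries
#' the same allele (including a fixed difference from the reference) has
#' MAF 0.
#'
#' @param genotypes Integer vector of haploid allele indices (NA = missing),
#'   or a list of such vectors.
#' @return Numeric MAF in `[0, 0.5]` (vector when `genotypes` is a list);
#'   `NA` with a warning when every genotype is missing.
#' @export
minor_allele_frequency <- function(genotypes) {
  if (is.list(genotypes)) {
    return(vapply(genotypes, minor_allele_frequency, double(1)))
  }
  g <- genotypes[!is.na(genotypes)]
  if (length(g) == 0) {
    warn("site with all genotypes missing: MAF undefined")
    return(NA_real_)
  }
  freq <- sort(tabulate(g + 1L) / length(g), decreasing = TRUE)
  if (length(freq) < 2) 0 else freq[2]
}

#' Type, biallelic flag, substitution class and MAF for each variant
#'
#' @param variants Variant tibble.
#' @return `variants` with `var_type` (`"SNP"` iff ref and every alt are
#'   single bases, else `"INDEL"`), `biallelic`, `subst_type` (`NA` except
#'   for biallelic SNPs) and `maf` columns added.
#' @export
classify_variants <- function(variants) {
  if (nrow(variants) == 0) {
    return(variants |> mutate(var_type = character(), biallelic = logical(),
                              subst_type = character(), maf = double()))
  }
  is_snp <- nchar(variants$ref) == 1 &
    vapply(variants$alt, function(a) all(nchar(a) == 1), logical(1))
  biallelic <- lengths(variants$alt) == 1
  subst <- rep(NA_character_, nrow(variants))
  idx <- which(is_snp & biallelic)
  if (length(idx) > 0) {
    subst[idx] <- classify_substitution(
      variants$ref[idx], vapply(variants$alt[idx], `[`, character(1), 1))
  }
  variants |>
    mutate(var_type = ifelse(is_snp, "SNP", "INDEL"),
           biallelic = biallelic,
           subst_type = subst,
           maf = minor_allele_frequency(variants$genotypes))
}

#' Merge per-accession variant sets into one site-by-sample table
#'
#' Takes the union of sites across accessions (all called against the same
#' reference); at each site, alternate alleles are deduplicated in
#' first-seen order and genotype indices are recoded accordingly. Accessions
#' with no record at a site are genotyped as reference (default) or missing.
#' QUAL/QD/FS/MQ of a merged site are the means of the per-accession values,
#' making the merge independent of input order.
#'
#' @param variant_list Named or unnamed list of variant tibbles (each with a
#'   `samples` attribute; unnamed single-sample sets get `acc<i>` names).
#' @param absent `"ref"` (default) or `"missing"`: genotype for accessions
#'   lacking a record at a merged site.
#' @return Merged variant tibble with all samples in each `genotypes` entry.
#' @export
merge_accessions <- function(variant_list, absent = c("ref", "missing")) {
  absent <- match.arg(absent)
  fill <- if (absent == "ref") 0L else NA_integer_
  samp_of <- lapply(seq_along(variant_list), function(i) {
    s <- attr(variant_list[[i]], "samples")
    if (is.null(s) || length(s) == 0) s <- paste0("acc", i)
    s
  })
  all_samples <- unlist(samp_of)
  if (anyDuplicated(all_samples)) {
    all_samples <- make.unique(all_samples)
    k <- 0
    for (i in seq_along(samp_of)) {
      samp_of[[i]] <- all_samples[k + seq_along(samp_of[[i]])]
      k <- k + length(samp_of[[i]])
    }
  }
  keyed <- list()
  for (i in seq_along(variant_list)) {
    vt <- variant_list[[i]]
    if (nrow(vt) == 0) next
    for (j in seq_len(nrow(vt))) {
      key <- paste(vt$chrom[j], vt$pos[j], sep = ":")
      gt <- vt$genotypes[[j]]
      if (length(gt) == 0) gt <- rep(1L, length(samp_of[[i]]))
      names(gt) <- samp_of[[i]]
      rec <- list(chrom = vt$chrom[j], pos = vt$pos[j], ref = vt$ref[j],
                  alt = vt$alt[[j]], qual = vt$qual[j], qd = vt$qd[j],
                  fs = vt$fs[j], mq = vt$mq[j], gt = gt)
      if (is.null(keyed[[key]])) {
        keyed[[key]] <- rec
      } else {
        prev <- keyed[[key]]
        if (!identical(prev$ref, rec$ref)) {
          abort(sprintf("conflicting REF alleles at %s:%d ('%s' vs '%s')",
                        rec$chrom, rec$pos, prev$ref, rec$ref))
        }
        new_alt <- union(prev$alt, rec$alt)
        recode <- match(rec$alt, new_alt)
        gt2 <- rec$gt
        pos_alt <- !is.na(gt2) & gt2 > 0
        gt2[pos_alt] <- recode[gt2[pos_alt]]
        prev$alt <- new_alt
        prev$gt <- c(prev$gt, gt2)
        for (fld in c("qual", "qd", "fs", "mq")) {
          # accumulate; averaged at output so the merge is order-independent
          prev[[fld]] <- c(prev[[fld]], rec[[fld]])
        }
        keyed[[key]] <- prev
      }
    }
  }
  if (length(keyed) == 0) {
    out <- tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = list(), qual = double(), qd = double(), fs = double(),
                  mq = double(), genotypes = list())
    attr(out, "samples") <- all_samples
    return(out)
  }
  recs <- unname(keyed)
  out <- tibble(
    chrom = vapply(recs, `[[`, character(1), "chrom"),
    pos = vapply(recs, `[[`, integer(1), "pos"),
    ref = vapply(recs, `[[`, character(1), "ref"),
    alt = lapply(recs, `[[`, "alt"),
    qual = vapply(recs, function(r) mean(r$qual), double(1)),
    qd = vapply(recs, function(r) mean(r$qd), double(1)),
    fs = vapply(recs, function(r) mean(r$fs), double(1)),
    mq = vapply(recs, function(r) mean(r$mq), double(1)),
    genotypes = lapply(recs, function(r) {
      g <- rep(fill, length(all_samples))
      names(g) <- all_samples
      g[names(r$gt)] <- r$gt
      g
    })) |>
    arrange(.data$chrom, .data$pos)
  attr(out, "samples") <- all_samples
  out
}

#' Transition/transversion summary
#'
#' Counts transitions and transversions over the biallelic, filter-passing
#' SNPs (multiallelic SNPs are excluded, as is conventional for Ts/Tv
#' summaries of population call sets).
#'
#' @param variants Variant tibble; `pass_filter` (if present) and
#'   `var_type`/`biallelic`/`subst_type` columns (added on the fly when
#'   absent) are honoured.
#' @return One-row tibble: `n_biallelic`, `transitions`, `transversions`,
#'   `ratio` (`NA` when there are no transversions), `ts_pct`, `tv_pct`.
#' @export
tstv_summary <- function(variants) {
  if (!"subst_type" %in% names(variants)) {
    variants <- classify_variants(variants)
  }
  if ("pass_filter" %in% names(variants)) {
    variants <- variants |> filter(.data$pass_filter)
  }
  bi <- variants |> filter(.data$var_type == "SNP", .data$biallelic)
  ts <- sum(bi$subst_type == "TRANSITION")
  tv <- sum(bi$subst_type == "TRANSVERSION")
  tibble(n_biallelic = nrow(bi), transitions = ts, transversions = tv,
         ratio = if (tv == 0) NA_real_ else ts / tv,
         ts_pct = if (nrow(bi) == 0) NA_real_ else 100 * ts / nrow(bi),
         tv_pct = if (nrow(bi) == 0) NA_real_ else 100 * tv / nrow(bi))
}

#' Write a variant table as VCF
#'
#' Emits a minimal, sorted, haploid-genotyped VCF 4.2 with the QD/FS/MQ INFO
#' annotations the hard filter consumes.
#'
#' @param variants Variant tibble.
#' @param path Output file.
#' @param genome Optional [annotated_genome] for the contig header line.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path, genome = NULL) {
  samples <- attr(variants, "samples")
  if (is.null(samples) && nrow(variants) > 0) {
    samples <- names(variants$genotypes[[1]])
  }
  if (is.null(samples)) samples <- character()
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=orgvar",
    if (!is.null(genome)) sprintf("##contig=<ID=%s,length=%d>",
                                  genome$seq_id, genome$length),
    '##INFO=<ID=QD,Number=1,Type=Float,Description="Quality by depth">',
    '##INFO=<ID=FS,Number=1,Type=Float,Description="Fisher strand bias">',
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(samples)) c("FORMAT", samples)), collapse = "\t"))
  body <- character(0)
  if (nrow(variants) > 0) {
    variants <- variants |> arrange(.data$chrom, .data$pos)
    num <- function(x) ifelse(is.na(x), ".", format(x, trim = TRUE,
                                                    scientific = FALSE))
    info <- sprintf("QD=%s;FS=%s;MQ=%s", num(variants$qd), num(variants$fs),
                    num(variants$mq))
    gt_str <- vapply(variants$genotypes, function(g) {
      paste(ifelse(is.na(g), ".", as.character(g)), collapse = "\t")
    }, character(1))
    body <- paste(
      variants$chrom, variants$pos, ".", variants$ref,
      vapply(variants$alt, paste, character(1), collapse = ","),
      num(variants$qual), ".", info,
      sep = "\t")
    if (length(samples)) body <- paste(body, "GT", gt_str, sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
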