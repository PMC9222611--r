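# Independent brute-force oracles and hand-built fixtures shared by the
# module and acceptance tests. These deliberately avoid the package's
# interval/partition internals: membership is decided by naive per-position
# scans so the two routes can disagree.

# amino acid of a codon under the standard code, straight from Biostrings
oracle_aa <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

# degeneracy class of one codon position by exhaustive substitution
oracle_degeneracy <- function(codon, codon_pos) {
  aa <- oracle_aa(codon)
  alt <- setdiff(c("A", "C", "G", "T"), substr(codon, codon_pos, codon_pos))
  preserved <- sum(vapply(alt, function(b) {
    mut <- codon
    substr(mut, codon_pos, codon_pos) <- b
    oracle_aa(mut) == aa
  }, logical(1)))
  c(`0` = 0L, `1` = 2L, `2` = 3L, `3` = 4L)[[as.character(preserved)]]
}

# naive membership masks + nested-ifelse precedence; site_classes provides
# the CDS site classes (shared input of both routes, as the CDS subdivision
# is upstream of the partition assignment being checked)
oracle_partition <- function(genome, site_classes, extra_repeats = NULL) {
  L <- genome$length
  f <- genome$features
  mask <- function(rows) {
    m <- rep(FALSE, L)
    for (i in seq_len(nrow(rows))) {
      s <- rows$start[i]; e <- rows$end[i]
      if (s <= e) m[s:e] <- TRUE else m[c(s:L, 1:e)] <- TRUE
    }
    m
  }
  cds_class <- rep(NA_character_, L)
  if (nrow(site_classes) > 0) cds_class[site_classes$pos] <- site_classes$class
  in_rrna <- mask(f[f$kind == "rRNA", ])
  in_trna <- mask(f[f$kind == "tRNA", ])
  in_pseudo <- mask(f[f$kind == "pseudogene", ])
  in_intron <- rep(FALSE, L)
  for (gid in unique(f$id[f$kind %in% c("CDS", "exon")])) {
    parts <- f[f$id == gid & f$kind %in% c("CDS", "exon"), ]
    if (any(parts$kind == "CDS")) parts <- parts[parts$kind == "CDS", ]
    gene <- f[f$id == gid & f$kind == "gene", ]
    span <- if (nrow(gene) > 0) {
      mask(gene[1, ])
    } else if (nrow(parts) > 1) {
      mask(tibble::tibble(start = min(parts$start), end = max(parts$end)))
    } else {
      rep(FALSE, L)
    }
    in_intron <- in_intron | (span & !mask(parts))
  }
  functional <- ifelse(
    !is.na(cds_class), cds_class,
    ifelse(in_rrna, "RRNA",
           ifelse(in_trna, "TRNA",
                  ifelse(in_pseudo, "PSEUDOGENE",
                         ifelse(in_intron, "INTRON", "INTERGENIC")))))
  reps <- f[f$kind == "repeat", c("start", "end")]
  if (!is.null(extra_repeats)) reps <- rbind(reps, extra_repeats)
  copy <- ifelse(mask(reps), "REPEAT", "SINGLE_COPY")
  list(functional = functional, copy_layer = copy)
}

# 100 bp toy genome: CDS [11,40] (valid ORF), rRNA [51,60], repeat [1,50]
toy_genome <- function() {
  mrna <- "ATGGCTGCCGCAGCGTTTAAACCCGGGTAA"  # M A A A A F K P G *
  seq <- paste0(strrep("T", 10), mrna, strrep("T", 10),
                strrep("C", 10), strrep("T", 40))
  feats <- tibble::tibble(
    id = c("g1", "g1", "rrn1", "rep1"),
    kind = c("gene", "CDS", "rRNA", "repeat"),
    strand = "+",
    start = c(11L, 11L, 51L, 1L),
    end = c(40L, 40L, 60L, 50L),
    part = 1L,
    phase = c(NA, 0L, NA, NA))
  annotated_genome(seq, seq_id = "toy", circular = TRUE, features = feats)
}

# variant-table builder for filter/Ts-Tv tests
make_variants <- function(ref, alt, pos = seq_along(ref), qual = 100,
                          qd = 25, fs = 5, mq = 40, genotypes = NULL) {
  n <- length(ref)
  if (is.null(genotypes)) {
    genotypes <- replicate(n, c(S1 = 0L, S2 = 1L), simplify = FALSE)
  }
  v <- tibble::tibble(
    chrom = "toy", pos = as.integer(pos), ref = ref,
    alt = lapply(alt, identity),
    qual = rep_len(qual, n), qd = rep_len(qd, n), fs = rep_len(fs, n),
    mq = rep_len(mq, n), genotypes = genotypes)
  attr(v, "samples") <- c("S1", "S2")
  v
}

# Lay out a partition from published per-category lengths (contiguous
# blocks, in the order given; the repeat layer occupies the last
# `repeat_len` positions, which fall inside the final functional block) and
# place the published SNP/indel counts inside their blocks. `repeat_snps` /
# `repeat_indels` of the final block's variants are placed inside the
# repeat zone. Returns the partition plus an assigned, classified variant
# table ready for compute_category_stats().
table_fixture <- function(fun_lengths, fun_snps, fun_indels = NULL,
                          repeat_len = 0, repeat_snps = 0,
                          repeat_indels = 0) {
  stopifnot(identical(names(fun_lengths), names(fun_snps)))
  if (is.null(fun_indels)) fun_indels <- setNames(rep(0L, length(fun_lengths)),
                                                  names(fun_lengths))
  L <- sum(fun_lengths)
  functional <- rep(names(fun_lengths), fun_lengths)
  copy <- rep("SINGLE_COPY", L)
  if (repeat_len > 0) copy[(L - repeat_len + 1):L] <- "REPEAT"
  part <- category_partition(functional, copy, seq_id = "published")
  offsets <- cumsum(c(0, unname(fun_lengths)))[seq_along(fun_lengths)]
  names(offsets) <- names(fun_lengths)
  last <- names(fun_lengths)[length(fun_lengths)]
  pos_snp <- integer(0); pos_ind <- integer(0)
  for (lb in names(fun_lengths)) {
    ns <- fun_snps[[lb]]; ni <- fun_indels[[lb]]
    if (lb == last) { ns <- ns - repeat_snps; ni <- ni - repeat_indels }
    # SNPs at the block start, indels after them; block sizes far exceed
    # the counts in every published table
    pos_snp <- c(pos_snp, offsets[[lb]] + seq_len(ns))
    pos_ind <- c(pos_ind, offsets[[lb]] + ns + seq_len(ni))
  }
  if (repeat_snps > 0) pos_snp <- c(pos_snp, L - seq_len(repeat_snps) + 1L)
  if (repeat_indels > 0) {
    pos_ind <- c(pos_ind, L - repeat_snps - seq_len(repeat_indels) + 1L)
  }
  v <- make_variants(
    ref = c(rep("A", length(pos_snp)), rep("AT", length(pos_ind))),
    alt = c(as.list(rep("G", length(pos_snp))),
            as.list(rep("A", length(pos_ind)))),
    pos = c(pos_snp, pos_ind))
  v <- assign_category(classify_variants(v), part)
  attr(v, "partition") <- part
  v
}

# small simulation config so generator-backed tests stay fast
small_cfg <- function(...) {
  sim_config(genome_length = 20000, n_samples = 10, seed = 42,
             n_cds = 4, n_rrna = 1, n_trna = 3, n_pseudogene = 1,
             n_repeat_pairs = 1, repeat_length_range = c(500, 900), ...)
}
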