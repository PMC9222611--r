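# Synthetic study generator: an annotated circular organelle genome, a
# population variant set with category-specific per-site mutation rates and
# GATK-style filter annotations, and per-site depth tables with implanted
# copy-number segments. Defaults emulate the magnitudes reported for real
# organelle population data: a few-hundred-kb circle, per-site SNP rates of
# ~4e-4 (nonsynonymous sites) to ~2e-3 (introns) with intergenic =
# synonymous (the neutral-baseline contrast), a 2:1 transition bias, and
# ~50x Poisson depth.

#' Simulation configuration
#'
#' @param genome_length Genome size, bp.
#' @param n_samples Number of sampled accessions.
#' @param seed Default seed used by the generators.
#' @param n_cds,cds_length_range Number of protein-coding genes and their
#'   coding-length range (bp; rounded to whole codons, start and stop codon
#'   included).
#' @param intron_fraction Probability a gene carries one intron.
#' @param intron_length_range Intron length range, bp.
#' @param n_rrna,rrna_length_range,n_trna,trna_length_range,n_pseudogene,pseudogene_length_range
#'   Counts and length ranges of the other feature kinds.
#' @param n_repeat_pairs,repeat_length_range Number of duplicated segment
#'   pairs and their length range; both copies are sequence-identical.
#' @param ir_length Length of an inverted-repeat pair (0 = none; set > 0 for
#'   a plastid-style genome). The two IR copies are reverse-complement
#'   identical.
#' @param mu Named per-site SNP probabilities, one per functional category.
#' @param indel_mu Named per-site indel probabilities.
#' @param tstv_bias Transition:transversion odds for simulated SNP alleles.
#' @param maf_law `"uniform_minor"`: alternate-allele carrier count uniform
#'   on `1..floor(n_samples/2)`; `"uniform"`: uniform on `1..n_samples`
#'   (allows fixed differences from the reference, MAF 0).
#' @param f_fail Fraction of variant sites drawn with one annotation that
#'   fails the hard filter.
#' @param multiallelic_prob Probability a SNP site receives a second
#'   alternate allele (exercises the Ts/Tv exclusion path).
#' @param indel_size_range Indel length range, bp.
#' @param mean_depth Background sequencing depth.
#' @param depth_noise `"poisson"` or `"none"` (exact step function).
#' @param cnv_segments Data frame `start`, `end`, `fold` of copy-number
#'   segments for [simulate_depth()]; `NULL` places one fold-2 and one
#'   fold-0.5 segment of 5 windows each.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome_length = 200000, n_samples = 20, seed = 1L,
                       n_cds = 30, cds_length_range = c(300, 1500),
                       intron_fraction = 0.4,
                       intron_length_range = c(100, 800),
                       n_rrna = 3, rrna_length_range = c(1200, 2900),
                       n_trna = 20, trna_length_range = c(70, 90),
                       n_pseudogene = 2,
                       pseudogene_length_range = c(400, 800),
                       n_repeat_pairs = 4,
                       repeat_length_range = c(800, 2500),
                       ir_length = 0,
                       mu = c(NONSYN_SITE = 4e-4, SYN_SITE = 9e-4,
                              RRNA = 1.2e-3, TRNA = 1.1e-3,
                              PSEUDOGENE = 1.1e-3, INTRON = 2.2e-3,
                              INTERGENIC = 9e-4),
                       indel_mu = c(NONSYN_SITE = 0, SYN_SITE = 0,
                                    RRNA = 2e-4, TRNA = 0, PSEUDOGENE = 0,
                                    INTRON = 3e-4, INTERGENIC = 5e-4),
                       tstv_bias = 2, maf_law = c("uniform_minor", "uniform"),
                       f_fail = 0.3, multiallelic_prob = 0,
                       indel_size_range = c(1, 5),
                       mean_depth = 50, depth_noise = c("poisson", "none"),
                       cnv_segments = NULL) {
  maf_law <- match.arg(maf_law)
  depth_noise <- match.arg(depth_noise)
  stopifnot(all(names(mu) %in% FUNCTIONAL_LEVELS),
            all(mu >= 0 & mu <= 1), all(indel_mu >= 0 & indel_mu <= 1),
            f_fail >= 0 && f_fail <= 1,
            multiallelic_prob >= 0 && multiallelic_prob <= 1,
            tstv_bias > 0, genome_length > 0, n_samples >= 1)
  if (is.null(cnv_segments)) {
    w <- 1000
    cnv_segments <- tibble(
      start = c(floor(0.3 * genome_length / w) * w + 1,
                floor(0.6 * genome_length / w) * w + 1),
      fold = c(2, 0.5))
    cnv_segments$end <- cnv_segments$start + 5 * w - 1
    cnv_segments <- cnv_segments[cnv_segments$end <= genome_length,
                                 c("start", "end", "fold")]
  }
  planned <- n_cds * (mean(cds_length_range) +
                        intron_fraction * mean(intron_length_range)) +
    n_rrna * mean(rrna_length_range) + n_trna * mean(trna_length_range) +
    n_pseudogene * mean(pseudogene_length_range) +
    2 * n_repeat_pairs * mean(repeat_length_range) + 2 * ir_length
  if (planned > 0.7 * genome_length) {
    abort(sprintf(
      "infeasible feature plan: ~%.0f bp of features on a %d bp genome",
      planned, genome_length))
  }
  keep <- setdiff(names(formals(sim_config)), "...")
  structure(mget(keep, envir = environment()), class = "sim_config")
}

SENSE_CODONS <- function(code = genetic_code()) {
  names(code)[code != "*" & names(code) != "ATG"]
}
STOP_CODONS <- c("TAA", "TAG", "TGA")

# non-overlapping placement on a linear occupancy map (1 bp margin)
make_placer <- function(genome_length) {
  occ <- logical(genome_length)
  function(len) {
    for (try in 1:2000) {
      s <- sample.int(genome_length - len + 1L, 1L)
      span <- seq.int(max(1L, s - 1L), min(genome_length, s + len))
      if (!any(occ[span])) {
        occ[span] <<- TRUE
        return(s)
      }
    }
    abort("could not place feature: genome too crowded")
  }
}

#' Generate an annotated organelle-like genome
#'
#' Random background sequence with planted features: protein-coding genes
#' that are valid ORFs (start codon, no internal stop, whole codons, some
#' with one intron), rRNA/tRNA/pseudogene features, exact duplicated repeat
#' pairs, and optionally a reverse-complement inverted-repeat pair.
#' Byte-identical output under the same seed.
#'
#' @param cfg A [sim_config()].
#' @param seed Seed; defaults to `cfg$seed`.
#' @return List: `genome` (an [annotated_genome] whose features include the
#'   repeat copies), `repeats` (tibble of repeat intervals), `ir` (tibble
#'   with rows `IRA`, `IRB`, or `NULL`).
#' @export
simulate_genome <- function(cfg, seed = cfg$seed) {
  withr::with_seed(seed, simulate_genome_impl(cfg))
}

simulate_genome_impl <- function(cfg) {
  L <- cfg$genome_length
  chars <- sample(BASES, L, replace = TRUE)
  place <- make_placer(L)
  feats <- list()
  sense <- SENSE_CODONS()

  ir <- NULL
  if (cfg$ir_length > 0) {
    s1 <- place(cfg$ir_length); s2 <- place(cfg$ir_length)
    seg <- chars[seq.int(s1, s1 + cfg$ir_length - 1L)]
    chars[seq.int(s2, s2 + cfg$ir_length - 1L)] <-
      rev(c(A = "T", C = "G", G = "C", T = "A")[seg])
    ir <- tibble(name = c("IRA", "IRB"), start = as.integer(c(s1, s2)),
                 end = as.integer(c(s1, s2) + cfg$ir_length - 1L))
    feats[[length(feats) + 1]] <- tibble(
      id = c("ira", "irb"), kind = "IR", strand = "+",
      start = ir$start, end = ir$end, part = 1L, phase = NA_integer_)
  }

  rng <- function(r) if (r[1] == r[2]) r[1] else sample(seq.int(r[1], r[2]), 1L)

  for (i in seq_len(cfg$n_cds)) {
    ncod <- max(3L, round(rng(cfg$cds_length_range) / 3))
    mrna <- c("ATG", sample(sense, ncod - 2L, replace = TRUE),
              sample(STOP_CODONS, 1L))
    coding <- unlist(strsplit(paste(mrna, collapse = ""), ""))
    clen <- length(coding)
    has_intron <- runif(1) < cfg$intron_fraction
    ilen <- if (has_intron) rng(cfg$intron_length_range) else 0L
    total <- clen + ilen
    s <- place(total)
    strand <- sample(c("+", "-"), 1L)
    gid <- sprintf("gene%02d", i)
    if (!has_intron) {
      seg <- if (strand == "+") coding else
        rev(c(A = "T", C = "G", G = "C", T = "A")[coding])
      chars[seq.int(s, s + clen - 1L)] <- seg
      parts <- tibble(id = gid, kind = "CDS", strand = strand,
                      start = s, end = s + clen - 1L, part = 1L, phase = 0L)
    } else {
      n1 <- sample.int(clen - 1L, 1L)
      c1 <- coding[seq_len(n1)]
      c2 <- coding[seq.int(n1 + 1L, clen)]
      n2 <- clen - n1
      phase2 <- (3L - n1 %% 3L) %% 3L
      if (strand == "+") {
        chars[seq.int(s, s + n1 - 1L)] <- c1
        chars[seq.int(s + n1 + ilen, s + total - 1L)] <- c2
        parts <- tibble(
          id = gid, kind = "CDS", strand = strand,
          start = c(s, s + n1 + ilen), end = c(s + n1 - 1L, s + total - 1L),
          part = 1:2, phase = c(0L, phase2))
      } else {
        rc <- function(x) rev(c(A = "T", C = "G", G = "C", T = "A")[x])
        chars[seq.int(s, s + n2 - 1L)] <- rc(c2)
        chars[seq.int(s + n2 + ilen, s + total - 1L)] <- rc(c1)
        parts <- tibble(
          id = gid, kind = "CDS", strand = strand,
          start = c(s + n2 + ilen, s), end = c(s + total - 1L, s + n2 - 1L),
          part = 1:2, phase = c(0L, phase2))
      }
    }
    feats[[length(feats) + 1]] <- bind_rows(
      tibble(id = gid, kind = "gene", strand = strand, start = s,
             end = s + total - 1L, part = 1L, phase = NA_integer_),
      parts)
  }

  plain <- function(n, range, kind, prefix) {
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      len <- rng(range)
      s <- place(len)
      rows[[i]] <- tibble(id = sprintf("%s%02d", prefix, i), kind = kind,
                          strand = sample(c("+", "-"), 1L), start = s,
                          end = s + len - 1L, part = 1L, phase = NA_integer_)
    }
    bind_rows(rows)
  }
  feats[[length(feats) + 1]] <- plain(cfg$n_rrna, cfg$rrna_length_range,
                                      "rRNA", "rrn")
  feats[[length(feats) + 1]] <- plain(cfg$n_trna, cfg$trna_length_range,
                                      "tRNA", "trn")
  feats[[length(feats) + 1]] <- plain(cfg$n_pseudogene,
                                      cfg$pseudogene_length_range,
                                      "pseudogene", "psi")

  rep_rows <- list()
  for (i in seq_len(cfg$n_repeat_pairs)) {
    len <- rng(cfg$repeat_length_range)
    s1 <- place(len); s2 <- place(len)
    chars[seq.int(s2, s2 + len - 1L)] <- chars[seq.int(s1, s1 + len - 1L)]
    rep_rows[[i]] <- tibble(
      id = sprintf("rep%02d%s", i, c("a", "b")), kind = "repeat",
      strand = "+", start = c(s1, s2), end = c(s1, s2) + len - 1L,
      part = 1L, phase = NA_integer_)
  }
  feats[[length(feats) + 1]] <- bind_rows(rep_rows)

  features <- bind_rows(feats) |>
    mutate(start = as.integer(.data$start), end = as.integer(.data$end),
           part = as.integer(.data$part)) |>
    arrange(.data$start, .data$id, .data$part)
  genome <- annotated_genome(paste(chars, collapse = ""), seq_id = "synth1",
                             circular = TRUE, features = features)
  list(genome = genome,
       repeats = features |> filter(.data$kind == "repeat") |>
         select("start", "end"),
       ir = ir)
}

#' Simulate a population variant set
#'
#' Every position becomes a SNP site independently with the per-site
#' probability of its functional category (and an indel site with the indel
#' probability; SNP wins when both fire). SNP alternate alleles follow the
#' configured transition:transversion odds; carrier counts follow the
#' allele-frequency law; QUAL/QD/FS/MQ are drawn so that an expected
#' fraction `f_fail` of sites fails the hard filter (one offending
#' annotation per failing site, chosen uniformly).
#'
#' @param genome An [annotated_genome] (typically from [simulate_genome()]).
#' @param partition Its `category_partition`.
#' @param cfg A [sim_config()].
#' @param seed Seed; defaults to `cfg$seed + 1`.
#' @return Variant tibble (the same shape [read_vcf_variants()] returns)
#'   with a `truth` attribute recording the generating parameters.
#' @export
simulate_variants <- function(genome, partition, cfg, seed = cfg$seed + 1L) {
  withr::with_seed(seed, simulate_variants_impl(genome, partition, cfg))
}

simulate_variants_impl <- function(genome, partition, cfg) {
  L <- genome$length
  lab <- as.character(partition$functional)
  mu_vec <- unname(cfg$mu[lab])
  mu_vec[is.na(mu_vec)] <- 0
  ind_vec <- unname(cfg$indel_mu[lab])
  ind_vec[is.na(ind_vec)] <- 0
  is_snp_site <- runif(L) < mu_vec
  is_indel_site <- runif(L) < ind_vec & !is_snp_site
  pos <- sort(c(which(is_snp_site), which(is_indel_site)))
  n <- cfg$n_samples
  samples <- sprintf("S%03d", seq_len(n))
  if (length(pos) == 0) {
    out <- tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = list(), qual = double(), qd = double(), fs = double(),
                  mq = double(), genotypes = list())
    attr(out, "samples") <- samples
    attr(out, "truth") <- sim_truth(cfg)
    return(out)
  }
  ts_of <- c(A = "G", G = "A", C = "T", T = "C")
  tv_of <- list(A = c("C", "T"), G = c("C", "T"),
                C = c("A", "G"), T = c("A", "G"))
  p_ts <- cfg$tstv_bias / (cfg$tstv_bias + 1)
  max_minor <- max(1L, floor(n / 2))
  recs <- vector("list", length(pos))
  for (k in seq_along(pos)) {
    p <- pos[k]
    base <- substr(genome$sequence, p, p)
    if (base == "N") next
    if (is_snp_site[p]) {
      ref <- base
      alt <- if (runif(1) < p_ts) ts_of[[base]] else sample(tv_of[[base]], 1L)
      if (runif(1) < cfg$multiallelic_prob) {
        alt <- c(alt, sample(setdiff(setdiff(BASES, base), alt), 1L))
      }
    } else {
      k_len <- sample(seq.int(cfg$indel_size_range[1],
                              cfg$indel_size_range[2]), 1L)
      if (runif(1) < 0.5 || p + k_len > L) {  # insertion
        ref <- base
        alt <- paste0(base, paste(sample(BASES, k_len, replace = TRUE),
                                  collapse = ""))
      } else {                                # deletion
        ref <- substr(genome$sequence, p, p + k_len)
        alt <- base
      }
    }
    m <- if (cfg$maf_law == "uniform_minor") sample.int(max_minor, 1L)
         else sample.int(n, 1L)
    gt <- integer(n)
    carriers <- sample.int(n, m)
    gt[carriers] <- 1L
    if (length(alt) == 2 && m >= 2) gt[carriers[1]] <- 2L
    names(gt) <- samples
    fails <- runif(1) < cfg$f_fail
    qual <- runif(1, 60, 2000); qd <- runif(1, 20, 40)
    fs <- runif(1, 0, 10); mq <- runif(1, 30, 60)
    if (fails) {
      fld <- sample(4L, 1L)
      if (fld == 1L) qual <- runif(1, 10, 59.9)
      if (fld == 2L) qd <- runif(1, 5, 19.9)
      if (fld == 3L) fs <- runif(1, 10.1, 40)
      if (fld == 4L) mq <- runif(1, 10, 29.9)
    }
    recs[[k]] <- tibble(chrom = genome$seq_id, pos = p, ref = ref,
                        alt = list(alt), qual = round(qual, 2),
                        qd = round(qd, 2), fs = round(fs, 2),
                        mq = round(mq, 2), genotypes = list(gt))
  }
  out <- bind_rows(recs)
  attr(out, "samples") <- samples
  attr(out, "truth") <- sim_truth(cfg)
  out
}

sim_truth <- function(cfg) {
  list(mu = cfg$mu, indel_mu = cfg$indel_mu, f_fail = cfg$f_fail,
       tstv_bias = cfg$tstv_bias, n_samples = cfg$n_samples,
       maf_law = cfg$maf_law, mean_depth = cfg$mean_depth,
       cnv_segments = cfg$cnv_segments)
}

#' Simulate a per-site depth table
#'
#' Depth is drawn around `mean_depth * fold`, with `fold` 1 outside the
#' configured copy-number segments.
#'
#' @param genome_length Genome length (or an [annotated_genome]).
#' @param cfg A [sim_config()].
#' @param seed Seed; defaults to `cfg$seed + 2`.
#' @param seq_id Sequence name for the table.
#' @return Tibble `seq_id`, `pos`, `depth` over all positions.
#' @export
simulate_depth <- function(genome_length, cfg, seed = cfg$seed + 2L,
                           seq_id = "synth1") {
  if (inherits(genome_length, "annotated_genome")) {
    seq_id <- genome_length$seq_id
    genome_length <- genome_length$length
  }
  seg <- cfg$cnv_segments
  fold <- rep(1, genome_length)
  if (!is.null(seg) && nrow(seg) > 0) {
    covered <- logical(genome_length)
    for (i in seq_len(nrow(seg))) {
      idx <- seq.int(seg$start[i], min(seg$end[i], genome_length))
      if (any(covered[idx])) abort("overlapping CNV segments")
      covered[idx] <- TRUE
      fold[idx] <- seg$fold[i]
    }
  }
  lambda <- cfg$mean_depth * fold
  depth <- withr::with_seed(seed, {
    if (cfg$depth_noise == "poisson") rpois(genome_length, lambda)
    else as.integer(round(lambda))
  })
  tibble(seq_id = seq_id, pos = seq_len(genome_length), depth = depth)
}

#' Write a depth table as a 3-column TSV
#'
#' @param depth Tibble `seq_id`, `pos`, `depth`.
#' @param path Output file.
#' @param omit_zero Omit zero-depth positions (default `TRUE`, matching the
#'   producing tool's behaviour that [read_depth()] undoes).
#' @return `path`, invisibly.
#' @export
write_depth_tsv <- function(depth, path, omit_zero = TRUE) {
  if (omit_zero) depth <- depth |> filter(.data$depth > 0)
  readr::write_tsv(depth, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write intervals as BED
#'
#' @param intervals Tibble with `start`, `end` (1-based inclusive) and
#'   optionally `name`.
#' @param path Output file.
#' @param seq_id Sequence name for column 1.
#' @return `path`, invisibly.
#' @export
write_intervals_bed <- function(intervals, path, seq_id = "synth1") {
  nm <- if ("name" %in% names(intervals)) intervals$name
        else paste0("iv", seq_len(nrow(intervals)))
  writeLines(sprintf("%s\t%d\t%d\t%s", seq_id, intervals$start - 1L,
                     intervals$end, nm), path)
  invisible(path)
}

#' Generate a complete runnable input set on disk
#'
#' One call writes everything the pipeline consumes — FASTA, GFF3, repeat
#' (and optional IR) BED, a multi-sample VCF, per-sample depth TSVs — plus
#' `truth.json` recording the generating parameters for recovery tests.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param seed Base seed; defaults to `cfg$seed`. Component generators use
#'   fixed offsets from it.
#' @param n_depth_samples Number of per-sample depth tables (default 3).
#' @return Invisibly, a list with the file `paths` and the in-memory
#'   `genome`, `partition`, `variants`, `repeats`, `ir` and `truth` objects.
#' @export
simulate_dataset <- function(cfg, dir, seed = cfg$seed, n_depth_samples = 3) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- simulate_genome(cfg, seed = seed)
  genome <- sim$genome
  partition <- build_partition(genome)
  if (!is.null(sim$ir)) {
    partition <- assign_structural_regions(
      partition, c(sim$ir$start[1], sim$ir$end[1]),
      c(sim$ir$start[2], sim$ir$end[2]), genome = genome)
  }
  variants <- simulate_variants(genome, partition, cfg, seed = seed + 1L)
  paths <- c(
    fasta = file.path(dir, "genome.fasta"),
    gff = file.path(dir, "genome.gff3"),
    repeats = file.path(dir, "repeats.bed"),
    vcf = file.path(dir, "variants.vcf"),
    truth = file.path(dir, "truth.json"))
  write_genome_fasta(genome, paths[["fasta"]])
  write_features_gff(genome, paths[["gff"]])
  write_intervals_bed(sim$repeats, paths[["repeats"]], seq_id = genome$seq_id)
  if (!is.null(sim$ir)) {
    paths <- c(paths, ir = file.path(dir, "ir.bed"))
    write_intervals_bed(sim$ir, paths[["ir"]], seq_id = genome$seq_id)
  }
  write_variants_vcf(variants, paths[["vcf"]], genome = genome)
  for (i in seq_len(n_depth_samples)) {
    p <- file.path(dir, sprintf("depth_S%d.tsv", i))
    names(p) <- sprintf("depth_S%d", i)
    paths <- c(paths, p)
    write_depth_tsv(simulate_depth(genome, cfg, seed = seed + 1L + i), p)
  }
  truth <- attr(variants, "truth")
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(paths = paths, genome = genome, partition = partition,
                 variants = variants, repeats = sim$repeats, ir = sim$ir,
                 truth = truth))
}
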