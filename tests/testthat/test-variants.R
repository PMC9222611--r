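test_that("hard filter applies the strict criteria with exact boundaries", {
  v <- make_variants(
    ref = rep("A", 6), alt = as.list(rep("G", 6)),
    qual = c(100, 59.9, 60, 100, 100, 100),
    qd = c(25, 25, 20, 19.9, 25, 25),
    fs = c(5, 5, 10, 5, 10.1, 5),
    mq = c(40, 40, 30, 40, 40, 29.9))
  out <- hard_filter(v)
  # thresholds are strict inequalities: values exactly on them pass
  expect_equal(out$pass_filter, c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_match(out$filter_reasons[2], "LowQual")
  expect_match(out$filter_reasons[4], "LowQD")
  expect_match(out$filter_reasons[5], "HighFS")
  expect_match(out$filter_reasons[6], "LowMQ")
  # missing annotations fail closed by default, pass when configured open
  vm <- make_variants("A", list("G"), qd = NA_real_)
  expect_false(hard_filter(vm)$pass_filter)
  expect_match(hard_filter(vm)$filter_reasons, "LowQD_missing")
  expect_true(hard_filter(vm, missing = "pass")$pass_filter)
})

test_that("relaxing any threshold never removes a passing variant", {
  set.seed(31)
  v <- make_variants(
    ref = rep("A", 200), alt = as.list(rep("G", 200)),
    qual = runif(200, 0, 200), qd = runif(200, 0, 45),
    fs = runif(200, 0, 30), mq = runif(200, 0, 70))
  base <- hard_filter(v)$pass_filter
  for (i in 1:20) {
    relaxed <- hard_filter(v,
      qual = 60 - runif(1, 0, 60), qd = 20 - runif(1, 0, 20),
      fs = 10 + runif(1, 0, 30), mq = 30 - runif(1, 0, 30))$pass_filter
    expect_true(all(relaxed[base]))
  }
})

test_that("substitution typing enumerates 4 transitions and 8 transversions", {
  expect_equal(classify_substitution("A", "G"), "TRANSITION")
  expect_equal(classify_substitution("A", "C"), "TRANSVERSION")
  pairs <- expand.grid(ref = c("A", "C", "G", "T"), alt = c("A", "C", "G", "T"),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  types <- classify_substitution(pairs$ref, pairs$alt)
  expect_equal(sum(types == "TRANSITION"), 4)
  expect_equal(sum(types == "TRANSVERSION"), 8)
  expect_error(classify_substitution("A", "A"), "identical")
})

test_that("MAF is the second-largest sample allele frequency", {
  expect_equal(minor_allele_frequency(c(rep(0L, 8), rep(1L, 2))), 0.2)
  # fixed difference from the reference: every sample alternate, MAF 0
  expect_equal(minor_allele_frequency(rep(1L, 10)), 0)
  expect_equal(minor_allele_frequency(c(rep(0L, 5), rep(1L, 5))), 0.5)
  # missing genotypes are excluded from the denominator
  expect_equal(minor_allele_frequency(c(0L, 0L, 1L, NA, NA)), 1 / 3)
  expect_warning(res <- minor_allele_frequency(c(NA_integer_, NA_integer_)),
                 "missing")
  expect_true(is.na(res))
})

test_that("MAF is invariant under ref/alt relabeling and bounded by 0.5", {
  set.seed(7)
  for (i in 1:50) {
    g <- sample(c(0L, 1L, NA), 20, replace = TRUE, prob = c(0.5, 0.4, 0.1))
    if (all(is.na(g))) next
    m <- suppressWarnings(minor_allele_frequency(g))
    swapped <- ifelse(is.na(g), NA_integer_, 1L - g)
    expect_equal(suppressWarnings(minor_allele_frequency(swapped)), m)
    expect_gte(m, 0); expect_lte(m, 0.5)
  }
})

test_that("variant typing separates SNPs, indels and multiallelic sites", {
  v <- make_variants(
    ref = c("A", "A", "AT", "A", "C"),
    alt = list("G", c("G", "T"), "A", "ATT", "T"))
  out <- classify_variants(v)
  expect_equal(out$var_type, c("SNP", "SNP", "INDEL", "INDEL", "SNP"))
  expect_equal(out$biallelic, c(TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(out$subst_type,
               c("TRANSITION", NA, NA, NA, "TRANSITION"))
})

test_that("Ts/Tv summary counts biallelic SNPs only", {
  v <- classify_variants(make_variants(
    ref = c("A", "C", "A", "A"),
    alt = list("G", "T", "C", c("G", "C"))))
  s <- tstv_summary(v)
  # the triallelic site is excluded
  expect_equal(s$n_biallelic, 3)
  expect_equal(s$transitions, 2)
  expect_equal(s$transversions, 1)
  expect_equal(s$ratio, 2)
  expect_equal(s$ts_pct + s$tv_pct, 100)
  # conservation: ts + tv always equals the biallelic SNP count
  expect_equal(s$transitions + s$transversions, s$n_biallelic)
  # no transversions: ratio undefined
  s0 <- tstv_summary(classify_variants(make_variants("A", list("G"))))
  expect_true(is.na(s0$ratio))
})

test_that("accession merging unions sites and recodes alleles", {
  v1 <- make_variants(ref = c("A", "C"), alt = list("G", "T"), pos = c(10, 20),
                      genotypes = list(c(a1 = 1L), c(a1 = 1L)))
  attr(v1, "samples") <- "a1"
  v2 <- make_variants(ref = c("C", "T"), alt = list("A", "G"), pos = c(20, 30),
                      genotypes = list(c(a2 = 1L), c(a2 = 1L)))
  attr(v2, "samples") <- "a2"
  m <- merge_accessions(list(v1, v2))
  expect_equal(m$pos, c(10L, 20L, 30L))
  # absent accessions hold the reference allele by default
  expect_equal(m$genotypes[[1]], c(a1 = 1L, a2 = 0L))
  # same site, different alts: two alternates, no longer biallelic
  expect_equal(m$alt[[2]], c("T", "A"))
  expect_equal(m$genotypes[[2]], c(a1 = 1L, a2 = 2L))
  expect_false(classify_variants(m)$biallelic[2])
  # missing-genotype policy
  m2 <- merge_accessions(list(v1, v2), absent = "missing")
  expect_true(is.na(m2$genotypes[[1]][["a2"]]))
  # conflicting reference alleles are an error naming the position
  v3 <- make_variants(ref = "G", alt = list("A"), pos = 20,
                      genotypes = list(c(a3 = 1L)))
  attr(v3, "samples") <- "a3"
  expect_error(merge_accessions(list(v1, v3)), "20")
})

test_that("merging is independent of accession order", {
  set.seed(13)
  # ref is a deterministic function of position, as for a shared reference
  ref_at <- function(pos) c("A", "C", "G", "T")[pos %% 4 + 1]
  accs <- lapply(1:4, function(i) {
    n <- 8
    pos <- sample(100, n)
    v <- make_variants(
      ref = ref_at(pos),
      alt = lapply(seq_len(n), function(j)
        sample(setdiff(c("A", "C", "G", "T"), ref_at(pos[j])), 1)),
      pos = pos,
      genotypes = replicate(n, setNames(sample(0:1, 1), paste0("s", i)),
                            simplify = FALSE))
    attr(v, "samples") <- paste0("s", i)
    v
  })
  m1 <- merge_accessions(accs)
  m2 <- merge_accessions(rev(accs))
  expect_equal(m1$pos, m2$pos)
  expect_equal(m1$qual, m2$qual)
  for (k in seq_len(nrow(m1))) {
    expect_equal(m1$genotypes[[k]][sort(names(m1$genotypes[[k]]))] > 0,
                 m2$genotypes[[k]][sort(names(m2$genotypes[[k]]))] > 0)
  }
})

test_that("VCF writing and reading round-trip, including haploid genotypes", {
  v <- make_variants(
    ref = c("A", "C", "AT"), alt = list("G", c("T", "G"), "A"),
    pos = c(5, 9, 14),
    qual = c(100.5, 80, 200), qd = c(25.1, 30, 35), fs = c(0.5, 2, 9.9),
    mq = c(40, 50, 60),
    genotypes = list(c(S1 = 0L, S2 = 1L), c(S1 = 2L, S2 = NA),
                     c(S1 = 1L, S2 = 1L)))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_variants_vcf(v, path)
  back <- read_vcf_variants(path)
  expect_equal(back$pos, v$pos)
  expect_equal(back$ref, v$ref)
  expect_equal(back$alt, v$alt)
  expect_equal(back$qual, v$qual)
  expect_equal(back$qd, v$qd)
  expect_equal(back$fs, v$fs)
  expect_equal(back$mq, v$mq)
  expect_equal(back$genotypes, v$genotypes)
  expect_equal(attr(back, "samples"), c("S1", "S2"))
})

test_that("diploid-encoded and heterozygous genotypes collapse to haploid", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=QD,Number=1,Type=Float,Description="x">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="x">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", "s4", sep = "\t"),
    paste("c1", "10", ".", "A", "G", "99", ".", "QD=30", "GT",
          "1/1", "0/0", "0/1", "1/1", sep = "\t"),
    paste("c1", "20", ".", "C", "T", "99", ".", "QD=30", "GT",
          "0", "1", ".", "0/1", sep = "\t")), path)
  v <- suppressMessages(read_vcf_variants(path))
  # site 10: homozygous collapse 1,0; het resolved to the major allele (1)
  expect_equal(unname(v$genotypes[[1]]), c(1L, 0L, 1L, 1L))
  # site 20: haploid calls kept, '.' missing, het -> major among {0,1} tie -> 0
  expect_equal(unname(v$genotypes[[2]]), c(0L, 1L, NA, 0L))
  v2 <- read_vcf_variants(path, het = "missing")
  expect_true(is.na(v2$genotypes[[1]][[3]]))
})
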