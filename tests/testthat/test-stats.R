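test_that("variants take the partition labels of their positions", {
  g <- toy_genome()
  part <- build_partition(g)
  v <- make_variants(ref = c("C", "T", "T"), alt = list("T", "C", "TA"),
                     pos = c(55, 45, 15))
  out <- assign_category(classify_variants(v), part)
  expect_equal(out$functional, c("RRNA", "INTERGENIC", "NONSYN_SITE"))
  # the repeat interval [1, 50] covers positions 45 and 15 but not 55
  expect_equal(out$copy_layer, c("SINGLE_COPY", "REPEAT", "REPEAT"))
  expect_error(
    assign_category(make_variants("A", list("G"), pos = 999), part),
    "outside")
})

test_that("effect mode reclassifies coding SNPs by amino-acid change", {
  g <- toy_genome()  # CDS starts at 11: ATG GCT GCC GCA GCG TTT ...
  part <- build_partition(g)
  sc <- cds_site_classes(g)
  # pos 16 is GCT codon position 3 (ref T): G/C/A all keep Ala -> synonymous
  # pos 15 is GCT codon position 2: any change is nonsynonymous
  v <- classify_variants(make_variants(
    ref = c("T", "C"), alt = list("A", "G"), pos = c(16, 15)))
  by_site <- assign_category(v, part, cds_mode = "site")
  by_eff <- assign_category(v, part, cds_mode = "effect", site_classes = sc)
  expect_equal(by_site$functional, c("SYN_SITE", "NONSYN_SITE"))
  expect_equal(by_eff$functional, c("SYN_SITE", "NONSYN_SITE"))
  # TTT -> TTC (both Phe) at codon pos 3 (pos 28): a 2-fold site, so the two
  # modes disagree: site class NONSYN (not 4-fold), effect synonymous
  v2 <- classify_variants(make_variants("T", list("C"), pos = 28))
  expect_equal(assign_category(v2, part, cds_mode = "site")$functional,
               "NONSYN_SITE")
  expect_equal(
    assign_category(v2, part, cds_mode = "effect",
                    site_classes = sc)$functional,
    "SYN_SITE")
  # non-CDS rows are identical between modes
  v3 <- classify_variants(make_variants("C", list("T"), pos = 55))
  expect_equal(assign_category(v3, part, cds_mode = "site")$functional,
               assign_category(v3, part, cds_mode = "effect",
                               site_classes = sc)$functional)
})

test_that("category stats reproduce a naive per-variant recount", {
  sim <- simulate_genome(small_cfg(), seed = 12)
  g <- sim$genome
  part <- build_partition(g)
  cfg <- small_cfg()
  cfg$mu[] <- 2e-3  # enough variants on a small genome
  cfg$indel_mu[] <- 5e-4
  v <- simulate_variants(g, part, cfg, seed = 77)
  v <- assign_category(classify_variants(hard_filter(v)), part)
  st <- compute_category_stats(v, part)
  lens <- category_lengths(part)
  vp <- v[v$pass_filter, ]
  # naive recount per functional label
  for (lb in c("NONSYN_SITE", "SYN_SITE", "RRNA", "TRNA", "PSEUDOGENE",
               "INTRON", "INTERGENIC")) {
    nb_snp <- sum(as.character(part$functional[vp$pos]) == lb &
                    vp$var_type == "SNP")
    nb_ind <- sum(as.character(part$functional[vp$pos]) == lb &
                    vp$var_type == "INDEL")
    row <- st[st$label == lb, ]
    expect_equal(row$snps, nb_snp, label = lb)
    expect_equal(row$indels, nb_ind, label = lb)
    expect_equal(row$sites, lens$sites[lens$label == lb], label = lb)
    if (row$sites > 0) expect_equal(row$snps_per_site, nb_snp / row$sites)
    if (nb_snp > 0) {
      expect_equal(row$snp_maf_mean,
                   mean(vp$maf[as.character(part$functional[vp$pos]) == lb &
                                 vp$var_type == "SNP"]))
    }
  }
  # conservation: functional rows sum to the Total row; copy rows too
  fun <- st[st$layer == "functional" & st$label != "PROTEIN_CODING", ]
  tot <- st[st$label == "TOTAL", ]
  expect_equal(sum(fun$snps), tot$snps)
  expect_equal(sum(fun$indels), tot$indels)
  expect_equal(sum(fun$sites), tot$sites)
  cop <- st[st$layer == "copy", ]
  expect_equal(sum(cop$snps), tot$snps)
  expect_equal(sum(cop$sites), tot$sites)
  # protein-coding row is the merge of the two site classes
  pc <- st[st$label == "PROTEIN_CODING", ]
  expect_equal(pc$snps, sum(st$snps[st$label %in% c("NONSYN_SITE",
                                                    "SYN_SITE")]))
  # zero-variant categories report rate 0 and MAF NA
  if (any(fun$snps == 0)) {
    z <- fun[fun$snps == 0 & fun$sites > 0, ]
    expect_true(all(z$snps_per_site == 0))
    expect_true(all(is.na(z$snp_maf_mean)))
  }
})

test_that("structural stratification restricts denominators per stratum", {
  cfg <- small_cfg(ir_length = 1500)
  sim <- simulate_genome(cfg, seed = 21)
  g <- sim$genome
  part <- build_partition(g)
  part <- assign_structural_regions(part, unlist(sim$ir[1, c("start", "end")]),
                                    unlist(sim$ir[2, c("start", "end")]),
                                    genome = g)
  cfg$mu[] <- 2e-3
  v <- assign_category(classify_variants(hard_filter(
    simulate_variants(g, part, cfg, seed = 5))), part)
  ss <- structural_stats(v, part)
  st <- compute_category_stats(v, part)
  # per-category sites over LSC+SSC+IR equal the whole-genome category sites
  for (lb in c("NONSYN_SITE", "SYN_SITE", "RRNA", "INTRON", "INTERGENIC")) {
    expect_equal(sum(ss$sites[ss$label == lb]),
                 st$sites[st$layer == "functional" & st$label == lb],
                 label = lb)
  }
  expect_equal(sum(ss$snps[ss$label == "TOTAL"]), st$snps[st$label == "TOTAL"])
  # IRA and IRB are merged into one IR stratum
  expect_equal(sort(unique(ss$stratum)), c("IR", "LSC", "SSC"))
  ir_sites <- ss$sites[ss$stratum == "IR" & ss$label == "TOTAL"]
  expect_equal(ir_sites, sum(part$structural %in% c("IRA", "IRB")))
  # a mitochondrial (no-IR) partition yields an empty result with a warning
  part0 <- build_partition(g)
  expect_warning(empty <- structural_stats(v, part0), "no structural")
  expect_equal(nrow(empty), 0)
})

test_that("single variants land in the right stratum cell", {
  g <- annotated_genome(strrep("A", 1000))
  part <- assign_structural_regions(build_partition(g),
                                    c(101L, 200L), c(701L, 800L))
  # one SNP in the SSC arc (positions 801-1000 + 1-100), intergenic
  v <- assign_category(classify_variants(
    make_variants("A", list("G"), pos = 900)), part)
  ss <- structural_stats(v, part)
  expect_equal(ss$snps[ss$stratum == "SSC" & ss$label == "INTERGENIC"], 1)
  expect_equal(sum(ss$snps), 2)  # the INTERGENIC row and the TOTAL row
  expect_true(all(ss$snps[ss$stratum != "SSC"] == 0))
})

test_that("neutrality ratios compare abundances to the intergenic baseline", {
  st <- tibble::tibble(
    layer = "functional",
    label = c("SYN_SITE", "NONSYN_SITE", "INTERGENIC"),
    sites = c(10000L, 30000L, 100000L),
    snps = c(9L, 12L, 90L),
    snps_per_site = snps / sites,
    snp_maf_mean = NA_real_, indels = 0L, indels_per_site = 0,
    indel_maf_mean = NA_real_)
  nr <- neutrality_ratios(st)
  expect_equal(nr$ratio[nr$label == "SYN_SITE"], 1)
  expect_equal(nr$classification[nr$label == "SYN_SITE"], "near baseline")
  expect_equal(nr$classification[nr$label == "NONSYN_SITE"], "below baseline")
  # doubling all counts leaves ratios unchanged
  st2 <- st; st2$snps <- st2$snps * 2L
  st2$snps_per_site <- st2$snps / st2$sites
  expect_equal(neutrality_ratios(st2)$ratio, nr$ratio)
  # zero-abundance category: ratio 0; zero intergenic: all NA
  st3 <- st; st3$snps[1] <- 0L; st3$snps_per_site[1] <- 0
  expect_equal(neutrality_ratios(st3)$ratio[1], 0)
  st4 <- st; st4$snps_per_site[3] <- 0
  expect_true(all(is.na(neutrality_ratios(st4)$ratio)))
})

test_that("report TSVs round-trip and percentages are consistent", {
  g <- toy_genome()
  part <- build_partition(g)
  v <- assign_category(classify_variants(make_variants(
    ref = c("C", "T"), alt = list("T", "G"), pos = c(55, 45))), part)
  st <- compute_category_stats(v, part)
  ts <- tstv_summary(v)
  dir <- withr::local_tempdir()
  paths <- write_report(st, ts, dir)
  back <- readr::read_tsv(paths[["functional"]], show_col_types = FALSE)
  expect_equal(back$snps, st$snps)
  expect_equal(back$snps_per_site, round(st$snps_per_site, 4))
  tstv_back <- readr::read_tsv(paths[["tstv"]], show_col_types = FALSE)
  expect_equal(tstv_back$ts_pct + tstv_back$tv_pct, 100)
  # empty variant set: header-only stats still write and re-parse
  v0 <- assign_category(classify_variants(make_variants(
    character(), list())), part)
  st0 <- compute_category_stats(v0, part)
  p0 <- write_report(st0, NULL, dir)
  expect_equal(sum(readr::read_tsv(p0[["functional"]],
                                   show_col_types = FALSE)$snps), 0)
})
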