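# Per-category variant statistics: the machine-readable form of the
# SNP/indel abundance tables (counts, per-site rates, mean MAF) for
# functional categories, copy layer, structural strata, and neutrality
# ratios against the intergenic baseline.

FUNCTIONAL_ROW_ORDER <- c("PROTEIN_CODING", "NONSYN_SITE", "SYN_SITE",
                          "RRNA", "TRNA", "PSEUDOGENE", "INTRON",
                          "INTERGENIC")

#' Assign partition categories to variants
#'
#' SNPs take the labels of their position; indels take the labels of their
#' VCF anchor position. With `cds_mode = "site"` (default), a coding SNP
#' keeps the site class of its position — the numerator then matches the
#' denominator's definition, keeping abundance a true per-site rate. With
#' `cds_mode = "effect"`, a coding SNP is `SYN_SITE` only if every alternate
#' allele leaves the encoded amino acid unchanged.
#'
#' @param variants Variant tibble.
#' @param partition A `category_partition`.
#' @param cds_mode `"site"` or `"effect"`.
#' @param site_classes Output of [cds_site_classes()]; required for
#'   `cds_mode = "effect"` (or supply `genome`).
#' @param genome [annotated_genome] used to compute `site_classes` when
#'   needed.
#' @param code A [genetic_code()].
#' @return `variants` with `functional`, `copy_layer`, `structural` columns.
#' @export
assign_category <- function(variants, partition,
                            cds_mode = c("site", "effect"),
                            site_classes = NULL, genome = NULL,
                            code = genetic_code()) {
  cds_mode <- match.arg(cds_mode)
  if (nrow(variants) > 0 &&
      any(variants$pos < 1 | variants$pos > partition$length)) {
    abort("variant position outside the genome")
  }
  functional <- as.character(partition$functional[variants$pos])
  if (cds_mode == "effect") {
    if (is.null(site_classes)) {
      if (is.null(genome)) abort("effect mode needs site_classes or genome")
      site_classes <- cds_site_classes(genome, code = code)
    }
    if (!"var_type" %in% names(variants)) {
      variants <- classify_variants(variants)
    }
    in_cds <- which(functional %in% c("NONSYN_SITE", "SYN_SITE") &
                      variants$var_type == "SNP")
    if (length(in_cds) > 0) {
      sc <- site_classes[match(variants$pos[in_cds], site_classes$pos), ]
      for (j in seq_along(in_cds)) {
        i <- in_cds[j]
        if (is.na(sc$codon[j])) next  # phase overhang: keep site label
        syn <- vapply(variants$alt[[i]], function(a) {
          b <- if (sc$strand[j] == "-") revcomp(a) else a
          mut <- sc$codon[j]
          substr(mut, sc$codon_pos[j], sc$codon_pos[j]) <- b
          !is.na(code[mut]) && code[mut] == code[sc$codon[j]] &&
            code[sc$codon[j]] != "*"
        }, logical(1))
        functional[i] <- if (all(syn)) "SYN_SITE" else "NONSYN_SITE"
      }
    }
  }
  variants |>
    mutate(functional = functional,
           copy_layer = as.character(partition$copy_layer[variants$pos]),
           structural = as.character(partition$structural[variants$pos]))
}

category_stats_rows <- function(variants, sites_by_label, maf_fun = mean) {
  row_for <- function(label, sites, vsub) {
    snp_tbl <- vsub |> filter(.data$var_type == "SNP")
    ind_tbl <- vsub |> filter(.data$var_type == "INDEL")
    n_snp <- nrow(snp_tbl)
    n_ind <- nrow(ind_tbl)
    tibble(
      label = label, sites = as.integer(sites),
      snps = n_snp,
      snps_per_site = if (sites > 0) n_snp / sites else NA_real_,
      snp_maf_mean = if (n_snp > 0) maf_fun(snp_tbl$maf) else NA_real_,
      indels = n_ind,
      indels_per_site = if (sites > 0) n_ind / sites else NA_real_,
      indel_maf_mean = if (n_ind > 0) maf_fun(ind_tbl$maf) else NA_real_)
  }
  bind_rows(lapply(names(sites_by_label), function(lb) {
    vsub <- switch(lb,
      PROTEIN_CODING = variants |>
        filter(.data$functional %in% c("NONSYN_SITE", "SYN_SITE")),
      SINGLE_COPY = variants |> filter(.data$copy_layer == "SINGLE_COPY"),
      REPEAT = variants |> filter(.data$copy_layer == "REPEAT"),
      TOTAL = variants,
      variants |> filter(.data$functional == lb))
    row_for(lb, sites_by_label[[lb]], vsub)
  }))
}

#' Per-category SNP/indel abundance table
#'
#' One row per functional category, plus a merged `PROTEIN_CODING` row
#' (nonsynonymous + synonymous sites), the copy-layer rows, and a `TOTAL`
#' row. Rates are kept at full precision here; [write_report()] rounds to
#' 4 decimals for the printed tables.
#'
#' @param variants Variant tibble with categories assigned
#'   ([assign_category()]); filter-failing variants (column `pass_filter`)
#'   are excluded.
#' @param partition The `category_partition` the variants were assigned
#'   against; supplies every `sites` denominator.
#' @param maf_fun Aggregator for the per-category MAF column (default
#'   `mean`; e.g. `median`).
#' @return Tibble of class `category_stats`: `layer`, `label`, `sites`,
#'   `snps`, `snps_per_site`, `snp_maf_mean`, `indels`, `indels_per_site`,
#'   `indel_maf_mean`.
#' @export
compute_category_stats <- function(variants, partition, maf_fun = mean) {
  variants <- prep_stats_variants(variants)
  lens <- category_lengths(partition)
  fl <- setNames(lens$sites[lens$layer == "functional"],
                 lens$label[lens$layer == "functional"])
  cl <- setNames(lens$sites[lens$layer == "copy"],
                 lens$label[lens$layer == "copy"])
  sites_by_label <- c(
    list(PROTEIN_CODING = unname(fl["NONSYN_SITE"] + fl["SYN_SITE"])),
    as.list(fl[FUNCTIONAL_ROW_ORDER[-1]]),
    list(SINGLE_COPY = unname(cl["SINGLE_COPY"]),
         REPEAT = unname(cl["REPEAT"]),
         TOTAL = partition$length))
  out <- category_stats_rows(variants, sites_by_label, maf_fun) |>
    mutate(layer = dplyr::case_when(
      label %in% c("SINGLE_COPY", "REPEAT") ~ "copy",
      label == "TOTAL" ~ "total",
      TRUE ~ "functional"), .before = 1)
  class(out) <- c("category_stats", class(out))
  out
}

prep_stats_variants <- function(variants) {
  if (!"var_type" %in% names(variants)) variants <- classify_variants(variants)
  if ("pass_filter" %in% names(variants)) {
    variants <- variants |> filter(.data$pass_filter)
  }
  if (!"functional" %in% names(variants)) {
    abort("variants lack category columns; run assign_category() first")
  }
  variants
}

#' Structural-region-stratified abundance table
#'
#' The plastid stratification: within each of LSC, SSC and IR (the two IR
#' copies merged into one stratum), per-functional-category site counts and
#' variant statistics, with denominators restricted to the stratum.
#'
#' @inheritParams compute_category_stats
#' @return Tibble of class `category_stats` with a leading `stratum` column;
#'   empty (with a warning) when the partition has no structural labels.
#' @export
structural_stats <- function(variants, partition, maf_fun = mean) {
  if (all(partition$structural == "NONE")) {
    warn("no structural regions assigned; empty result")
    out <- tibble(stratum = character(), label = character(),
                  sites = integer(), snps = integer(),
                  snps_per_site = double(), snp_maf_mean = double(),
                  indels = integer(), indels_per_site = double(),
                  indel_maf_mean = double())
    return(out)
  }
  variants <- prep_stats_variants(variants)
  strat_of <- c(LSC = "LSC", SSC = "SSC", IRA = "IR", IRB = "IR",
                NONE = NA_character_)
  pos_strat <- strat_of[as.character(partition$structural)]
  var_strat <- strat_of[variants$structural]
  out <- bind_rows(lapply(c("LSC", "SSC", "IR"), function(st) {
    in_st <- !is.na(pos_strat) & pos_strat == st
    fl <- table(factor(as.character(partition$functional)[in_st],
                       levels = FUNCTIONAL_LEVELS))
    sites_by_label <- c(
      list(PROTEIN_CODING = unname(fl[["NONSYN_SITE"]] + fl[["SYN_SITE"]])),
      as.list(as.integer(fl)[match(FUNCTIONAL_ROW_ORDER[-1],
                                   FUNCTIONAL_LEVELS)] |>
                setNames(FUNCTIONAL_ROW_ORDER[-1])),
      list(TOTAL = sum(in_st)))
    vsub <- variants[!is.na(var_strat) & var_strat == st, ]
    category_stats_rows(vsub, sites_by_label, maf_fun) |>
      mutate(stratum = st, .before = 1)
  }))
  class(out) <- c("category_stats", class(out))
  out
}

#' SNP abundance relative to the intergenic baseline
#'
#' Intergenic sites are conventionally taken as the neutral reference:
#' a category whose per-site SNP abundance matches the intergenic abundance
#' behaves neutrally; a lower ratio suggests purifying selection, a higher
#' one relaxed constraint or positive selection.
#'
#' @param stats A functional `category_stats` table
#'   ([compute_category_stats()]).
#' @param bands Two breakpoints: ratios below the first are
#'   `"below baseline"`, above the second `"above baseline"`, else
#'   `"near baseline"`.
#' @return Tibble: `label`, `snps_per_site`, `ratio`, `classification`.
#'   All ratios are `NA` when the intergenic abundance is 0.
#' @export
neutrality_ratios <- function(stats, bands = c(0.8, 1.25)) {
  fun <- stats |> filter(.data$layer == "functional")
  base <- fun$snps_per_site[fun$label == "INTERGENIC"]
  if (length(base) != 1) abort("stats table lacks an INTERGENIC row")
  ratio <- if (is.na(base) || base == 0) rep(NA_real_, nrow(fun))
           else fun$snps_per_site / base
  tibble(label = fun$label, snps_per_site = fun$snps_per_site, ratio = ratio,
         classification = dplyr::case_when(
           is.na(ratio) ~ NA_character_,
           ratio < bands[1] ~ "below baseline",
           ratio > bands[2] ~ "above baseline",
           TRUE ~ "near baseline"))
}

#' Write the report tables
#'
#' Writes the functional abundance table, the structural stratification (when
#' supplied) and the Ts/Tv summary as TSVs, with per-site rates and MAFs
#' rounded to 4 decimals and the Ts/Tv ratio and percentages to 2, matching
#' conventional reporting of these statistics.
#'
#' @param stats Functional `category_stats` table.
#' @param tstv One-row [tstv_summary()] tibble, or `NULL`.
#' @param dir Output directory (created if needed).
#' @param structural Optional [structural_stats()] table.
#' @return Named character vector of the files written, invisibly.
#' @export
write_report <- function(stats, tstv = NULL, dir = ".", structural = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  round_cols <- function(df) {
    df |> mutate(dplyr::across(
      dplyr::any_of(c("snps_per_site", "snp_maf_mean", "indels_per_site",
                      "indel_maf_mean")), ~ round(.x, 4)))
  }
  paths <- c(functional = file.path(dir, "category_stats.tsv"))
  readr::write_tsv(round_cols(stats), paths[["functional"]], progress = FALSE)
  if (!is.null(structural)) {
    paths <- c(paths, structural = file.path(dir, "structural_stats.tsv"))
    readr::write_tsv(round_cols(structural), paths[["structural"]],
                     progress = FALSE)
  }
  if (!is.null(tstv)) {
    paths <- c(paths, tstv = file.path(dir, "tstv_summary.tsv"))
    readr::write_tsv(
      tstv |> mutate(ratio = round(.data$ratio, 2),
                     ts_pct = round(.data$ts_pct, 2),
                     tv_pct = round(.data$tv_pct, 2)),
      paths[["tstv"]], progress = FALSE)
  }
  invisible(paths)
}
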