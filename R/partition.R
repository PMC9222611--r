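# Three-layer per-position partition of the genome:
#   functional : NONSYN_SITE/SYN_SITE/RRNA/TRNA/PSEUDOGENE/INTRON/INTERGENIC
#   copy_layer : SINGLE_COPY/REPEAT
#   structural : LSC/SSC/IRA/IRB/NONE (plastids only)
# The layers are orthogonal: each sums to the genome length on its own, which
# is what lets repeat and functional statistics share one denominator total.

#' Construct a category partition from per-position labels
#'
#' Low-level constructor, useful for rebuilding a partition from an exported
#' per-position table, or for laying out a partition whose category lengths
#' are known (e.g. from a published summary table) without the underlying
#' genome. [build_partition()] is the usual entry point.
#'
#' @param functional Character/factor vector of per-position functional
#'   labels (see `FUNCTIONAL_LEVELS`: NONSYN_SITE, SYN_SITE, RRNA, TRNA,
#'   PSEUDOGENE, INTRON, INTERGENIC).
#' @param copy_layer Per-position SINGLE_COPY/REPEAT labels; default all
#'   SINGLE_COPY.
#' @param structural Per-position LSC/SSC/IRA/IRB/NONE labels; default all
#'   NONE.
#' @param seq_id Sequence identifier.
#' @param circular Is the genome circular?
#' @return An object of class `category_partition`.
#' @export
category_partition <- function(functional, copy_layer = NULL,
                               structural = NULL, seq_id = "seq1",
                               circular = TRUE) {
  L <- length(functional)
  if (is.null(copy_layer)) copy_layer <- rep("SINGLE_COPY", L)
  if (is.null(structural)) structural <- rep("NONE", L)
  if (length(copy_layer) != L || length(structural) != L) {
    abort("all three layers must have the same length")
  }
  chk <- function(x, levels, layer) {
    x <- as.character(x)
    if (anyNA(x) || !all(x %in% levels)) {
      abort(sprintf("invalid %s label(s): %s", layer,
                    paste(unique(setdiff(x, levels)), collapse = ", ")))
    }
    factor(x, levels = levels)
  }
  structure(
    list(seq_id = seq_id, length = L, circular = circular,
         functional = chk(functional, FUNCTIONAL_LEVELS, "functional"),
         copy_layer = chk(copy_layer, COPY_LEVELS, "copy"),
         structural = chk(structural, STRUCTURAL_LEVELS, "structural"),
         precedence = NULL),
    class = "category_partition")
}

#' Build the per-position category partition
#'
#' Assigns every genomic position exactly one functional label and one copy
#' label. Functional labels are assigned by precedence (default
#' CDS > rRNA > tRNA > pseudogene > intron > intergenic): when features
#' overlap, the higher-precedence category keeps the position. CDS positions
#' are subdivided into `NONSYN_SITE`/`SYN_SITE` site classes. The copy layer
#' marks positions covered by any repeat interval as `REPEAT`, independently
#' of the functional layer. The structural layer starts all-`NONE`; see
#' [assign_structural_regions()].
#'
#' Assignment is canonical: features are processed in a deterministic order,
#' so permuting the input feature table never changes the result.
#'
#' @param genome An [annotated_genome] with features.
#' @param site_classes Output of [cds_site_classes()]; computed from `genome`
#'   with `mode` when `NULL`.
#' @param repeats Optional extra repeat intervals, a tibble with `start`,
#'   `end` (1-based inclusive), merged with `kind == "repeat"` features.
#' @param precedence Functional precedence, highest first. `"CDS"` stands for
#'   the pair of site classes.
#' @param mode Site-classification mode passed to [cds_site_classes()] when
#'   `site_classes` is `NULL` (hard modes only).
#' @param code A [genetic_code()].
#' @return An object of class `category_partition`.
#' @export
build_partition <- function(genome, site_classes = NULL, repeats = NULL,
                            precedence = c("CDS", "RRNA", "TRNA",
                                           "PSEUDOGENE", "INTRON"),
                            mode = c("fourfold", "any_syn"),
                            code = genetic_code()) {
  mode <- match.arg(mode)
  L <- genome$length
  if (is.null(site_classes)) {
    site_classes <- cds_site_classes(genome, mode = mode, code = code)
  }
  functional <- rep("INTERGENIC", L)
  feats <- genome$features
  kind_of <- c(CDS = "CDS", RRNA = "rRNA", TRNA = "tRNA",
               PSEUDOGENE = "pseudogene", INTRON = "intron")
  # assign lowest precedence first so higher precedence overwrites
  for (cat in rev(precedence)) {
    if (cat == "INTRON") {
      iv <- derive_introns(genome)
    } else if (cat == "CDS") {
      if (nrow(site_classes) > 0) functional[site_classes$pos] <- site_classes$class
      next
    } else {
      iv <- feats |> filter(.data$kind == kind_of[[cat]]) |>
        arrange(.data$id, .data$start)
    }
    if (nrow(iv) == 0) next
    pos <- unlist(lapply(seq_len(nrow(iv)), function(i)
      interval_positions(iv$start[i], iv$end[i], L, genome$circular)))
    functional[pos] <- c(CDS = NA, RRNA = "RRNA", TRNA = "TRNA",
                         PSEUDOGENE = "PSEUDOGENE", INTRON = "INTRON")[[cat]]
  }
  copy_layer <- rep("SINGLE_COPY", L)
  rep_iv <- feats |> filter(.data$kind == "repeat") |>
    select("start", "end")
  if (!is.null(repeats) && nrow(repeats) > 0) {
    rep_iv <- bind_rows(rep_iv, repeats |> select("start", "end"))
  }
  if (nrow(rep_iv) > 0) {
    pos <- unlist(lapply(seq_len(nrow(rep_iv)), function(i)
      interval_positions(rep_iv$start[i], rep_iv$end[i], L, genome$circular)))
    copy_layer[unique(pos)] <- "REPEAT"
  }
  structure(
    list(seq_id = genome$seq_id, length = L, circular = genome$circular,
         functional = factor(functional, levels = FUNCTIONAL_LEVELS),
         copy_layer = factor(copy_layer, levels = COPY_LEVELS),
         structural = factor(rep("NONE", L), levels = STRUCTURAL_LEVELS),
         precedence = precedence),
    class = "category_partition")
}

#' @export
print.category_partition <- function(x, ...) {
  cat(sprintf("<category_partition> %s: %s bp\n", x$seq_id,
              format(x$length, big.mark = ",")))
  print(category_lengths(x))
  invisible(x)
}

#' Label plastid structural regions (LSC/SSC/IR)
#'
#' Marks the two inverted-repeat intervals `IRA`/`IRB`; of the two remaining
#' arcs of the circle, the longer is labelled `LSC` and the shorter `SSC`.
#' Mitochondrial partitions simply keep `NONE` everywhere by never calling
#' this.
#'
#' @param partition A `category_partition`.
#' @param ir_a,ir_b Length-2 integer vectors `c(start, end)`, 1-based
#'   inclusive; `ir_a`/`ir_b` must be disjoint. Unequal lengths only draw a
#'   warning (the caller vouches for reverse-complement equivalence).
#' @param genome Optional [annotated_genome]; when given, the
#'   reverse-complement identity of the two IRs is checked (warning only).
#' @return The partition with the structural layer assigned.
#' @export
assign_structural_regions <- function(partition, ir_a = NULL, ir_b = NULL,
                                      genome = NULL) {
  L <- partition$length
  structural <- rep("NONE", L)
  if (is.null(ir_a) || is.null(ir_b)) {
    partition$structural <- factor(structural, levels = STRUCTURAL_LEVELS)
    return(partition)
  }
  pa <- interval_positions(ir_a[1], ir_a[2], L, partition$circular)
  pb <- interval_positions(ir_b[1], ir_b[2], L, partition$circular)
  if (length(intersect(pa, pb)) > 0) abort("IR intervals overlap")
  if (length(pa) != length(pb)) {
    warn(sprintf("IR lengths differ (%d vs %d bp); labels assigned anyway",
                 length(pa), length(pb)))
  }
  if (!is.null(genome) && length(pa) == length(pb)) {
    sa <- interval_sequence(genome, ir_a[1], ir_a[2])
    sb <- interval_sequence(genome, ir_b[1], ir_b[2])
    if (!identical(sa, revcomp(sb))) {
      warn("IR intervals are not reverse-complement identical")
    }
  }
  structural[pa] <- "IRA"
  structural[pb] <- "IRB"
  sc <- which(structural == "NONE")
  if (length(sc) > 0) {
    arcs <- runs_to_intervals(sc)
    # on a circle, merge the run touching position 1 with the run touching L
    if (partition$circular && nrow(arcs) > 1 &&
        arcs$start[1] == 1L && arcs$end[nrow(arcs)] == L) {
      arcs$id[nrow(arcs)] <- "wrap"
      arcs$id[1] <- "wrap"
    }
    arcs$id[is.na(arcs$id)] <- paste0("arc", seq_len(sum(is.na(arcs$id))))
    lens <- arcs |> group_by(.data$id) |>
      summarise(n = sum(.data$end - .data$start + 1L)) |> arrange(-.data$n)
    if (nrow(lens) > 2) {
      warn("more than two single-copy arcs; largest labelled LSC, rest SSC")
    }
    lsc_id <- lens$id[1]
    for (i in seq_len(nrow(arcs))) {
      lab <- if (arcs$id[i] == lsc_id) "LSC" else "SSC"
      structural[seq.int(arcs$start[i], arcs$end[i])] <- lab
    }
  }
  partition$structural <- factor(structural, levels = STRUCTURAL_LEVELS)
  partition
}

#' Per-category site counts (the denominators of every abundance)
#'
#' @param partition A `category_partition`.
#' @return Tibble with columns `layer`, `label`, `sites`. Within each layer,
#'   the counts sum to the genome length (the structural layer reports `NONE`
#'   only when no IRs were assigned).
#' @export
category_lengths <- function(partition) {
  f <- as.data.frame(table(partition$functional), stringsAsFactors = FALSE)
  cc <- as.data.frame(table(partition$copy_layer), stringsAsFactors = FALSE)
  s <- as.data.frame(table(partition$structural), stringsAsFactors = FALSE)
  out <- bind_rows(
    tibble(layer = "functional", label = f[[1]], sites = as.integer(f[[2]])),
    tibble(layer = "copy", label = cc[[1]], sites = as.integer(cc[[2]])),
    tibble(layer = "structural", label = s[[1]], sites = as.integer(s[[2]])))
  if (all(partition$structural == "NONE")) {
    out <- out |> filter(!(.data$layer == "structural" & .data$label != "NONE"))
  }
  out
}

#' @export
tidy.category_partition <- function(x, ...) {
  tibble(position = seq_len(x$length),
         functional = as.character(x$functional),
         copy_layer = as.character(x$copy_layer),
         structural = as.character(x$structural))
}

#' @export
glance.category_partition <- function(x, ...) {
  tibble(seq_id = x$seq_id, length = x$length,
         cds_sites = sum(x$functional %in% c("NONSYN_SITE", "SYN_SITE")),
         repeat_sites = sum(x$copy_layer == "REPEAT"),
         has_structural = any(x$structural != "NONE"))
}

#' Export a partition to TSV
#'
#' Writes the per-position table (position, functional, copy_layer,
#' structural) and, alongside it, a `<path>.summary.tsv` matching
#' [category_lengths()].
#'
#' @param partition A `category_partition`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_partition_tsv <- function(partition, path) {
  readr::write_tsv(tidy(partition), path, progress = FALSE)
  readr::write_tsv(category_lengths(partition),
                   paste0(path, ".summary.tsv"), progress = FALSE)
  invisible(path)
}
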