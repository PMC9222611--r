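# Codon degeneracy and synonymous/nonsynonymous site classification.
#
# A codon position is d-fold degenerate when d of the three possible
# single-base substitutions at that position preserve the amino acid
# (0 preserved -> "0-fold", 1 -> "2-fold", 2 -> "3-fold", 3 -> "4-fold").
# Plant organelle CDSs use the standard genetic code (NCBI table 1), the
# package default.

BASES <- c("A", "C", "G", "T")

#' Genetic code table
#'
#' @param table_id NCBI translation table number (default 1, the standard
#'   code used by plant organelle protein-coding genes).
#' @return Named character vector of 64 codons to one-letter amino acids,
#'   `"*"` for stop, with attribute `table_id`.
#' @export
genetic_code <- function(table_id = 1L) {
  gc <- Biostrings::getGeneticCode(as.character(table_id))
  structure(gc[!is.na(names(gc))], table_id = as.integer(table_id))
}

# 64 x 3 matrix: number of amino-acid-preserving substitutions at each codon
# position; NA rows for stop codons. Memoised per code.
degeneracy_matrix <- function(code = genetic_code()) {
  codons <- names(code)
  m <- matrix(NA_integer_, nrow = length(codons), ncol = 3,
              dimnames = list(codons, NULL))
  for (cd in codons) {
    if (code[[cd]] == "*") next
    for (p in 1:3) {
      alt <- setdiff(BASES, substr(cd, p, p))
      mut <- vapply(alt, function(b) {
        x <- cd; substr(x, p, p) <- b; code[[x]]
      }, character(1))
      m[cd, p] <- sum(mut == code[[cd]])
    }
  }
  m
}

PRESERVED_TO_FOLD <- c(`0` = 0L, `1` = 2L, `2` = 3L, `3` = 4L)

#' Degeneracy class of a codon position
#'
#' @param codon Character vector of 3-mers (A/C/G/T only, sense codons).
#' @param codon_pos Position within the codon, 1-3.
#' @param code A [genetic_code()].
#' @return Integer vector of degeneracy classes: 0, 2, 3 or 4 (0-fold,
#'   2-fold, 3-fold, 4-fold).
#' @export
codon_degeneracy <- function(codon, codon_pos, code = genetic_code()) {
  codon <- toupper(codon)
  if (any(!codon %in% names(code))) {
    abort(sprintf("not a valid codon: %s",
                  paste(setdiff(codon, names(code)), collapse = ", ")))
  }
  if (any(!codon_pos %in% 1:3)) abort("codon_pos must be 1, 2 or 3")
  if (any(code[codon] == "*")) {
    abort(sprintf("stop codon has no degeneracy class: %s",
                  paste(unique(codon[code[codon] == "*"]), collapse = ", ")))
  }
  m <- degeneracy_matrix(code)
  preserved <- m[cbind(match(codon, rownames(m)), codon_pos)]
  unname(PRESERVED_TO_FOLD[as.character(preserved)])
}

#' Classify the sites of an in-frame CDS
#'
#' Partitions every position of a coding sequence into synonymous
#' (`SYN_SITE`) and nonsynonymous (`NONSYN_SITE`) site classes from codon
#' degeneracy, or assigns Nei-Gojobori-style fractional synonymous weights.
#'
#' Hard modes: `fourfold` calls a position synonymous only when it is 4-fold
#' degenerate; `any_syn` when it is at least 2-fold degenerate. In both, the
#' two classes partition the sequence length exactly. `fractional` assigns
#' each position the weight (preserving substitutions)/3, so weights within a
#' codon sum to its synonymous site count.
#'
#' A terminal stop codon is kept in the partition (class `NONSYN_SITE`,
#' weight 0) so that site-class lengths sum to the annotated CDS length.
#' Codons containing N are classed `NONSYN_SITE` with a warning.
#'
#' @param cds_sequence In-frame coding sequence (length a multiple of 3).
#' @param mode `"fourfold"` (default), `"any_syn"` or `"fractional"`.
#' @param code A [genetic_code()].
#' @param strict Error on internal stop codons (default `TRUE`); otherwise
#'   warn and class their positions `NONSYN_SITE`.
#' @return Tibble with one row per CDS position: `cds_pos`, `codon`,
#'   `codon_pos`, `degeneracy`, `syn_weight`, `class`.
#' @export
classify_cds_sites <- function(cds_sequence,
                               mode = c("fourfold", "any_syn", "fractional"),
                               code = genetic_code(), strict = TRUE) {
  mode <- match.arg(mode)
  cds_sequence <- toupper(cds_sequence)
  n <- nchar(cds_sequence)
  if (n %% 3 != 0) abort("CDS length is not a multiple of 3")
  n_codon <- n %/% 3
  codons <- substring(cds_sequence, 3 * seq_len(n_codon) - 2, 3 * seq_len(n_codon))
  is_stop <- !is.na(match(codons, names(code))) & code[codons] == "*"
  internal_stop <- is_stop & seq_len(n_codon) < n_codon
  if (any(internal_stop)) {
    msg <- sprintf("internal stop codon at codon %s",
                   paste(which(internal_stop), collapse = ", "))
    if (strict) abort(msg) else warn(msg)
  }
  ambiguous <- !codons %in% names(code)
  if (any(ambiguous)) {
    warn(sprintf("%d codon(s) with ambiguous bases classed NONSYN_SITE",
                 sum(ambiguous)))
  }
  m <- degeneracy_matrix(code)
  idx <- match(codons, rownames(m))
  preserved <- m[rep(idx, each = 3) +
                   (rep(1:3, n_codon) - 1L) * nrow(m)]
  preserved[is.na(preserved)] <- 0L  # stop or ambiguous codons
  fold <- unname(PRESERVED_TO_FOLD[as.character(preserved)])
  cls <- switch(mode,
    fourfold = ifelse(fold == 4L, "SYN_SITE", "NONSYN_SITE"),
    any_syn = ifelse(fold >= 2L, "SYN_SITE", "NONSYN_SITE"),
    fractional = NA_character_)
  tibble(
    cds_pos = seq_len(n),
    codon = rep(codons, each = 3),
    codon_pos = rep(1:3, n_codon),
    degeneracy = fold,
    syn_weight = preserved / 3,
    class = cls)
}

#' Translate a coding sequence
#'
#' @param cds_sequence In-frame coding sequence (length a multiple of 3).
#' @param code A [genetic_code()].
#' @param strict Error on internal stop codons (default `TRUE`).
#' @return Amino-acid string, `"*"` for stop, `"X"` for ambiguous codons.
#' @export
translate_cds <- function(cds_sequence, code = genetic_code(), strict = TRUE) {
  cds_sequence <- toupper(cds_sequence)
  n <- nchar(cds_sequence)
  if (n %% 3 != 0) abort("CDS length is not a multiple of 3")
  n_codon <- n %/% 3
  codons <- substring(cds_sequence, 3 * seq_len(n_codon) - 2, 3 * seq_len(n_codon))
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  if (strict && any(aa == "*" & seq_len(n_codon) < n_codon)) {
    abort("internal stop codon in CDS")
  }
  paste(aa, collapse = "")
}

#' Per-gene synonymous/nonsynonymous site classes in genome coordinates
#'
#' Reconstructs each protein-coding gene's in-frame CDS from its parts
#' (strand-aware transcription order, reverse-complementing minus-strand
#' parts, honouring the phase of the first part), classifies its sites with
#' [classify_cds_sites()], and maps each site class back to the genomic
#' position it came from. Genes whose phase-adjusted length is not a multiple
#' of 3 are flagged non-canonical: complete codons are classified and
#' leftover positions are classed `NONSYN_SITE`.
#'
#' When two genes' CDS parts overlap, the gene that comes first in canonical
#' order (by id, then start) keeps the position; a warning is raised.
#'
#' @param genome An [annotated_genome] with CDS features.
#' @inheritParams classify_cds_sites
#' @return Tibble with one row per CDS genomic position: `gene`, `pos`,
#'   `strand`, `codon`, `codon_pos`, `degeneracy`, `syn_weight`, `class`,
#'   `canonical`.
#' @export
cds_site_classes <- function(genome,
                             mode = c("fourfold", "any_syn", "fractional"),
                             code = genetic_code(), strict = TRUE) {
  mode <- match.arg(mode)
  cds <- genome$features |> filter(.data$kind == "CDS")
  if (nrow(cds) == 0) {
    return(tibble(gene = character(), pos = integer(), strand = character(),
                  codon = character(), codon_pos = integer(),
                  degeneracy = integer(), syn_weight = double(),
                  class = character(), canonical = logical()))
  }
  genes <- cds |> distinct(.data$id, .data$start) |>
    group_by(.data$id) |> summarise(start = min(.data$start)) |>
    arrange(.data$id, .data$start)
  res <- vector("list", nrow(genes))
  for (k in seq_len(nrow(genes))) {
    gid <- genes$id[k]
    p <- cds |> filter(.data$id == gid) |> arrange(.data$part)
    minus <- p$strand[1] == "-"
    part_seq <- vapply(seq_len(nrow(p)), function(i) {
      s <- interval_sequence(genome, p$start[i], p$end[i])
      if (minus) revcomp(s) else s
    }, character(1))
    part_pos <- lapply(seq_len(nrow(p)), function(i) {
      pos <- interval_positions(p$start[i], p$end[i], genome$length,
                                genome$circular)
      if (minus) rev(pos) else pos
    })
    full_seq <- paste(part_seq, collapse = "")
    full_pos <- unlist(part_pos)
    phase <- p$phase[1]
    if (is.na(phase)) phase <- 0L
    n <- nchar(full_seq)
    frame_len <- n - phase
    n_complete <- frame_len %/% 3L
    canonical <- phase == 0L && frame_len %% 3L == 0L
    in_frame <- substr(full_seq, phase + 1L, phase + 3L * n_complete)
    sites <- classify_cds_sites(in_frame, mode = mode, code = code,
                                strict = strict)
    cls <- rep("NONSYN_SITE", n)      # phase/overhang positions
    degv <- rep(NA_integer_, n)
    wt <- rep(0, n)
    cp <- rep(NA_integer_, n)
    cod <- rep(NA_character_, n)
    at <- phase + seq_len(3L * n_complete)
    if (mode != "fractional") cls[at] <- sites$class
    degv[at] <- sites$degeneracy
    wt[at] <- sites$syn_weight
    cp[at] <- sites$codon_pos
    cod[at] <- sites$codon
    res[[k]] <- tibble(gene = gid, pos = full_pos, strand = p$strand[1],
                       codon = cod, codon_pos = cp, degeneracy = degv,
                       syn_weight = wt, class = cls, canonical = canonical)
  }
  out <- bind_rows(res)
  dup <- duplicated(out$pos)
  if (any(dup)) {
    warn(sprintf(
      "%d CDS position(s) covered by more than one gene; first gene in canonical order kept",
      sum(dup)))
    out <- out[!dup, ]
  }
  out
}
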