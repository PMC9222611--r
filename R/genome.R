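# Reference genome + feature model.
#
# Internal coordinate convention: 1-based, fully inclusive intervals, the
# GFF3/VCF/IRanges convention. BED input (0-based half-open) is converted at
# the I/O boundary. A feature part with start > end wraps the origin and is
# only legal on a circular genome.

FUNCTIONAL_LEVELS <- c("NONSYN_SITE", "SYN_SITE", "RRNA", "TRNA",
                       "PSEUDOGENE", "INTRON", "INTERGENIC")
COPY_LEVELS       <- c("SINGLE_COPY", "REPEAT")
STRUCTURAL_LEVELS <- c("LSC", "SSC", "IRA", "IRB", "NONE")
FEATURE_KINDS     <- c("gene", "CDS", "exon", "rRNA", "tRNA",
                       "pseudogene", "repeat", "IR")

#' Construct an annotated genome
#'
#' The container every statistic in the package is computed over: one
#' reference sequence (typically a circular organelle genome) plus a validated
#' feature table.
#'
#' @param sequence Single nucleotide string; lowercase accepted, only
#'   A/C/G/T/N retained after uppercasing.
#' @param seq_id Sequence identifier.
#' @param circular Is the molecule circular? Plant organelle reference
#'   genomes conventionally are.
#' @param features Feature tibble with columns `id`, `kind` (one of
#'   gene, CDS, exon, rRNA, tRNA, pseudogene, repeat, IR), `strand`
#'   (`"+"`/`"-"`), `start`, `end` (1-based inclusive), `part` (ordinal of the
#'   part within a multi-part feature, in transcription order) and `phase`
#'   (0-2 for CDS parts, NA otherwise).
#' @return An object of class `annotated_genome`.
#' @export
annotated_genome <- function(sequence, seq_id = "seq1", circular = TRUE,
                             features = empty_features()) {
  sequence <- toupper(sequence)
  bad <- stringr::str_locate(sequence, "[^ACGTN]")[1, 1]
  if (!is.na(bad)) {
    abort(sprintf("illegal character '%s' at position %d of sequence '%s'",
                  substr(sequence, bad, bad), bad, seq_id))
  }
  g <- structure(
    list(seq_id = seq_id, sequence = sequence, length = nchar(sequence),
         circular = circular, features = as_tibble(features)),
    class = "annotated_genome")
  validate_features(g)
  g
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s: %s bp, %s, %d feature part(s)\n",
              x$seq_id, format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear", nrow(x$features)))
  if (nrow(x$features) > 0) {
    print(dplyr::count(x$features, .data$kind))
  }
  invisible(x)
}

#' @rdname annotated_genome
#' @export
empty_features <- function() {
  tibble(id = character(), kind = character(), strand = character(),
         start = integer(), end = integer(), part = integer(),
         phase = integer())
}

validate_features <- function(genome) {
  f <- genome$features
  if (nrow(f) == 0) return(invisible(genome))
  stopifnot(all(c("id", "kind", "strand", "start", "end", "part", "phase")
                %in% names(f)))
  if (!all(f$kind %in% FEATURE_KINDS)) {
    abort(sprintf("unknown feature kind(s): %s",
                  paste(setdiff(f$kind, FEATURE_KINDS), collapse = ", ")))
  }
  wraps <- f$start > f$end
  if (any(wraps) && !genome$circular) {
    abort("origin-wrapping feature on a non-circular genome")
  }
  out <- f$start < 1 | f$end < 1 | f$start > genome$length | f$end > genome$length
  if (any(out)) {
    abort(sprintf("feature '%s' [%d, %d] exceeds genome length %d",
                  f$id[which(out)[1]], f$start[which(out)[1]],
                  f$end[which(out)[1]], genome$length))
  }
  invisible(genome)
}

# positions covered by a 1-based inclusive interval, wrapping the origin when
# start > end (circular genomes only)
interval_positions <- function(start, end, genome_length, circular = TRUE) {
  if (start <= end) return(seq.int(start, end))
  if (!circular) abort("interval wraps origin of a non-circular genome")
  c(seq.int(start, genome_length), seq.int(1L, end))
}

interval_length <- function(start, end, genome_length) {
  ifelse(start <= end, end - start + 1L, genome_length - start + 1L + end)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# sequence of a (possibly wrapping) interval on the forward strand
interval_sequence <- function(genome, start, end) {
  if (start <= end) return(substr(genome$sequence, start, end))
  paste0(substr(genome$sequence, start, genome$length),
         substr(genome$sequence, 1, end))
}

#' Read a reference genome from FASTA
#'
#' Loads the first record (or the record named `seq_id`), uppercases it and
#' rejects any character outside A/C/G/T/N.
#'
#' @param path FASTA file.
#' @param seq_id Optional record name to select; default first record.
#' @param circular Treat the molecule as circular (default `TRUE`).
#' @return An [annotated_genome] with an empty feature table.
#' @export
read_genome_fasta <- function(path, seq_id = NULL, circular = TRUE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  # read as raw strings: the DNA reader silently drops non-IUPAC letters,
  # which would hide corrupt records; annotated_genome() validates instead
  seqs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) abort(sprintf(
                     "malformed FASTA '%s': %s", path, conditionMessage(e))))
  if (length(seqs) == 0) abort(sprintf("no sequence records in '%s'", path))
  nm <- sub("\\s.*$", "", names(seqs))
  i <- 1L
  if (!is.null(seq_id)) {
    i <- match(seq_id, nm)
    if (is.na(i)) abort(sprintf("record '%s' not found in '%s'", seq_id, path))
  }
  annotated_genome(as.character(seqs[[i]]), seq_id = nm[i], circular = circular)
}

# rtracklayer GFF3 'type' -> internal kind
GFF_KIND_MAP <- c(gene = "gene", CDS = "CDS", exon = "exon",
                  rRNA = "rRNA", tRNA = "tRNA",
                  pseudogene = "pseudogene",
                  pseudogenic_region = "pseudogene",
                  repeat_region = "repeat", inverted_repeat = "IR")

#' Read feature annotation from GFF3
#'
#' Captures gene, CDS, exon, rRNA, tRNA, pseudogene and repeat records
#' (other types are ignored). CDS parts are grouped under their parent gene
#' and ordered in strand-aware transcription order: ascending start on `+`,
#' descending start on `-`.
#'
#' @param path GFF3 file (1-based inclusive coordinates).
#' @param genome An [annotated_genome]; features are validated against its
#'   length.
#' @return The genome with `features` populated.
#' @export
read_features_gff <- function(path, genome) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  kind <- unname(GFF_KIND_MAP[as.character(df$type)])
  keep <- !is.na(kind)
  if (!any(keep)) {
    genome$features <- empty_features()
    return(genome)
  }
  df <- df[keep, , drop = FALSE]
  kind <- kind[keep]
  parent <- if ("Parent" %in% names(df)) {
    vapply(df$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
           character(1))
  } else rep(NA_character_, nrow(df))
  id <- if ("ID" %in% names(df)) as.character(df$ID) else rep(NA_character_, nrow(df))
  # CDS/exon parts belong to their parent gene
  fid <- ifelse(kind %in% c("CDS", "exon") & !is.na(parent), parent, id)
  fid[is.na(fid)] <- paste0(tolower(kind[is.na(fid)]), "_",
                            seq_len(sum(is.na(fid))))
  phase <- if ("phase" %in% names(df)) suppressWarnings(as.integer(df$phase))
           else rep(NA_integer_, nrow(df))
  feats <- tibble(
    id = fid, kind = kind,
    strand = ifelse(as.character(df$strand) == "-", "-", "+"),
    start = as.integer(df$start), end = as.integer(df$end),
    part = NA_integer_, phase = ifelse(kind == "CDS", phase, NA_integer_))
  feats <- feats |>
    group_by(.data$id, .data$kind) |>
    arrange(ifelse(.data$strand == "-", -.data$start, .data$start),
            .by_group = TRUE) |>
    mutate(part = row_number()) |>
    ungroup() |>
    arrange(.data$start, .data$id, .data$part)
  genome$features <- feats
  validate_features(genome)
  genome
}

#' Read BED intervals
#'
#' BED is 0-based half-open; intervals are converted to the package's
#' 1-based inclusive convention on read.
#'
#' @param path BED file (first three columns used).
#' @return Tibble with columns `seq_id`, `start`, `end` (1-based inclusive).
#' @export
read_intervals_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) == 0) {
    return(tibble(seq_id = character(), start = integer(), end = integer()))
  }
  tibble(seq_id = as.character(raw[[1]]),
         start = as.integer(raw[[2]]) + 1L,
         end = as.integer(raw[[3]]))
}

#' Derive introns from multi-part gene structures
#'
#' For every gene with CDS (or exon) parts, the introns are the gene span
#' minus the union of its parts. Single-part genes contribute nothing.
#'
#' @param genome An [annotated_genome] with features loaded.
#' @return Tibble with columns `id`, `start`, `end`; disjoint intervals.
#' @export
derive_introns <- function(genome) {
  f <- genome$features
  parts <- f |> filter(.data$kind %in% c("CDS", "exon"))
  if (nrow(parts) == 0) {
    return(tibble(id = character(), start = integer(), end = integer()))
  }
  out <- vector("list", length(unique(parts$id)))
  names(out) <- unique(parts$id)
  for (gid in unique(parts$id)) {
    p <- parts[parts$id == gid, ]
    # prefer CDS parts when both CDS and exon are annotated
    if (any(p$kind == "CDS")) p <- p[p$kind == "CDS", ]
    gene_row <- f[f$id == gid & f$kind == "gene", ]
    covered <- unlist(lapply(seq_len(nrow(p)), function(i)
      interval_positions(p$start[i], p$end[i], genome$length, genome$circular)))
    span <- if (nrow(gene_row) > 0) {
      interval_positions(gene_row$start[1], gene_row$end[1], genome$length,
                         genome$circular)
    } else if (nrow(p) > 1) {
      seq.int(min(p$start), max(p$end))
    } else {
      covered  # single part, no gene record: no declared extent, no introns
    }
    intron_pos <- sort(setdiff(span, covered))
    if (length(intron_pos) == 0) next
    out[[gid]] <- runs_to_intervals(intron_pos, gid)
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) tibble(id = character(), start = integer(),
                             end = integer()) else res
}

# contiguous runs of sorted positions -> interval tibble
runs_to_intervals <- function(pos, id = NA_character_) {
  brk <- c(0L, which(diff(pos) != 1L), length(pos))
  tibble(id = id,
         start = pos[brk[-length(brk)] + 1L],
         end = pos[brk[-1L]])
}

#' @export
tidy.annotated_genome <- function(x, ...) x$features

#' @export
glance.annotated_genome <- function(x, ...) {
  tibble(seq_id = x$seq_id, length = x$length, circular = x$circular,
         n_features = length(unique(x$features$id)),
         n_parts = nrow(x$features))
}

#' Write features as GFF3
#'
#' @param genome An [annotated_genome] with features.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_features_gff <- function(genome, path) {
  f <- genome$features
  type_map <- c(gene = "gene", CDS = "CDS", exon = "exon", rRNA = "rRNA",
                tRNA = "tRNA", pseudogene = "pseudogene",
                "repeat" = "repeat_region", IR = "inverted_repeat")
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", genome$seq_id, genome$length))
  if (nrow(f) > 0) {
    attrs <- ifelse(f$kind %in% c("CDS", "exon"),
                    sprintf("ID=%s-%s.%d;Parent=%s",
                            tolower(f$kind), f$id, f$part, f$id),
                    sprintf("ID=%s", f$id))
    lines <- c(lines, sprintf(
      "%s\torgvar\t%s\t%d\t%d\t.\t%s\t%s\t%s",
      genome$seq_id, type_map[f$kind], f$start, f$end, f$strand,
      ifelse(f$kind == "CDS",
             as.character(ifelse(is.na(f$phase), 0L, f$phase)), "."), attrs))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a FASTA file
#'
#' @param genome An [annotated_genome].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(setNames(genome$sequence, genome$seq_id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
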