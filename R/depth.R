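# Windowed coverage depth and copy-number profiling.
#
# Input contract: the 3-column TSV `seq_id TAB pos TAB depth` that
# `samtools depth` emits. That tool omits zero-coverage positions by
# default, so missing positions are recorded as depth 0 on read.

#' Read a per-site depth table
#'
#' @param path 3-column TSV (seq_id, 1-based position, depth), no header.
#' @param genome_length Genome length; positions absent from the file are
#'   filled with depth 0.
#' @param seq_id Optional sequence name; default taken from the file.
#' @return Tibble `seq_id`, `pos`, `depth` covering positions
#'   `1..genome_length`.
#' @export
read_depth <- function(path, genome_length, seq_id = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  # malformed lines are reported through problems() as a parse error below
  raw <- suppressWarnings(
    readr::read_tsv(path, col_names = c("seq_id", "pos", "depth"),
                    col_types = "cii", show_col_types = FALSE,
                    progress = FALSE))
  pb <- readr::problems(raw)
  if (nrow(pb) > 0) {
    abort(sprintf("malformed depth line %d: expected %s, got '%s'",
                  pb$row[1], pb$expected[1], pb$actual[1]))
  }
  if (nrow(raw) > 0) {
    if (any(is.na(raw$pos) | is.na(raw$depth))) {
      abort(sprintf("malformed depth line %d",
                    which(is.na(raw$pos) | is.na(raw$depth))[1]))
    }
    if (any(raw$depth < 0)) {
      abort(sprintf("negative depth at line %d", which(raw$depth < 0)[1]))
    }
    if (any(raw$pos < 1 | raw$pos > genome_length)) {
      abort("depth position outside the genome")
    }
    if (is.null(seq_id)) seq_id <- raw$seq_id[1]
  }
  if (is.null(seq_id)) seq_id <- "seq1"
  depth <- integer(genome_length)
  depth[raw$pos] <- raw$depth
  tibble(seq_id = seq_id, pos = seq_len(genome_length), depth = depth)
}

#' Mean depth in non-overlapping windows
#'
#' Tiles the genome from position 1 in fixed windows (1000 bp by default,
#' the conventional resolution for organelle copy-number profiling); each
#' window's mean includes its zero-depth positions. The final window may be
#' shorter and is averaged over its own length, or dropped with
#' `drop_partial`.
#'
#' @param depth Depth tibble from [read_depth()] (or any tibble with `pos`,
#'   `depth`; missing positions count as 0).
#' @param genome_length Genome length; defaults to `max(pos)`.
#' @param window Window size in bp.
#' @param drop_partial Drop a trailing partial window (default `FALSE`).
#' @return Tibble of class `depth_profile`: `window`, `start`, `end`
#'   (1-based inclusive), `n_sites`, `mean_depth`.
#' @export
window_means <- function(depth, genome_length = NULL, window = 1000,
                         drop_partial = FALSE) {
  if (window < 1) abort("window must be >= 1")
  if (is.null(genome_length)) genome_length <- max(depth$pos)
  if (genome_length <= 0) abort("genome_length must be positive")
  win <- (seq_len(genome_length) - 1L) %/% as.integer(window)
  d <- numeric(genome_length)
  d[depth$pos] <- depth$depth
  sums <- tapply(d, win, sum)
  n_win <- length(sums)
  starts <- (seq_len(n_win) - 1L) * as.integer(window) + 1L
  ends <- pmin(starts + as.integer(window) - 1L, genome_length)
  out <- tibble(window = seq_len(n_win), start = starts, end = ends,
                n_sites = ends - starts + 1L,
                mean_depth = as.numeric(sums) / (ends - starts + 1L))
  if (drop_partial && out$n_sites[n_win] < window) out <- out[-n_win, ]
  structure(out, class = c("depth_profile", class(out)),
            genome_length = genome_length, window = window)
}

#' Normalise a depth profile to copy number
#'
#' Divides every window mean by the median window mean — a robust baseline
#' that is not dragged by the copy-number segments themselves — so a
#' two-copy segment sits near `norm_copy = 2` regardless of sequencing
#' effort.
#'
#' @param profile A `depth_profile`.
#' @return The profile with a `norm_copy` column and a
#'   `genome_median_depth` attribute; `norm_copy` is `NA` when the median is
#'   0.
#' @export
normalize_profile <- function(profile) {
  med <- median(profile$mean_depth)
  profile$norm_copy <- if (is.na(med) || med == 0) NA_real_
                       else profile$mean_depth / med
  attr(profile, "genome_median_depth") <- med
  profile
}

#' Flag windows overlapping repeat intervals
#'
#' @param profile A `depth_profile`.
#' @param repeats Tibble with `start`, `end` (1-based inclusive) repeat
#'   intervals.
#' @return The profile with `is_repeat`: `TRUE` when the window overlaps any
#'   repeat by at least 1 bp.
#' @export
overlay_repeats <- function(profile, repeats) {
  if (is.null(repeats) || nrow(repeats) == 0) {
    profile$is_repeat <- FALSE
    return(profile)
  }
  profile$is_repeat <- vapply(seq_len(nrow(profile)), function(i) {
    any(profile$start[i] <= repeats$end & profile$end[i] >= repeats$start)
  }, logical(1))
  profile
}

#' Flag putative copy-number-variant windows
#'
#' A simple fold-change flag, not a segmentation caller: windows whose
#' normalised copy number falls outside `[lower, upper]`.
#'
#' @param profile A normalised `depth_profile`.
#' @param lower,upper Fold-change band (default 0.5-2).
#' @return The profile with a logical `cnv_flag` column.
#' @export
flag_cnv <- function(profile, lower = 0.5, upper = 2) {
  if (!"norm_copy" %in% names(profile)) profile <- normalize_profile(profile)
  profile$cnv_flag <- !is.na(profile$norm_copy) &
    (profile$norm_copy < lower | profile$norm_copy > upper)
  profile
}

#' Write a depth profile as TSV
#'
#' @param profile A `depth_profile`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  readr::write_tsv(as_tibble(profile), path, progress = FALSE)
  invisible(path)
}

#' Plot a depth profile
#'
#' Mean depth (or normalised copy number) per window along the genome, with
#' repeat-overlapping windows shaded.
#'
#' @param object A `depth_profile`.
#' @param y `"mean_depth"` or `"norm_copy"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.depth_profile <- function(object, y = c("mean_depth", "norm_copy"),
                                   ...) {
  y <- match.arg(y)
  if (y == "norm_copy" && !"norm_copy" %in% names(object)) {
    object <- normalize_profile(object)
  }
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                        y = .data[[y]]))
  if ("is_repeat" %in% names(df) && any(df$is_repeat)) {
    p <- p + ggplot2::geom_rect(
      data = df |> filter(.data$is_repeat),
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, fill = "pink", alpha = 0.5,
      inherit.aes = FALSE)
  }
  p + ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "genomic position (bp)",
                  y = if (y == "mean_depth") "mean depth" else
                    "normalised copy number") +
    ggplot2::theme_minimal()
}
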