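# Report plots for the category statistics and the Ts/Tv summary.

#' Bar plot of per-category SNP (or indel) abundance
#'
#' @param stats A functional `category_stats` table.
#' @param what `"snps_per_site"` or `"indels_per_site"`.
#' @return A ggplot object.
#' @export
plot_category_abundance <- function(stats,
                                    what = c("snps_per_site",
                                             "indels_per_site")) {
  what <- match.arg(what)
  df <- stats |> filter(.data$layer == "functional",
                        .data$label != "PROTEIN_CODING",
                        !is.na(.data[[what]]))
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$label, levels = FUNCTIONAL_ROW_ORDER),
    y = .data[[what]])) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = gsub("_", " ", what)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Bar plot of transition/transversion percentages
#'
#' @param tstv A [tstv_summary()] tibble (optionally several rows with a
#'   `genome` column for side-by-side comparison).
#' @return A ggplot object.
#' @export
plot_tstv <- function(tstv) {
  if (!"genome" %in% names(tstv)) tstv$genome <- "genome"
  df <- tstv |>
    tidyr::pivot_longer(c("ts_pct", "tv_pct"), names_to = "type",
                        values_to = "pct") |>
    mutate(type = ifelse(.data$type == "ts_pct", "transition",
                         "transversion"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$genome, y = .data$pct,
                                   fill = .data$type)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% of biallelic SNPs", fill = NULL) +
    ggplot2::theme_minimal()
}
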