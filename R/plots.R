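#' Plot per-plant SNV and InDel counts by experiment
#'
#' Dot plot of the per-plant counts produced by [count_table()] (or
#' [apt_editing_counts()]), split into SNVs and InDels.
#'
#' @param counts Per-plant count table with `sample_id`, a grouping column,
#'   `n_snv` and `n_indel`.
#' @param by Name of the grouping column.
#' @return A ggplot object.
#' @export
plot_variant_counts <- function(counts, by = "experiment") {
  if (!by %in% names(counts)) stop("grouping column not found: ", by)
  long <- counts |>
    dplyr::select(dplyr::all_of(c("sample_id", by, "n_snv", "n_indel"))) |>
    tidyr::pivot_longer(c("n_snv", "n_indel"), names_to = "var_type",
                        values_to = "n") |>
    dplyr::mutate(var_type = dplyr::recode(.data$var_type,
                                           n_snv = "SNV", n_indel = "InDel"))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data[[by]], y = .data$n)) +
    ggplot2::geom_point(position = ggplot2::position_jitter(width = 0.12,
                                                            height = 0),
                        alpha = 0.8) +
    ggplot2::facet_wrap(~var_type) +
    ggplot2::labs(x = NULL, y = "variants per plant (vs matched wild type)") +
    ggplot2::theme_bw()
}

#' Plot per-chromosome variant counts against chromosome length
#'
#' Scatter plot used to eyeball length-proportionality of variant placement
#' (quantified by [chromosome_length_correlation()]).
#'
#' @param per_chrom_counts Tibble with `chrom` and `n`.
#' @param lengths Tibble with `chrom` and `length`.
#' @return A ggplot object.
#' @export
plot_chromosome_distribution <- function(per_chrom_counts, lengths) {
  joined <- dplyr::inner_join(per_chrom_counts, lengths, by = "chrom")
  ggplot2::ggplot(joined,
                  ggplot2::aes(x = .data$length, y = .data$n)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$chrom),
                       vjust = -0.6, size = 3) +
    ggplot2::labs(x = "chromosome length (bp)",
                  y = "variants on chromosome") +
    ggplot2::theme_bw()
}
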