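# broom-style tidiers and ggplot2 methods for the pipeline's result types.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a similarity matrix into long format
#'
#' @param x A [similarity_matrix()].
#' @param ... Unused.
#' @return Tibble `(genome_a, genome_b, metric, value)` over the upper
#'   triangle.
#' @method tidy similarity_matrix
#' @export
tidy.similarity_matrix <- function(x, ...) {
  ids <- rownames(x)
  ut <- which(upper.tri(x), arr.ind = TRUE)
  tibble(genome_a = ids[ut[, 1]], genome_b = ids[ut[, 2]],
         metric = attr(x, "metric"), value = x[ut])
}

#' @rdname tidy.similarity_matrix
#' @method autoplot similarity_matrix
#' @export
autoplot.similarity_matrix <- function(x, ...) {
  df <- tidy(x)
  df2 <- df |> dplyr::rename(genome_a = "genome_b", genome_b = "genome_a")
  long <- dplyr::bind_rows(df, df2)
  ggplot2::ggplot(long, ggplot2::aes(.data$genome_a, .data$genome_b,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = attr(x, "metric")) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Tidy a genus partition
#'
#' @param x A `genus_partition` from [demarcate()].
#' @param ... Unused.
#' @method tidy genus_partition
#' @export
tidy.genus_partition <- function(x, ...) {
  x$membership |>
    left_join(x$diagnostics, by = "group_id")
}

#' @rdname tidy.genus_partition
#' @method glance genus_partition
#' @export
glance.genus_partition <- function(x, ...) {
  tibble(n_genomes = nrow(x$membership),
         n_genera = nrow(x$diagnostics),
         n_singletons = sum(x$diagnostics$n == 1),
         aai_min = x$config$aai_min,
         dist_max = x$config$dist_max,
         aai_pass_fraction = x$config$aai_pass_fraction)
}

#' @rdname tidy.genus_partition
#' @method autoplot genus_partition
#' @export
autoplot.genus_partition <- function(x, ...) {
  df <- x$diagnostics |> mutate(group_id = factor(.data$group_id))
  ggplot2::ggplot(df, ggplot2::aes(.data$group_id, .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "genus", y = "genomes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Tidy pan-genome accounting
#'
#' @param x A `pan_genome_summary` from [classify_clusters()].
#' @param ... Unused.
#' @method tidy pan_genome_summary
#' @export
tidy.pan_genome_summary <- function(x, ...) {
  x$per_genome |>
    tidyr::pivot_longer(c("core_count", "accessory_count", "unique_count"),
                        names_to = "class", values_to = "n") |>
    mutate(class = sub("_count$", "", .data$class))
}

#' @rdname tidy.pan_genome_summary
#' @method glance pan_genome_summary
#' @export
glance.pan_genome_summary <- function(x, ...) {
  tibble(total_oc_count = x$totals$total_oc_count,
         core_oc_count = x$totals$core_oc_count,
         single_copy_core_count = x$totals$single_copy_core_count,
         n_genomes = length(x$genome_ids))
}

#' @rdname tidy.pan_genome_summary
#' @method autoplot pan_genome_summary
#' @export
autoplot.pan_genome_summary <- function(x, ...) {
  ggplot2::ggplot(tidy(x),
                  ggplot2::aes(.data$genome_id, .data$n,
                               fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "orthologous clusters") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Histogram of inter- vs intra-group metric values
#'
#' @param inter_intra Long tibble as produced by [run_all()] (columns
#'   `metric`, `pair_type`, `value`) or by [split_inter_intra()].
#' @param bins Histogram bin count.
#' @export
plot_inter_intra <- function(inter_intra, bins = 30) {
  if (!"metric" %in% names(inter_intra)) inter_intra$metric <- "value"
  ggplot2::ggplot(inter_intra,
                  ggplot2::aes(.data$value, fill = .data$pair_type)) +
    ggplot2::geom_histogram(bins = bins, position = "identity",
                            alpha = 0.6) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::scale_fill_manual(values = c(inter = "#c0392b",
                                          intra = "#2980b9"),
                               name = NULL) +
    ggplot2::theme_minimal()
}
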