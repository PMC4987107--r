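#' Abundance-diversity scatter plot
#'
#' One point per genome: calcium-binding protein count (x) against distinct
#' calcium-binding architecture count (y), with a least-squares line. The
#' tightness of the relationship shows how far repertoire growth has been
#' accompanied by domain shuffling rather than duplication alone.
#'
#' @param summaries Summary tibble from [summarize_genomes()].
#' @return A ggplot object.
#' @export
plot_abundance_diversity <- function(summaries) {
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = .data$n_ca_proteins, y = .data$n_ca_archs,
                               colour = .data$taxon_group)) +
    ggplot2::geom_smooth(ggplot2::aes(group = 1), method = "lm",
                         formula = y ~ x, se = FALSE, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Calcium-binding proteins",
                  y = "Distinct calcium-binding architectures",
                  colour = "Taxon") +
    ggplot2::theme_minimal()
}

#' Heatmap of the genome x superfamily occurrence matrix
#'
#' @param occurrence Tibble from [superfamily_occurrence_matrix()].
#' @return A ggplot object.
#' @export
plot_occurrence_matrix <- function(occurrence) {
  long <- tidyr::pivot_longer(occurrence, -"genome_id",
                              names_to = "superfamily_id",
                              values_to = "n_proteins")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$superfamily_id,
                                     y = .data$genome_id,
                                     fill = .data$n_proteins)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue4") +
    ggplot2::labs(x = "Calcium-binding superfamily", y = "Genome",
                  fill = "Proteins") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Histogram of single-purpose architectures per component
#'
#' @param breakdown Result of [component_breakdown()].
#' @return A ggplot object.
#' @export
plot_component_breakdown <- function(breakdown) {
  ggplot2::ggplot(breakdown$single_purpose,
                  ggplot2::aes(x = .data$component_id, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Functional component",
                  y = "Single-purpose architectures") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Presence map of a Dollo reconstruction
#'
#' Node-by-architecture tile plot of reconstructed presence (ancestral nodes
#' included), architectures ordered by gain node.
#'
#' @param object A `dollo_reconstruction`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dollo_reconstruction
#' @export
autoplot.dollo_reconstruction <- function(object, ...) {
  long <- tidy.dollo_reconstruction(object)
  long$node <- factor(long$node, levels = rownames(object$states))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$architecture, y = .data$node,
                                     fill = .data$present)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey20", `FALSE` = "white")) +
    ggplot2::labs(x = "Architecture", y = "Tree node", fill = "Present") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
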