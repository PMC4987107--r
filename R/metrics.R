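#' Per-genome repertoire summary
#'
#' For each genome, counts annotated proteins and distinct architectures,
#' overall and restricted to calcium-binding architectures (those containing
#' at least one registry superfamily). Architecture distinctness is at exact
#' token-sequence level, gaps included: `47473` and `47473,_gap_` are
#' different architectures.
#'
#' @param genomes Long tibble `genome_id, protein_id, architecture` (one or
#'   more genomes; see [read_proteome_dir()]).
#' @param registry A `ca_registry` or integer id vector.
#' @param metadata Optional metadata tibble from [read_genome_metadata()];
#'   genomes missing from it get taxon_group `"unknown"` and
#'   `total_gene_count` equal to their annotated protein count.
#' @return One row per genome:
#'   `genome_id, taxon_group, total_gene_count, n_proteins_total,
#'   n_archs_total, n_ca_proteins, n_ca_archs`.
#' @examples
#' toy <- tibble::tibble(
#'   genome_id = "g1",
#'   protein_id = c("A", "B", "C", "D", "E"),
#'   architecture = c("47473", "47473,_gap_", "56112", "47473", "49562,56112")
#' )
#' summarize_genomes(toy, ca_builtin_registry())
#' @export
summarize_genomes <- function(genomes, registry, metadata = NULL) {
  stopifnot(all(c("genome_id", "protein_id", "architecture") %in% names(genomes)))
  genomes <- as_tibble(genomes)
  if (nrow(genomes) > 0L) {
    genomes$is_ca <- arch_is_ca(genomes$architecture, registry)
  } else {
    genomes$is_ca <- logical()
  }
  out <- genomes |>
    dplyr::group_by(.data$genome_id) |>
    dplyr::summarise(
      n_proteins_total = dplyr::n(),
      n_archs_total = dplyr::n_distinct(.data$architecture),
      n_ca_proteins = sum(.data$is_ca),
      n_ca_archs = dplyr::n_distinct(.data$architecture[.data$is_ca]),
      .groups = "drop"
    )
  if (!is.null(metadata)) {
    out <- dplyr::left_join(out, metadata, by = "genome_id")
  } else {
    out$taxon_group <- NA_character_
    out$total_gene_count <- NA_integer_
  }
  out$taxon_group[is.na(out$taxon_group)] <- "unknown"
  out$total_gene_count <- ifelse(is.na(out$total_gene_count),
                                 out$n_proteins_total, out$total_gene_count)
  dplyr::select(out, "genome_id", "taxon_group", "total_gene_count",
                "n_proteins_total", "n_archs_total", "n_ca_proteins",
                "n_ca_archs") |>
    dplyr::arrange(.data$genome_id)
}

#' Summarize a single genome
#'
#' Convenience wrapper around [summarize_genomes()] for one genome; an empty
#' table yields a single all-zero row.
#'
#' @param genome Tibble `protein_id, architecture` (optionally `genome_id`).
#' @param registry A `ca_registry` or integer id vector.
#' @param genome_id Identifier used if the table lacks a `genome_id` column.
#' @return A one-row summary tibble (see [summarize_genomes()]).
#' @export
summarize_genome <- function(genome, registry, genome_id = "genome") {
  genome <- as_tibble(genome)
  if (!"genome_id" %in% names(genome)) {
    genome$genome_id <- rep(genome_id, nrow(genome))
  }
  if (nrow(genome) == 0L) {
    return(tibble(genome_id = genome_id, taxon_group = "unknown",
                  total_gene_count = 0L, n_proteins_total = 0L,
                  n_archs_total = 0L, n_ca_proteins = 0L, n_ca_archs = 0L))
  }
  summarize_genomes(genome, registry)
}

#' Calcium-binding diversity fraction of a genome
#'
#' The fraction of a proteome's distinct architectures that contain at least
#' one calcium-binding domain: `n_ca_archs / n_archs_total`, in `[0, 1]`.
#'
#' @param summary Summary tibble from [summarize_genomes()] (any number of
#'   rows) .
#' @return Numeric vector, one value per genome row.
#' @export
diversity_fraction <- function(summary) {
  if (any(summary$n_archs_total == 0L)) {
    abort("diversity_fraction undefined for a genome with no architectures.",
          class = "catoolkit_undefined_error")
  }
  summary$n_ca_archs / summary$n_archs_total
}

#' Calcium-binding redundancy ratio of a genome
#'
#' Proteins per architecture among calcium-binding architectures, divided by
#' proteins per architecture over the whole proteome:
#' `(n_ca_proteins / n_ca_archs) / (n_proteins_total / n_archs_total)`.
#' A value of 1 means calcium-binding architectures are duplicated at the
#' proteome-average rate; above 1, more.
#'
#' @inheritParams diversity_fraction
#' @return Numeric vector, one value per genome row.
#' @export
redundancy_ratio <- function(summary) {
  if (any(summary$n_ca_archs == 0L | summary$n_archs_total == 0L)) {
    abort("redundancy_ratio undefined where n_ca_archs or n_archs_total is zero.",
          class = "catoolkit_undefined_error")
  }
  (summary$n_ca_proteins / summary$n_ca_archs) /
    (summary$n_proteins_total / summary$n_archs_total)
}

#' Abundance-diversity correlation across genomes
#'
#' Pearson product-moment correlation, across genomes, between the number of
#' calcium-binding proteins (abundance, x) and the number of distinct
#' calcium-binding architectures (diversity, y). Each genome contributes one
#' point.
#'
#' @param summaries Summary tibble from [summarize_genomes()], at least three
#'   rows, with nonzero variance on both axes.
#' @return The correlation coefficient (scalar).
#' @export
abundance_diversity_correlation <- function(summaries) {
  if (nrow(summaries) < 3L) {
    abort("Need at least 3 genomes for a correlation.",
          class = "catoolkit_undefined_error")
  }
  x <- summaries$n_ca_proteins
  y <- summaries$n_ca_archs
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    abort("Correlation undefined: zero variance on one axis.",
          class = "catoolkit_undefined_error")
  }
  stats::cor(x, y, method = "pearson")
}

#' Genome x superfamily occurrence matrix
#'
#' For each genome and each registry superfamily, the number of proteins
#' whose architecture contains that superfamily at least once. Counting is
#' per protein, not per domain copy: a protein with two EF-hand domains
#' counts once in the EF-hand column, and a protein carrying two different
#' registry superfamilies counts once in each of their columns.
#'
#' @param genomes Long tibble `genome_id, protein_id, architecture`.
#' @param registry A `ca_registry` or integer id vector.
#' @param genome_ids Optional character vector of genomes to report rows for;
#'   defaults to the genomes present in `genomes`. A listed genome with no
#'   rows yields an all-zero row.
#' @return Tibble with `genome_id` and one integer column per distinct
#'   registry superfamily id (sorted ascending, names are the ids).
#' @export
superfamily_occurrence_matrix <- function(genomes, registry, genome_ids = NULL) {
  ids <- registry_ids(registry)
  gids <- if (is.null(genome_ids)) sort(unique(genomes$genome_id))
          else sort(unique(genome_ids))
  mat <- matrix(0L, nrow = length(gids), ncol = length(ids),
                dimnames = list(gids, as.character(ids)))
  genomes <- genomes[genomes$genome_id %in% gids, , drop = FALSE]
  if (nrow(genomes) > 0L) {
    doms <- arch_domain_ids(genomes$architecture)
    for (i in seq_len(nrow(genomes))) {
      hit <- intersect(unique(doms[[i]]), ids)
      if (length(hit) > 0L) {
        g <- genomes$genome_id[i]
        mat[g, as.character(hit)] <- mat[g, as.character(hit)] + 1L
      }
    }
  }
  dplyr::bind_cols(tibble(genome_id = gids), as_tibble(mat))
}
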