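#' Read a functional-component catalog
#'
#' The catalog lists the components of the calcium-signaling toolkit — the
#' roles an architecture can play: generating the signal (influx), removing
#' calcium from the cytosol (efflux), decoding the signal, relaying it to
#' effectors — as data, not code. TSV with header
#' `component_id<TAB>category<TAB>binds_calcium`. `binds_calcium` marks
#' components whose proteins themselves bind calcium; architectures labeled
#' with such a component must contain a registry domain
#' (see [build_annotation_map()]). An editable example catalog ships with the
#' package ([ca_example_catalog()]).
#'
#' @param path Path to the catalog TSV.
#' @return Tibble `component_id, category, binds_calcium` with unique
#'   component ids and categories in
#'   `{influx, efflux, decoding, relay, other}`.
#' @export
read_component_catalog <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    component_id = readr::col_character(),
    category = readr::col_character(),
    binds_calcium = readr::col_logical()
  ), progress = FALSE)
  missing <- setdiff(c("component_id", "category", "binds_calcium"), names(df))
  if (length(missing) > 0L) {
    abort(sprintf("Catalog lacks column(s): %s.", paste(missing, collapse = ", ")),
          class = "catoolkit_catalog_error")
  }
  if (anyDuplicated(df$component_id)) {
    abort(sprintf("Catalog has duplicate component_id '%s'.",
                  df$component_id[duplicated(df$component_id)][1]),
          class = "catoolkit_catalog_error")
  }
  bad <- setdiff(unique(df$category), c("influx", "efflux", "decoding", "relay", "other"))
  if (length(bad) > 0L) {
    abort(sprintf("Unknown catalog category '%s'.", bad[1]),
          class = "catoolkit_catalog_error")
  }
  as_tibble(df)
}

#' The example component catalog shipped with the package
#'
#' Component names attested for the toolkit (e.g. `decoding-CDPK`,
#' `relay-muscle-contraction`, `relay-calmodulin-kinase`) across the four
#' categories; user-replaceable.
#'
#' @return Catalog tibble (see [read_component_catalog()]).
#' @export
ca_example_catalog <- function() {
  read_component_catalog(system.file("extdata", "component_catalog_example.tsv",
                                     package = "catoolkit", mustWork = TRUE))
}

#' Read a protein-to-component label table
#'
#' TSV with header `protein_id<TAB>genome_id<TAB>component_id`, emulating
#' pathway/literature-derived assignments of full-length proteins to toolkit
#' components.
#'
#' @param path Path to the TSV.
#' @return Tibble `protein_id, genome_id, component_id`.
#' @export
read_protein_components <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  missing <- setdiff(c("protein_id", "genome_id", "component_id"), names(df))
  if (length(missing) > 0L) {
    abort(sprintf("Protein-component table lacks column(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "catoolkit_io_error")
  }
  as_tibble(df[, c("protein_id", "genome_id", "component_id")])
}

#' Infer component labels onto architectures
#'
#' Implements the labeling procedure: each labeled protein is resolved to its
#' domain architecture in its genome, and the component label is inferred
#' onto that architecture. Labels from a calcium-binding component
#' (`binds_calcium = TRUE`) are restricted to architectures that contain at
#' least one registry domain — a labeled protein whose architecture has none
#' is dropped with a warning. Annotations are global: the same architecture
#' seen in several genomes accrues the union of its labels, deduplicated.
#'
#' @param protein_components Tibble `protein_id, genome_id, component_id`
#'   (see [read_protein_components()]).
#' @param genomes Long tibble `genome_id, protein_id, architecture`.
#' @param catalog Component catalog tibble.
#' @param registry A `ca_registry` or integer id vector.
#' @return Annotation tibble, one row per annotated architecture:
#'   `architecture`, `components` (list column of sorted component ids),
#'   `n_components`. Rows sorted by architecture string.
#' @examples
#' \donttest{
#' sim <- simulate_toolkit(sim_config(n_leaves = 6, n_architectures = 30, seed = 1))
#' ann <- build_annotation_map(sim$protein_components, sim$genomes,
#'                             sim$catalog, sim$registry)
#' head(classify_purpose(ann))
#' }
#' @export
build_annotation_map <- function(protein_components, genomes, catalog, registry) {
  pct <- as_tibble(protein_components)
  unknown_comp <- setdiff(unique(pct$component_id), catalog$component_id)
  if (length(unknown_comp) > 0L) {
    abort(sprintf("Unknown component_id '%s' (not in catalog).", unknown_comp[1]),
          class = "catoolkit_catalog_error")
  }
  joined <- dplyr::left_join(pct, as_tibble(genomes),
                             by = c("protein_id", "genome_id"))
  unresolved <- is.na(joined$architecture)
  if (any(unresolved)) {
    warn(sprintf("%d protein-component row(s) reference proteins absent from the genome tables; skipped.",
                 sum(unresolved)))
    joined <- joined[!unresolved, , drop = FALSE]
  }
  if (nrow(joined) > 0L) {
    binds <- catalog$binds_calcium[match(joined$component_id, catalog$component_id)]
    is_ca <- arch_is_ca(joined$architecture, registry)
    drop <- binds & !is_ca
    if (any(drop)) {
      warn(sprintf("%d label(s) from calcium-binding components dropped: architecture lacks a registry domain.",
                   sum(drop)))
      joined <- joined[!drop, , drop = FALSE]
    }
  }
  if (nrow(joined) == 0L) {
    abort("No architecture annotations survive labeling.",
          class = "catoolkit_annotation_error")
  }
  joined |>
    dplyr::distinct(.data$architecture, .data$component_id) |>
    dplyr::group_by(.data$architecture) |>
    dplyr::summarise(components = list(sort(unique(.data$component_id))),
                     .groups = "drop") |>
    dplyr::mutate(n_components = lengths(.data$components)) |>
    dplyr::arrange(.data$architecture)
}

#' Classify architectures as single- or multipurpose
#'
#' An architecture is multipurpose when it carries at least `min_components`
#' distinct component labels (default 2); the subset playing three or more
#' roles is the highly multipurpose set reported by [count_multipurpose()].
#'
#' @param annotations Annotation tibble from [build_annotation_map()].
#' @param min_components Integer threshold >= 2.
#' @return `annotations` with an added `purpose` column, `"single"` or
#'   `"multi"`.
#' @export
classify_purpose <- function(annotations, min_components = 2L) {
  stopifnot(min_components >= 2L)
  dplyr::mutate(annotations,
                purpose = ifelse(.data$n_components >= min_components,
                                 "multi", "single"))
}

#' @rdname classify_purpose
#' @param k Component-count threshold.
#' @return `count_multipurpose()`: the number of annotated architectures with
#'   at least `k` components.
#' @export
count_multipurpose <- function(annotations, k = 2L) {
  sum(annotations$n_components >= k)
}

#' The conserved core of the toolkit
#'
#' A component belongs to the core at coverage threshold `t` iff the fraction
#' of genomes containing at least one architecture annotated with it is
#' `>= t`. With `t = 1` this is the minimal toolkit: components represented
#' in every single genome. Presence is exact architecture-string membership
#' in the genome's table. Lowering `t` can only grow the set (antitone in the
#' threshold); comparing `core_toolkit(..., 1.0)` with `0.9` probes how
#' robust the core is.
#'
#' @param annotations Annotation tibble from [build_annotation_map()].
#' @param genomes Long tibble `genome_id, protein_id, architecture`.
#' @param coverage_threshold Fraction in `(0, 1]`.
#' @return Sorted character vector of component ids.
#' @export
core_toolkit <- function(annotations, genomes, coverage_threshold = 1.0) {
  stopifnot(coverage_threshold > 0, coverage_threshold <= 1)
  cov <- component_coverage(annotations, genomes)
  sort(cov$component_id[cov$coverage >= coverage_threshold])
}

#' @rdname core_toolkit
#' @return `component_coverage()`: tibble `component_id, n_genomes, coverage`
#'   (fraction of genomes containing the component).
#' @export
component_coverage <- function(annotations, genomes) {
  gids <- unique(genomes$genome_id)
  if (length(gids) == 0L) {
    abort("No genomes supplied.", class = "catoolkit_undefined_error")
  }
  long <- tidyr::unnest(
    dplyr::select(annotations, "architecture", "components"),
    "components"
  )
  names(long)[names(long) == "components"] <- "component_id"
  present <- dplyr::distinct(as_tibble(genomes), .data$genome_id, .data$architecture)
  hit <- dplyr::inner_join(long, present, by = "architecture",
                           relationship = "many-to-many") |>
    dplyr::distinct(.data$component_id, .data$genome_id)
  cov <- hit |>
    dplyr::group_by(.data$component_id) |>
    dplyr::summarise(n_genomes = dplyr::n(), .groups = "drop")
  all_comp <- sort(unique(long$component_id))
  cov <- dplyr::left_join(tibble(component_id = all_comp), cov, by = "component_id")
  cov$n_genomes[is.na(cov$n_genomes)] <- 0L
  cov$coverage <- cov$n_genomes / length(gids)
  cov
}

#' Core-toolkit sensitivity sweep
#'
#' Evaluates [core_toolkit()] at several coverage thresholds.
#'
#' @inheritParams core_toolkit
#' @param thresholds Numeric vector of thresholds in `(0, 1]`.
#' @return Tibble `threshold, n_components, components` (list column).
#' @export
core_toolkit_sweep <- function(annotations, genomes, thresholds = c(1.0, 0.9)) {
  cov <- component_coverage(annotations, genomes)
  tibble(
    threshold = thresholds,
    components = lapply(thresholds,
                        function(t) sort(cov$component_id[cov$coverage >= t]))
  ) |>
    dplyr::mutate(n_components = lengths(.data$components)) |>
    dplyr::select("threshold", "n_components", "components")
}

#' Functional breakdown of one genome's annotated architectures
#'
#' Over the distinct architectures present in a genome and found in the
#' annotation map: per-component counts of single-purpose architectures, and
#' the list of multipurpose architectures present. Architectures absent from
#' the annotation map contribute nothing.
#'
#' @param genome Tibble `protein_id, architecture` (one genome).
#' @param annotations Annotation tibble from [build_annotation_map()].
#' @param catalog Optional catalog; when given, components absent from the
#'   genome are reported with a zero count.
#' @param min_components Multipurpose threshold (default 2).
#' @return List with `single_purpose` (tibble `component_id, n`) and
#'   `multipurpose` (tibble `architecture, n_components`).
#' @export
component_breakdown <- function(genome, annotations, catalog = NULL,
                                min_components = 2L) {
  present <- unique(as_tibble(genome)$architecture)
  ann <- classify_purpose(annotations, min_components)
  ann <- ann[ann$architecture %in% present, , drop = FALSE]
  single <- ann[ann$purpose == "single", , drop = FALSE]
  sp <- tibble(component_id = as.character(unlist(single$components))) |>
    dplyr::count(.data$component_id, name = "n")
  if (!is.null(catalog)) {
    sp <- dplyr::left_join(tibble(component_id = sort(catalog$component_id)),
                           sp, by = "component_id")
    sp$n[is.na(sp$n)] <- 0L
  }
  multi <- ann[ann$purpose == "multi", c("architecture", "n_components")]
  list(single_purpose = sp, multipurpose = as_tibble(multi))
}
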