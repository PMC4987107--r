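#' Pipeline run configuration
#'
#' Collects the input paths and thresholds of a full analysis run. All input
#' paths must exist when the configuration is built.
#'
#' @param tree Path to the rooted newick species tree.
#' @param proteomes Directory of `<genome_id>.tsv` proteome tables.
#' @param registry Path to the calcium-binding registry CSV.
#' @param catalog Path to the component catalog TSV.
#' @param components Path to the protein-component TSV.
#' @param out Output directory (created if needed).
#' @param metadata Optional path to a genome metadata TSV.
#' @param min_multi Multipurpose threshold (components per architecture).
#' @param core_thresholds Coverage thresholds for the core-toolkit sweep.
#' @return A `ca_run_config` list.
#' @export
ca_run_config <- function(tree, proteomes, registry, catalog, components, out,
                          metadata = NULL, min_multi = 2L,
                          core_thresholds = c(1.0, 0.9)) {
  paths <- c(tree = tree, proteomes = proteomes, registry = registry,
             catalog = catalog, components = components)
  for (nm in names(paths)) {
    if (!file.exists(paths[[nm]])) {
      abort(sprintf("Input path for '%s' does not exist: %s", nm, paths[[nm]]),
            class = "catoolkit_config_error")
    }
  }
  if (!is.null(metadata) && !file.exists(metadata)) {
    abort(sprintf("Metadata path does not exist: %s", metadata),
          class = "catoolkit_config_error")
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  structure(list(tree = tree, proteomes = proteomes, registry = registry,
                 catalog = catalog, components = components, out = out,
                 metadata = metadata, min_multi = as.integer(min_multi),
                 core_thresholds = core_thresholds),
            class = "ca_run_config")
}

load_inputs <- function(config) {
  list(
    tree = read_species_tree(config$tree),
    genomes = read_proteome_dir(config$proteomes),
    registry = read_ca_registry(config$registry),
    catalog = read_component_catalog(config$catalog),
    protein_components = read_protein_components(config$components),
    metadata = if (!is.null(config$metadata)) read_genome_metadata(config$metadata)
  )
}

#' Run the repertoire-metrics stage
#'
#' Reads all genomes, writes per-genome summaries (with diversity fraction
#' and redundancy ratio where defined; genomes failing the preconditions get
#' `NA` with a warning and are dropped from cross-genome statistics), the
#' genome x superfamily occurrence matrix, and a cross-genome statistics
#' JSON with the abundance-diversity Pearson correlation.
#'
#' @param config A [ca_run_config()].
#' @return Invisibly, list with `summaries`, `occurrence`, `stats`, and the
#'   written file paths.
#' @export
run_metrics <- function(config) {
  inp <- load_inputs(config)
  summ <- summarize_genomes(inp$genomes, inp$registry, inp$metadata)
  summ$diversity_fraction <- ifelse(summ$n_archs_total > 0,
                                    summ$n_ca_archs / summ$n_archs_total,
                                    NA_real_)
  summ$redundancy_ratio <- ifelse(summ$n_ca_archs > 0 & summ$n_archs_total > 0,
    (summ$n_ca_proteins / summ$n_ca_archs) /
      (summ$n_proteins_total / summ$n_archs_total),
    NA_real_)
  dropped <- summ$genome_id[is.na(summ$diversity_fraction) |
                            is.na(summ$redundancy_ratio)]
  if (length(dropped) > 0L) {
    warn(sprintf("%d genome(s) excluded from ratio/correlation statistics: %s",
                 length(dropped), paste(dropped, collapse = ", ")))
  }
  occ <- superfamily_occurrence_matrix(inp$genomes, inp$registry,
                                       genome_ids = summ$genome_id)
  usable <- summ[!summ$genome_id %in% dropped, , drop = FALSE]
  corr <- if (nrow(usable) >= 3L &&
              stats::var(usable$n_ca_proteins) > 0 &&
              stats::var(usable$n_ca_archs) > 0)
    abundance_diversity_correlation(usable) else NA_real_
  stats_json <- list(
    n_genomes = nrow(summ),
    n_genomes_in_correlation = nrow(usable),
    abundance_diversity_pearson_r = corr,
    mean_diversity_fraction = mean(usable$diversity_fraction),
    mean_redundancy_ratio = mean(usable$redundancy_ratio)
  )
  f_sum <- file.path(config$out, "genome_summaries.tsv")
  f_occ <- file.path(config$out, "occurrence_matrix.tsv")
  f_sta <- file.path(config$out, "cross_genome_stats.json")
  readr::write_tsv(summ, f_sum, progress = FALSE)
  readr::write_tsv(occ, f_occ, progress = FALSE)
  jsonlite::write_json(stats_json, f_sta, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(summaries = summ, occurrence = occ, stats = stats_json,
                 files = c(f_sum, f_occ, f_sta)))
}

#' Run the component-annotation stage
#'
#' Builds the architecture annotation map, the core-toolkit sensitivity
#' sweep over the configured coverage thresholds, and per-genome functional
#' breakdowns.
#'
#' @param config A [ca_run_config()].
#' @return Invisibly, list with `annotations`, `core`, `breakdown_single`,
#'   `breakdown_multi`, and the written file paths.
#' @export
run_components <- function(config) {
  inp <- load_inputs(config)
  if (nrow(inp$protein_components) == 0L) {
    abort("Protein-component table is empty.", class = "catoolkit_annotation_error")
  }
  ann <- build_annotation_map(inp$protein_components, inp$genomes,
                              inp$catalog, inp$registry)
  sweep <- core_toolkit_sweep(ann, inp$genomes, config$core_thresholds)
  gids <- sort(unique(inp$genomes$genome_id))
  singles <- list(); multis <- list()
  for (g in gids) {
    br <- component_breakdown(inp$genomes[inp$genomes$genome_id == g, ],
                              ann, inp$catalog, config$min_multi)
    singles[[g]] <- dplyr::bind_cols(tibble(genome_id = rep(g, nrow(br$single_purpose))),
                                     br$single_purpose)
    if (nrow(br$multipurpose) > 0L) {
      multis[[g]] <- dplyr::bind_cols(tibble(genome_id = rep(g, nrow(br$multipurpose))),
                                      br$multipurpose)
    }
  }
  bs <- dplyr::bind_rows(singles)
  bm <- if (length(multis) > 0L) dplyr::bind_rows(multis)
        else tibble(genome_id = character(), architecture = character(),
                    n_components = integer())
  ann_out <- tibble(
    architecture = ann$architecture,
    components = vapply(ann$components, paste, character(1), collapse = ";"),
    n_components = ann$n_components
  )
  core_json <- list(
    thresholds = lapply(seq_len(nrow(sweep)), function(i) list(
      threshold = sweep$threshold[i],
      n_components = sweep$n_components[i],
      components = sweep$components[[i]]
    )),
    n_multipurpose = count_multipurpose(ann, config$min_multi),
    n_multipurpose_3plus = count_multipurpose(ann, 3L)
  )
  f_ann <- file.path(config$out, "annotation_map.tsv")
  f_core <- file.path(config$out, "core_toolkit.json")
  f_bs <- file.path(config$out, "breakdown_single_purpose.tsv")
  f_bm <- file.path(config$out, "breakdown_multipurpose.tsv")
  readr::write_tsv(ann_out, f_ann, progress = FALSE)
  jsonlite::write_json(core_json, f_core, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  readr::write_tsv(bs, f_bs, progress = FALSE)
  readr::write_tsv(bm, f_bm, progress = FALSE)
  invisible(list(annotations = ann, core = sweep, breakdown_single = bs,
                 breakdown_multi = bm,
                 files = c(f_ann, f_core, f_bs, f_bm)))
}

#' Run the ancestral-reconstruction stage
#'
#' Dollo reconstruction of calcium-binding architecture repertoires at every
#' node of the species tree, per-branch gain/loss events, and per-node
#' treemap tables.
#'
#' @param config A [ca_run_config()].
#' @return Invisibly, list with `recon`, `events`, `treemap`, and the
#'   written file paths.
#' @export
run_ancestral <- function(config) {
  inp <- load_inputs(config)
  pres <- presence_from_genomes(inp$genomes, inp$registry)
  recon <- dollo_reconstruct(inp$tree, pres)
  events <- branch_events(recon)
  ann <- build_annotation_map(inp$protein_components, inp$genomes,
                              inp$catalog, inp$registry)
  tm <- treemap_tables(recon, ann, config$min_multi)
  states_tbl <- dplyr::bind_cols(
    tibble(node = rownames(recon$states)),
    as_tibble(matrix(as.integer(recon$states), nrow = nrow(recon$states),
                     dimnames = dimnames(recon$states)))
  )
  f_sta <- file.path(config$out, "ancestral_states.tsv")
  f_ev <- file.path(config$out, "branch_events.tsv")
  f_tm <- file.path(config$out, "treemap_tables.json")
  readr::write_tsv(states_tbl, f_sta, progress = FALSE)
  readr::write_tsv(events, f_ev, progress = FALSE)
  jsonlite::write_json(list(multipurpose = tm$multipurpose,
                            single_purpose = tm$single_purpose),
                       f_tm, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(recon = recon, events = events, treemap = tm,
                 files = c(f_sta, f_ev, f_tm)))
}

#' Run the full pipeline
#'
#' Executes the metrics, components, and ancestral stages in order and
#' writes a manifest JSON listing inputs, package version, and the MD5 hash
#' of every output file. The pipeline is a pure function of its input files
#' and configuration: identical inputs yield identical output hashes.
#'
#' @param config A [ca_run_config()].
#' @return Invisibly, list with the three stage results and the manifest.
#' @export
run_all <- function(config) {
  m <- run_metrics(config)
  cm <- run_components(config)
  an <- run_ancestral(config)
  outputs <- sort(c(m$files, cm$files, an$files))
  manifest <- list(
    package = "catoolkit",
    version = as.character(utils::packageVersion("catoolkit")),
    inputs = list(tree = config$tree, proteomes = config$proteomes,
                  registry = config$registry, catalog = config$catalog,
                  components = config$components,
                  metadata = config$metadata),
    thresholds = list(min_multi = config$min_multi,
                      core_thresholds = config$core_thresholds),
    outputs = lapply(outputs, function(f) list(
      file = basename(f),
      md5 = unname(tools::md5sum(f))
    ))
  )
  f_man <- file.path(config$out, "manifest.json")
  jsonlite::write_json(manifest, f_man, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(metrics = m, components = cm, ancestral = an,
                 manifest = manifest, manifest_file = f_man))
}
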