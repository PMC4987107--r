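#' Read one genome's proteome architecture table
#'
#' A proteome table lists the annotated proteins of one genome, one row per
#' protein, as a TSV with header `protein_id<TAB>architecture`. Proteins with
#' no structural annotation are simply absent: all repertoire totals are over
#' annotated proteins. The genome id defaults to the file name stem
#' (`<genome_id>.tsv`); taxon labels and total gene counts live in a separate
#' metadata table ([read_genome_metadata()]).
#'
#' @param path Path to the TSV file.
#' @param genome_id Genome identifier; defaults to the file name without its
#'   extension.
#' @return A tibble with columns `genome_id`, `protein_id`, `architecture`,
#'   rows in file order. The reader accepts LF or CRLF line endings with or
#'   without a trailing newline.
#' @seealso [write_genome_table()], [read_proteome_dir()]
#' @export
read_genome_table <- function(path, genome_id = NULL) {
  if (is.null(genome_id)) {
    genome_id <- sub("\\.[^.]*$", "", basename(path))
  }
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE, na = character())
  required <- c("protein_id", "architecture")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("Proteome table '%s' lacks column(s): %s.",
                  path, paste(missing, collapse = ", ")),
          class = "catoolkit_io_error")
  }
  if (nrow(df) > 0L) {
    blank <- which(!nzchar(trimws(df$protein_id)))
    if (length(blank) > 0L) {
      abort(sprintf("Proteome table '%s': empty protein_id at data row %d.",
                    path, blank[1]),
            class = "catoolkit_io_error")
    }
    dup <- df$protein_id[duplicated(df$protein_id)]
    if (length(dup) > 0L) {
      abort(sprintf("Proteome table '%s': duplicate protein_id '%s'.",
                    path, dup[1]),
            class = "catoolkit_io_error")
    }
    for (i in seq_len(nrow(df))) {
      tryCatch(parse_architecture(df$architecture[i]), error = function(e) {
        abort(sprintf("Proteome table '%s', data row %d (protein '%s'): %s",
                      path, i, df$protein_id[i], conditionMessage(e)),
              class = "catoolkit_io_error")
      })
    }
  }
  tibble(
    genome_id = rep(genome_id, nrow(df)),
    protein_id = df$protein_id,
    architecture = if (nrow(df)) vapply(df$architecture,
                                        function(s) parse_architecture(s)$source,
                                        character(1), USE.NAMES = FALSE)
                   else character()
  )
}

#' Write one genome's proteome table
#'
#' Writes the canonical TSV form; [read_genome_table()] of the result
#' reproduces the input rows exactly (round trip).
#'
#' @param genome Tibble with columns `protein_id` and `architecture` (a
#'   `genome_id` column, if present, must be constant and is not written).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genome_table <- function(genome, path) {
  stopifnot(all(c("protein_id", "architecture") %in% names(genome)))
  if ("genome_id" %in% names(genome) && nrow(genome) > 0L &&
      length(unique(genome$genome_id)) != 1L) {
    abort("`genome` holds rows from more than one genome_id.",
          class = "catoolkit_io_error")
  }
  if (nrow(genome) > 0L) arch_validate(genome$architecture)
  out <- genome[, c("protein_id", "architecture")]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a directory of proteome tables
#'
#' Reads every `*.tsv` file in `dir` as one genome (file name stem = genome
#' id) and binds them into one long tibble, the package's working
#' representation of a genome collection.
#'
#' @param dir Directory containing `<genome_id>.tsv` files.
#' @return Tibble `genome_id, protein_id, architecture`, genomes in
#'   lexicographic file order.
#' @export
read_proteome_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (length(files) == 0L) {
    abort(sprintf("No .tsv proteome tables found in '%s'.", dir),
          class = "catoolkit_io_error")
  }
  dplyr::bind_rows(lapply(files, read_genome_table))
}

#' Read genome metadata
#'
#' Optional per-genome metadata: TSV with header
#' `genome_id<TAB>taxon_group<TAB>total_gene_count`. Genomes absent from the
#' table default to taxon_group `"unknown"` and a total gene count equal to
#' their annotated protein count; the join is performed by
#' [summarize_genomes()].
#'
#' @param path Path to the metadata TSV.
#' @return Tibble `genome_id, taxon_group, total_gene_count`.
#' @export
read_genome_metadata <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    genome_id = readr::col_character(),
    taxon_group = readr::col_character(),
    total_gene_count = readr::col_integer()
  ), progress = FALSE)
  missing <- setdiff(c("genome_id", "taxon_group", "total_gene_count"), names(df))
  if (length(missing) > 0L) {
    abort(sprintf("Metadata table lacks column(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "catoolkit_io_error")
  }
  as_tibble(df)
}
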