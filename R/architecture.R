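#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

GAP_TOKEN <- "_gap_"

# A domain token is a strictly positive integer in canonical form: no sign, no
# leading zeros. "047473" would not round-trip through format() and is rejected.
is_domain_token <- function(tok) {
  grepl("^[1-9][0-9]*$", tok)
}

#' Parse a domain-architecture string
#'
#' A domain architecture is the ordered N-terminal to C-terminal sequence of
#' SCOP superfamily domains along one protein, serialized as comma-separated
#' superfamily ids with the literal `_gap_` marker for unannotated stretches,
#' e.g. `"47473,_gap_,50729,56112,_gap_"`. At least one token must be a
#' superfamily id: an all-gap string describes no annotated domain and is
#' rejected. Any token that is neither a positive integer nor `_gap_` is an
#' error, never silently treated as a gap.
#'
#' @param text A single architecture string. Leading/trailing whitespace is
#'   stripped; no whitespace is allowed between tokens.
#' @return An object of class `domain_architecture` with elements `tokens`
#'   (character vector of ids and gap markers, in order), `domain_ids`
#'   (integer vector of the superfamily ids, in order), and `source` (the
#'   canonical serialization).
#' @examples
#' a <- parse_architecture("47473,_gap_,50729,56112,_gap_")
#' a$domain_ids
#' format_architecture(a)
#' @seealso [format_architecture()], [arch_domain_count()]
#' @export
parse_architecture <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    abort("`text` must be a single architecture string.",
          class = "catoolkit_parse_error")
  }
  text <- trimws(text)
  if (!nzchar(text)) {
    abort("Empty architecture string.", class = "catoolkit_parse_error")
  }
  tokens <- strsplit(text, ",", fixed = TRUE)[[1]]
  # strsplit drops a trailing empty field; a trailing comma must still fail
  if (grepl(",$", text)) tokens <- c(tokens, "")
  is_gap <- tokens == GAP_TOKEN
  is_dom <- is_domain_token(tokens)
  bad <- which(!is_gap & !is_dom)
  if (length(bad) > 0L) {
    abort(
      sprintf("Malformed architecture token '%s' (position %d) in \"%s\".",
              tokens[bad[1]], bad[1], text),
      class = "catoolkit_parse_error"
    )
  }
  if (!any(is_dom)) {
    abort(
      sprintf("Architecture \"%s\" contains no superfamily id token.", text),
      class = "catoolkit_parse_error"
    )
  }
  structure(
    list(
      tokens = tokens,
      domain_ids = as.integer(tokens[is_dom]),
      source = paste(tokens, collapse = ",")
    ),
    class = "domain_architecture"
  )
}

#' Serialize a domain architecture to its canonical string
#'
#' Inverse of [parse_architecture()]: `parse_architecture(format_architecture(a))`
#' reproduces `a` exactly.
#'
#' @param arch A `domain_architecture` object, or a character vector of tokens
#'   (superfamily ids and `_gap_` markers).
#' @return The canonical comma-separated string.
#' @export
format_architecture <- function(arch) {
  if (inherits(arch, "domain_architecture")) return(arch$source)
  if (is.numeric(arch)) arch <- as.character(as.integer(arch))
  if (!is.character(arch) || length(arch) == 0L) {
    abort("`arch` must be a domain_architecture or a token vector.",
          class = "catoolkit_parse_error")
  }
  out <- paste(arch, collapse = ",")
  parse_architecture(out)  # validate
  out
}

#' @export
print.domain_architecture <- function(x, ...) {
  cat("<domain_architecture> ", x$source, "\n", sep = "")
  cat("  domains: ", length(x$domain_ids),
      "; gaps: ", sum(x$tokens == GAP_TOKEN), "\n", sep = "")
  invisible(x)
}

#' @export
format.domain_architecture <- function(x, ...) x$source

#' @export
`==.domain_architecture` <- function(e1, e2) {
  s1 <- if (inherits(e1, "domain_architecture")) e1$source else as.character(e1)
  s2 <- if (inherits(e2, "domain_architecture")) e2$source else as.character(e2)
  s1 == s2
}

# -- vectorized helpers over architecture-string columns ----------------------

arch_token_list <- function(x) {
  x <- if (inherits(x, "domain_architecture")) x$source else as.character(x)
  strsplit(trimws(x), ",", fixed = TRUE)
}

#' Vectorized token counts for architecture strings
#'
#' Tibble-friendly helpers: each takes a character vector of architecture
#' strings (one per protein) and returns an integer vector. Strings are
#' validated; a malformed element is an error naming its index.
#'
#' @param x Character vector of architecture strings.
#' @return Integer vector: number of superfamily-id tokens
#'   (`arch_domain_count`), number of `_gap_` markers (`arch_gap_count`).
#' @examples
#' arch_domain_count(c("47473,55729", "_gap_,56112"))
#' @export
arch_domain_count <- function(x) {
  arch_validate(x)
  vapply(arch_token_list(x), function(t) sum(is_domain_token(t)), integer(1))
}

#' @rdname arch_domain_count
#' @export
arch_gap_count <- function(x) {
  arch_validate(x)
  vapply(arch_token_list(x), function(t) sum(t == GAP_TOKEN), integer(1))
}

#' Validate a vector of architecture strings
#'
#' @param x Character vector of architecture strings.
#' @return Invisibly, `x`. Errors on the first invalid element, naming it.
#' @export
arch_validate <- function(x) {
  x <- if (inherits(x, "domain_architecture")) x$source else x
  for (i in seq_along(x)) {
    tryCatch(parse_architecture(x[[i]]), error = function(e) {
      abort(sprintf("Invalid architecture at element %d: %s",
                    i, conditionMessage(e)),
            class = "catoolkit_parse_error")
    })
  }
  invisible(x)
}

#' List the superfamily ids of each architecture string
#'
#' @param x Character vector of architecture strings.
#' @return A list of integer vectors, one per element of `x`, in N-to-C order.
#' @export
arch_domain_ids <- function(x) {
  arch_validate(x)
  lapply(arch_token_list(x), function(t) as.integer(t[is_domain_token(t)]))
}

# -- calcium-binding superfamily registry -------------------------------------

#' Read the calcium-binding superfamily registry
#'
#' The registry is the curated set of SCOP superfamilies whose domains bind
#' calcium; an architecture counts as calcium-binding iff it contains at least
#' one registry superfamily. The file is a CSV with header
#' `superfamily_id,name,prosite_ids` (prosite ids semicolon-separated,
#' possibly empty). Duplicate rows are retained in `$entries` exactly as
#' printed but collapsed in `$id_set`, so membership is well-defined. A
#' registry shipped with the package is available via [ca_builtin_registry()].
#'
#' @param path Path to the registry CSV.
#' @return A `ca_registry`: list with `entries` (tibble in file order) and
#'   `id_set` (sorted distinct integer superfamily ids).
#' @export
read_ca_registry <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  required <- c("superfamily_id", "name", "prosite_ids")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("Registry file lacks column(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "catoolkit_registry_error")
  }
  if (nrow(df) == 0L) {
    abort("Registry file has a header but no entries; an empty registry is rejected.",
          class = "catoolkit_registry_error")
  }
  bad <- which(!is_domain_token(df$superfamily_id))
  if (length(bad) > 0L) {
    abort(sprintf("Registry row %d: superfamily_id '%s' is not a positive integer.",
                  bad[1], df$superfamily_id[bad[1]]),
          class = "catoolkit_registry_error")
  }
  if (any(is.na(df$name) | !nzchar(trimws(df$name)))) {
    i <- which(is.na(df$name) | !nzchar(trimws(df$name)))[1]
    abort(sprintf("Registry row %d has an empty name.", i),
          class = "catoolkit_registry_error")
  }
  entries <- tibble(
    superfamily_id = as.integer(df$superfamily_id),
    name = df$name,
    prosite_ids = ifelse(is.na(df$prosite_ids), "", df$prosite_ids)
  )
  ca_registry(entries)
}

#' Construct a registry from an entries table
#'
#' @param entries Tibble/data frame with columns `superfamily_id` (positive
#'   integer), `name`, and optionally `prosite_ids`.
#' @return A `ca_registry` object.
#' @export
ca_registry <- function(entries) {
  entries <- as_tibble(entries)
  if (nrow(entries) == 0L) {
    abort("An empty registry is rejected.", class = "catoolkit_registry_error")
  }
  if (!"prosite_ids" %in% names(entries)) entries$prosite_ids <- ""
  structure(
    list(entries = entries, id_set = sort(unique(as.integer(entries$superfamily_id)))),
    class = "ca_registry"
  )
}

#' @export
print.ca_registry <- function(x, ...) {
  cat(sprintf("<ca_registry> %d entries, %d distinct superfamilies\n",
              nrow(x$entries), length(x$id_set)))
  print(utils::head(x$entries, 5))
  invisible(x)
}

#' Distinct superfamily ids of a registry
#'
#' @param registry A `ca_registry`, or an integer vector of superfamily ids
#'   (accepted anywhere a registry is, for ad hoc sets).
#' @return Sorted integer vector of distinct ids.
#' @export
registry_ids <- function(registry) {
  if (inherits(registry, "ca_registry")) return(registry$id_set)
  if (is.numeric(registry)) return(sort(unique(as.integer(registry))))
  abort("`registry` must be a ca_registry or an integer id vector.",
        class = "catoolkit_registry_error")
}

#' The calcium-binding registry shipped with the package
#'
#' Thirty-one curated entries (30 distinct superfamilies; one superfamily,
#' the TSP type-3 repeat, is listed twice in the curation and both rows are
#' kept). Includes, e.g., the EF-hand (47473) and the GLA
#' gamma-carboxyglutamic acid-rich domain (57630).
#'
#' @return A `ca_registry`.
#' @export
ca_builtin_registry <- function() {
  read_ca_registry(system.file("extdata", "ca_binding_superfamilies.csv",
                               package = "catoolkit", mustWork = TRUE))
}

#' Does an architecture contain a calcium-binding domain?
#'
#' True iff any superfamily id of the architecture is in the registry's
#' distinct id set. `contains_ca_domain()` is the scalar form;
#' `arch_is_ca()` is the vectorized, tibble-friendly form.
#'
#' @param arch A `domain_architecture` or a single architecture string.
#' @param registry A `ca_registry` or integer id vector.
#' @return Logical.
#' @examples
#' reg <- ca_builtin_registry()
#' contains_ca_domain("47473,55729", reg)       # EF-hand present
#' contains_ca_domain("89837,89837,56112", reg) # no registry domain
#' @export
contains_ca_domain <- function(arch, registry) {
  ids <- if (inherits(arch, "domain_architecture")) arch$domain_ids
         else arch_domain_ids(arch)[[1]]
  any(ids %in% registry_ids(registry))
}

#' @rdname contains_ca_domain
#' @param x Character vector of architecture strings.
#' @export
arch_is_ca <- function(x, registry) {
  ids <- registry_ids(registry)
  vapply(arch_domain_ids(x), function(d) any(d %in% ids), logical(1))
}
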