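#' Read a rooted species tree
#'
#' Reads a newick species tree whose leaves are genome ids. Polytomies are
#' allowed and handled natively throughout (no arbitrary binarization).
#' Unnamed internal nodes receive deterministic labels `N1, N2, ...` by
#' preorder index, so outputs are addressable and reproducible; named nodes
#' (e.g. `LECA` at the eukaryote root) keep their names.
#'
#' @param path Path to a newick file, or a newick string ending in `;`.
#' @return An [ape::read.tree()] `phylo` object, rooted, with unique tip and
#'   node labels.
#' @export
read_species_tree <- function(path) {
  tr <- if (grepl(";\\s*$", path)) ape::read.tree(text = path)
        else ape::read.tree(path)
  if (is.null(tr)) {
    abort("Could not parse newick tree.", class = "catoolkit_tree_error")
  }
  normalize_species_tree(tr)
}

normalize_species_tree <- function(tr) {
  if (!inherits(tr, "phylo")) {
    abort("Expected a phylo tree.", class = "catoolkit_tree_error")
  }
  if (ape::Ntip(tr) < 2L) {
    abort("Species tree needs at least 2 leaves.", class = "catoolkit_tree_error")
  }
  if (!ape::is.rooted(tr)) {
    abort("Species tree must be rooted.", class = "catoolkit_tree_error")
  }
  if (anyDuplicated(tr$tip.label)) {
    abort(sprintf("Duplicate leaf label '%s'.",
                  tr$tip.label[duplicated(tr$tip.label)][1]),
          class = "catoolkit_tree_error")
  }
  ntip <- ape::Ntip(tr)
  nnode <- tr$Nnode
  labs <- tr$node.label
  if (is.null(labs)) labs <- rep("", nnode)
  labs[is.na(labs)] <- ""
  # preorder index over internal nodes: root first, then cladewise edge order
  pre <- unique(c(ntip + 1L, reorder(tr, "cladewise")$edge[, 2]))
  pre <- pre[pre > ntip]
  fill <- which(!nzchar(labs))
  rank <- match(fill + ntip, pre)
  labs[fill] <- paste0("N", rank)
  if (anyDuplicated(c(tr$tip.label, labs))) {
    d <- c(tr$tip.label, labs)[duplicated(c(tr$tip.label, labs))][1]
    abort(sprintf("Duplicate node label '%s' after labeling.", d),
          class = "catoolkit_tree_error")
  }
  tr$node.label <- labs
  tr
}

node_labels <- function(tree) {
  c(tree$tip.label, tree$node.label)
}

#' Phyletic presence patterns from genome tables
#'
#' The leaf-level input of [dollo_reconstruct()]: which genomes contain each
#' distinct architecture. Optionally restricted to calcium-binding
#' architectures.
#'
#' @param genomes Long tibble `genome_id, protein_id, architecture`.
#' @param registry Optional `ca_registry`; when given, only architectures
#'   containing a registry domain are kept.
#' @return Tibble `architecture, genome_id`, one row per (architecture,
#'   genome) presence, deduplicated and sorted.
#' @export
presence_from_genomes <- function(genomes, registry = NULL) {
  pres <- dplyr::distinct(as_tibble(genomes), .data$architecture, .data$genome_id)
  if (!is.null(registry)) {
    keep <- arch_is_ca(unique(pres$architecture), registry)
    pres <- pres[pres$architecture %in% unique(pres$architecture)[keep], ,
                 drop = FALSE]
  }
  dplyr::arrange(pres, .data$architecture, .data$genome_id)
}

as_presence_list <- function(leaf_presence) {
  if (is.data.frame(leaf_presence)) {
    stopifnot(all(c("architecture", "genome_id") %in% names(leaf_presence)))
    return(split(leaf_presence$genome_id, leaf_presence$architecture))
  }
  if (is.list(leaf_presence)) return(leaf_presence)
  abort("leaf_presence must be a tibble (architecture, genome_id) or a named list.",
        class = "catoolkit_tree_error")
}

#' Dollo-parsimony reconstruction of ancestral architecture repertoires
#'
#' Under Dollo parsimony an architecture originates exactly once — the
#' independent re-creation of the same multidomain arrangement is treated as
#' improbable — and may subsequently be lost any number of times; losses are
#' minimized. For each architecture the gain node is the most recent common
#' ancestor of the leaves possessing it, and an ancestral node is scored
#' present iff it lies at or below the gain node and at least one possessing
#' leaf survives in its subtree. This assignment attains the minimum number
#' of losses among all single-gain histories consistent with the leaves.
#'
#' @param tree Rooted species tree from [read_species_tree()].
#' @param leaf_presence Either a tibble `architecture, genome_id`
#'   ([presence_from_genomes()]) or a named list mapping each architecture to
#'   the character vector of leaves possessing it. Every architecture must be
#'   present in at least one leaf; unknown leaf labels are errors.
#' @return A `dollo_reconstruction`: list with `tree`, `states` (logical
#'   node x architecture matrix; rownames are node labels, leaves first),
#'   `gains` (tibble `architecture, gain_node`), and `losses` (tibble
#'   `architecture, n_losses`). Explore with [tidy()], [glance()],
#'   [branch_events()], [lineage_trajectory()], [treemap_tables()].
#' @examples
#' tr <- read_species_tree("((A,B),(C,D));")
#' rec <- dollo_reconstruct(tr, list("47473" = c("A", "C")))
#' tidy(rec)
#' branch_events(rec)
#' @export
dollo_reconstruct <- function(tree, leaf_presence) {
  tree <- normalize_species_tree(tree)
  pres <- as_presence_list(leaf_presence)
  if (length(pres) == 0L) {
    abort("No architectures supplied.", class = "catoolkit_tree_error")
  }
  archs <- sort(names(pres))
  ntip <- ape::Ntip(tree)
  ntot <- ntip + tree$Nnode
  labs <- node_labels(tree)
  post <- reorder(tree, "postorder")$edge   # child after its subtree
  pre <- reorder(tree, "cladewise")$edge    # parent before child

  states <- matrix(FALSE, nrow = ntot, ncol = length(archs),
                   dimnames = list(labs, archs))
  gain_node <- character(length(archs))
  n_losses <- integer(length(archs))

  for (j in seq_along(archs)) {
    leaves <- unique(as.character(pres[[archs[j]]]))
    if (length(leaves) == 0L) {
      abort(sprintf("Architecture '%s' has an empty presence set.", archs[j]),
            class = "catoolkit_tree_error")
    }
    idx <- match(leaves, tree$tip.label)
    if (anyNA(idx)) {
      abort(sprintf("Unknown leaf label '%s' for architecture '%s'.",
                    leaves[which(is.na(idx))[1]], archs[j]),
            class = "catoolkit_tree_error")
    }
    # subtree counts of possessing leaves
    cnt <- integer(ntot)
    cnt[idx] <- 1L
    for (e in seq_len(nrow(post))) {
      cnt[post[e, 1]] <- cnt[post[e, 1]] + cnt[post[e, 2]]
    }
    gain <- if (length(idx) == 1L) idx else ape::getMRCA(tree, idx)
    # membership in subtree(gain), preorder propagation
    under <- logical(ntot)
    under[gain] <- TRUE
    for (e in seq_len(nrow(pre))) {
      if (under[pre[e, 1]]) under[pre[e, 2]] <- TRUE
    }
    present <- under & cnt > 0L
    states[, j] <- present
    gain_node[j] <- labs[gain]
    n_losses[j] <- sum(present[pre[, 1]] & !present[pre[, 2]])
  }

  structure(
    list(
      tree = tree,
      states = states,
      gains = tibble(architecture = archs, gain_node = gain_node),
      losses = tibble(architecture = archs, n_losses = n_losses)
    ),
    class = "dollo_reconstruction"
  )
}

#' @export
print.dollo_reconstruction <- function(x, ...) {
  cat(sprintf("<dollo_reconstruction> %d architectures on %d-leaf tree (%d nodes)\n",
              ncol(x$states), ape::Ntip(x$tree), nrow(x$states)))
  cat(sprintf("  total gains: %d; total losses: %d\n",
              ncol(x$states), sum(x$losses$n_losses)))
  invisible(x)
}

#' Tidy a Dollo reconstruction into a long node-state table
#'
#' @param x A `dollo_reconstruction`.
#' @param ... Unused.
#' @return Tibble `node, architecture, present`, one row per node and
#'   architecture.
#' @method tidy dollo_reconstruction
#' @export
tidy.dollo_reconstruction <- function(x, ...) {
  tibble(
    node = rep(rownames(x$states), times = ncol(x$states)),
    architecture = rep(colnames(x$states), each = nrow(x$states)),
    present = as.vector(x$states)
  )
}

#' One-row summary of a Dollo reconstruction
#'
#' @param x A `dollo_reconstruction`.
#' @param ... Unused.
#' @return Tibble with `n_architectures`, `n_leaves`, `n_nodes`, `n_gains`
#'   (one per architecture by construction), `n_losses`,
#'   `n_root_architectures`.
#' @method glance dollo_reconstruction
#' @export
glance.dollo_reconstruction <- function(x, ...) {
  root <- ape::Ntip(x$tree) + 1L
  tibble(
    n_architectures = ncol(x$states),
    n_leaves = ape::Ntip(x$tree),
    n_nodes = nrow(x$states),
    n_gains = ncol(x$states),
    n_losses = sum(x$losses$n_losses),
    n_root_architectures = sum(x$states[root, ])
  )
}

#' Per-branch gain and loss events
#'
#' Maps a reconstruction onto branches: an architecture is gained on the
#' branch (parent -> child) iff absent at the parent and present at the
#' child, lost iff present at the parent and absent at the child. The root's
#' incoming branch (parent `NA`) carries the gains of architectures present
#' at the root. Rows are sorted for reproducible output.
#'
#' @param recon A `dollo_reconstruction`.
#' @return Tibble `parent, child, event, architecture` with
#'   `event %in% c("gain", "loss")`.
#' @export
branch_events <- function(recon) {
  stopifnot(inherits(recon, "dollo_reconstruction"))
  tree <- recon$tree
  labs <- node_labels(tree)
  root <- ape::Ntip(tree) + 1L
  states <- recon$states
  edges <- tree$edge
  out <- list()
  root_arch <- colnames(states)[states[root, ]]
  if (length(root_arch) > 0L) {
    out[[1]] <- tibble(parent = NA_character_, child = labs[root],
                       event = "gain", architecture = root_arch)
  }
  for (e in seq_len(nrow(edges))) {
    p <- edges[e, 1]; ch <- edges[e, 2]
    gained <- colnames(states)[!states[p, ] & states[ch, ]]
    lost <- colnames(states)[states[p, ] & !states[ch, ]]
    if (length(gained) > 0L) {
      out[[length(out) + 1L]] <- tibble(parent = labs[p], child = labs[ch],
                                        event = "gain", architecture = gained)
    }
    if (length(lost) > 0L) {
      out[[length(out) + 1L]] <- tibble(parent = labs[p], child = labs[ch],
                                        event = "loss", architecture = lost)
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble(parent = character(), child = character(),
                  event = character(), architecture = character())
  }
  dplyr::arrange(res, !is.na(.data$parent), .data$parent, .data$child,
                 .data$event, .data$architecture)
}

root_to_leaf_path <- function(tree, leaf) {
  idx <- match(leaf, tree$tip.label)
  if (is.na(idx)) {
    abort(sprintf("Unknown leaf '%s'.", leaf), class = "catoolkit_tree_error")
  }
  parent <- integer(ape::Ntip(tree) + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  path <- idx
  while (parent[path[1]] != 0L) path <- c(parent[path[1]], path)
  path
}

node_repertoire_stats <- function(present_archs, annotations, min_components) {
  ann <- classify_purpose(annotations, min_components)
  ann <- ann[ann$architecture %in% present_archs, , drop = FALSE]
  single <- ann[ann$purpose == "single", , drop = FALSE]
  sp <- tibble(component_id = unlist(single$components))
  sp <- if (nrow(sp) > 0L) dplyr::count(sp, .data$component_id, name = "n")
        else tibble(component_id = character(), n = integer())
  list(
    n_annotated = nrow(ann),
    n_multipurpose = sum(ann$purpose == "multi"),
    n_single = sum(ann$purpose == "single"),
    single_purpose = sp
  )
}

#' Trace one lineage from the root to a leaf
#'
#' Walks the root-to-leaf path and reports, at every node, the reconstructed
#' repertoire intersected with the annotation map: how many multipurpose
#' architectures were present, and per-component counts of single-purpose
#' architectures.
#'
#' @param recon A `dollo_reconstruction`.
#' @param leaf A genome id (tip label).
#' @param annotations Annotation tibble from [build_annotation_map()].
#' @param min_components Multipurpose threshold (default 2).
#' @return Tibble with one row per node on the path (root first):
#'   `node, depth, n_present, n_annotated, n_multipurpose, single_purpose`
#'   (list column of per-component count tibbles).
#' @export
lineage_trajectory <- function(recon, leaf, annotations, min_components = 2L) {
  stopifnot(inherits(recon, "dollo_reconstruction"))
  tree <- recon$tree
  labs <- node_labels(tree)
  path <- root_to_leaf_path(tree, leaf)
  rows <- lapply(seq_along(path), function(i) {
    nd <- path[i]
    present <- colnames(recon$states)[recon$states[nd, ]]
    st <- node_repertoire_stats(present, annotations, min_components)
    tibble(node = labs[nd], depth = i - 1L, n_present = length(present),
           n_annotated = st$n_annotated, n_multipurpose = st$n_multipurpose,
           single_purpose = list(st$single_purpose))
  })
  dplyr::bind_rows(rows)
}

#' Treemap tables of ancestral and extant repertoires
#'
#' Tabular form of per-node repertoire treemaps: for every node of the tree,
#' the number and percentage of multipurpose architectures among annotated
#' architectures present at that node, and the percentage of single-purpose
#' architectures dedicated to each component (summing to 100 per node when
#' any single-purpose architecture is present).
#'
#' @param recon A `dollo_reconstruction`.
#' @param annotations Annotation tibble from [build_annotation_map()].
#' @param min_components Multipurpose threshold (default 2).
#' @return List of two tibbles: `multipurpose`
#'   (`node, n_annotated, n_multipurpose, n_single, pct_multipurpose, empty`)
#'   and `single_purpose` (`node, component_id, n, pct`).
#' @export
treemap_tables <- function(recon, annotations, min_components = 2L) {
  stopifnot(inherits(recon, "dollo_reconstruction"))
  labs <- rownames(recon$states)
  multi_rows <- list()
  sp_rows <- list()
  for (i in seq_along(labs)) {
    present <- colnames(recon$states)[recon$states[i, ]]
    st <- node_repertoire_stats(present, annotations, min_components)
    multi_rows[[i]] <- tibble(
      node = labs[i],
      n_annotated = st$n_annotated,
      n_multipurpose = st$n_multipurpose,
      n_single = st$n_single,
      pct_multipurpose = if (st$n_annotated > 0)
        100 * st$n_multipurpose / st$n_annotated else NA_real_,
      empty = st$n_annotated == 0L
    )
    if (nrow(st$single_purpose) > 0L) {
      sp <- st$single_purpose
      sp$pct <- 100 * sp$n / sum(sp$n)
      sp_rows[[length(sp_rows) + 1L]] <- dplyr::bind_cols(
        tibble(node = rep(labs[i], nrow(sp))), sp)
    }
  }
  sp_tbl <- if (length(sp_rows) > 0L) dplyr::bind_rows(sp_rows)
            else tibble(node = character(), component_id = character(),
                        n = integer(), pct = numeric())
  list(
    multipurpose = dplyr::bind_rows(multi_rows),
    single_purpose = sp_tbl
  )
}
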