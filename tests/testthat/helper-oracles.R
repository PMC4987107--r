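# Independent brute-force oracles. These never call the code paths they
# check: minimal Dollo loss counts are found by exhaustive enumeration of
# every single-gain state assignment, and coverage sets by direct counting.

# Minimum number of losses over all single-gain histories consistent with
# the observed leaf pattern. A history is a presence set forming a connected
# subtree with a unique top node (the gain); losses are branches from a
# present parent to an absent child. Enumerates presence of internal nodes
# exhaustively (leaf states are fixed by the pattern).
oracle_min_losses <- function(tree, present_leaves) {
  ntip <- ape::Ntip(tree)
  ntot <- ntip + tree$Nnode
  edges <- tree$edge
  root <- ntip + 1L
  parent <- integer(ntot)
  parent[edges[, 2]] <- edges[, 1]
  parent[root] <- root  # self-parent so vectorized indexing stays aligned
  leaf_state <- logical(ntip)
  leaf_state[match(present_leaves, tree$tip.label)] <- TRUE
  internals <- (ntip + 1L):ntot
  nint <- length(internals)
  best <- Inf
  for (mask in 0:(2^nint - 1)) {
    present <- logical(ntot)
    present[seq_len(ntip)] <- leaf_state
    present[internals] <- bitwAnd(mask, 2^(seq_len(nint) - 1)) > 0
    pres_nodes <- which(present)
    if (length(pres_nodes) == 0L) next
    # tops: present nodes whose parent is absent (or which are the root)
    tops <- pres_nodes[pres_nodes == root | !present[parent[pres_nodes]]]
    if (length(tops) != 1L) next  # not a single-gain history
    losses <- sum(present[edges[, 1]] & !present[edges[, 2]])
    if (losses < best) best <- losses
  }
  best
}

# Direct coverage counting for the core toolkit: a component is covered by a
# genome iff some architecture of that genome is annotated with it.
oracle_core <- function(annotations, genomes, threshold) {
  gids <- unique(genomes$genome_id)
  comps <- sort(unique(unlist(annotations$components)))
  keep <- vapply(comps, function(cc) {
    archs <- annotations$architecture[vapply(annotations$components,
                                             function(v) cc %in% v, logical(1))]
    covered <- vapply(gids, function(g) {
      any(genomes$architecture[genomes$genome_id == g] %in% archs)
    }, logical(1))
    mean(covered) >= threshold
  }, logical(1))
  comps[keep]
}

# Random annotation map + genome set for coverage trials.
random_annotation_dataset <- function(n_genomes = 5, n_archs = 12, n_comp = 4) {
  archs <- paste0(sample(10000:99999, n_archs))
  comps <- paste0("comp", seq_len(n_comp))
  ann <- tibble::tibble(
    architecture = sort(archs),
    components = lapply(seq_len(n_archs), function(i)
      sort(sample(comps, sample(1:2, 1))))
  )
  ann$n_components <- lengths(ann$components)
  rows <- list()
  for (g in seq_len(n_genomes)) {
    picked <- sample(archs, sample(seq_len(n_archs), 1))
    rows[[g]] <- tibble::tibble(
      genome_id = sprintf("g%02d", g),
      protein_id = sprintf("g%02d_p%03d", g, seq_along(picked)),
      architecture = picked
    )
  }
  list(annotations = ann, genomes = dplyr::bind_rows(rows))
}
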