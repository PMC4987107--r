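# Local RNG scope: save/restore the global stream so simulation never
# perturbs a caller's randomness, and a fixed seed gives identical output.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Bundles the parameters of the synthetic toolkit simulator. Defaults are
#' the package's standing study conditions: a 20-leaf tree carrying 200
#' architectures, 80% of them calcium-binding, gains placed uniformly over
#' internal nodes, a 10% per-branch loss probability, 1 + Poisson(1) protein
#' copies per present architecture per genome, and 1 + Poisson(0.4)
#' component labels per architecture.
#'
#' @param n_leaves Number of genomes (tree leaves), >= 2.
#' @param seed Integer seed; a fixed seed yields byte-identical emitted
#'   datasets.
#' @param n_architectures Number of distinct architectures evolved, >= 1.
#' @param fraction_ca Fraction of architectures built to contain at least one
#'   registry superfamily.
#' @param gain_placement `"uniform"` over internal nodes, or `"root_biased"`
#'   (root with probability 1/2, otherwise uniform).
#' @param loss_prob_per_branch Per-branch loss probability in `[0, 1)`.
#' @param copy_number_law List `list(name, ...)`: `"one_plus_poisson"` with
#'   `lambda`, or `"constant"` with `value`.
#' @param component_count_law Same forms, for labels per architecture.
#' @param terminal_losses_only If `TRUE`, losses are drawn on terminal
#'   branches only, a regime in which Dollo parsimony recovers the true
#'   history exactly.
#' @param gap_prob Probability of inserting a `_gap_` marker after each
#'   domain position (exercises the string dialect).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_leaves = 20L, seed = 1L, n_architectures = 200L,
                       fraction_ca = 0.8, gain_placement = "uniform",
                       loss_prob_per_branch = 0.1,
                       copy_number_law = list(name = "one_plus_poisson", lambda = 1),
                       component_count_law = list(name = "one_plus_poisson", lambda = 0.4),
                       terminal_losses_only = FALSE, gap_prob = 0.15) {
  stopifnot(n_leaves >= 2L, n_architectures >= 1L,
            fraction_ca >= 0, fraction_ca <= 1,
            loss_prob_per_branch >= 0, loss_prob_per_branch < 1,
            gap_prob >= 0, gap_prob < 1,
            gain_placement %in% c("uniform", "root_biased"))
  structure(list(
    n_leaves = as.integer(n_leaves), seed = as.integer(seed),
    n_architectures = as.integer(n_architectures), fraction_ca = fraction_ca,
    gain_placement = gain_placement,
    loss_prob_per_branch = loss_prob_per_branch,
    copy_number_law = copy_number_law,
    component_count_law = component_count_law,
    terminal_losses_only = isTRUE(terminal_losses_only),
    gap_prob = gap_prob
  ), class = "sim_config")
}

draw_law <- function(law, n) {
  switch(law$name,
    one_plus_poisson = 1L + stats::rpois(n, law$lambda),
    constant = rep(as.integer(law$value), n),
    abort(sprintf("Unknown law '%s'.", law$name), class = "catoolkit_sim_error")
  )
}

#' Simulate a rooted bifurcating species tree
#'
#' Grows a random bifurcating topology by uniform attachment: starting from
#' a two-leaf tree, each new leaf is attached on a branch chosen uniformly
#' at random (the root's incoming branch included). Leaves are named
#' `G0001, G0002, ...`; the result is deterministic under the seed.
#'
#' @param n_leaves Number of leaves, >= 2.
#' @param seed Integer seed.
#' @return A rooted `phylo` tree with internal labels assigned by
#'   [read_species_tree()] conventions.
#' @export
simulate_tree <- function(n_leaves, seed = 1L) {
  stopifnot(n_leaves >= 2L)
  with_local_seed(seed, {
    # nodes: list(label or NULL, children int vector); parent pointer vector
    children <- list(c(2L, 3L), integer(), integer())
    label <- c(NA, "G0001", "G0002")
    parent <- c(0L, 1L, 1L)
    root <- 1L
    if (n_leaves > 2L) {
      for (k in 3:n_leaves) {
        target <- sample(seq_along(children), 1L)  # attach on branch above target
        leaf <- length(children) + 1L
        children[[leaf]] <- integer()
        label[leaf] <- sprintf("G%04d", k)
        parent[leaf] <- 0L
        x <- length(children) + 1L
        children[[x]] <- c(target, leaf)
        label[x] <- NA
        parent[x] <- parent[target]
        if (target == root) {
          root <- x
        } else {
          p <- parent[target]
          children[[p]][children[[p]] == target] <- x
        }
        parent[target] <- x
        parent[leaf] <- x
      }
    }
    nwk <- function(i) {
      if (length(children[[i]]) == 0L) return(label[i])
      paste0("(", paste(vapply(children[[i]], nwk, character(1)), collapse = ","), ")")
    }
    read_species_tree(paste0(nwk(root), ";"))
  })
}

#' Simulate toolkit evolution along a tree
#'
#' Evolves architecture repertoires with known ground truth: each
#' architecture is gained once at a sampled node, propagated to descendants
#' with independent per-branch loss draws, materialized in each possessing
#' leaf genome as one or more protein copies, and labeled with functional
#' components (calcium-binding components only onto calcium-binding
#' architectures, so labels are consistent with the registry restriction of
#' [build_annotation_map()]). Architectures whose history leaves no
#' surviving leaf are redrawn. Randomness uses one sub-stream per
#' architecture index, derived from the configuration seed, so output does
#' not depend on evaluation order.
#'
#' @param tree Optional rooted `phylo`; simulated from the config when `NULL`.
#' @param config A [sim_config()].
#' @param registry Calcium-binding registry (default the built-in one).
#' @param catalog Component catalog (default the shipped example).
#' @return List of class `ca_simulation`: `tree`, `genomes` (long tibble),
#'   `metadata`, `protein_components`, `registry`, `catalog`, and `truth`
#'   (list: `states` node x architecture logical matrix, `events` tibble,
#'   `component_map`, `copy_numbers`, `ca_architectures`).
#' @export
simulate_repertoire_evolution <- function(tree = NULL, config = sim_config(),
                                          registry = ca_builtin_registry(),
                                          catalog = ca_example_catalog()) {
  if (is.null(tree)) tree <- simulate_tree(config$n_leaves, config$seed)
  tree <- normalize_species_tree(tree)
  ntip <- ape::Ntip(tree)
  ntot <- ntip + tree$Nnode
  labs <- node_labels(tree)
  pre <- reorder(tree, "cladewise")$edge
  post <- reorder(tree, "postorder")$edge
  root <- ntip + 1L
  internals <- (ntip + 1L):ntot
  reg_ids <- registry_ids(registry)
  universe <- setdiff(10000:99999, reg_ids)
  n_arch <- config$n_architectures
  n_ca <- round(config$fraction_ca * n_arch)
  comp_nonca <- catalog$component_id[!catalog$binds_calcium]
  if (n_ca < n_arch && length(comp_nonca) == 0L) {
    abort("Catalog has no non-calcium-binding components to label non-registry architectures.",
          class = "catoolkit_sim_error")
  }

  arch_string <- character(n_arch)
  states <- matrix(FALSE, nrow = ntot, ncol = n_arch, dimnames = list(labs, NULL))
  gain_nodes <- integer(n_arch)
  comp_map <- vector("list", n_arch)
  copy_rows <- vector("list", n_arch)

  used <- new.env(parent = emptyenv())
  for (j in seq_len(n_arch)) {
    sub_seed <- (config$seed %% 1000003L) * 2011L + j
    with_local_seed(sub_seed, {
      is_ca <- j <= n_ca
      # architecture tokens (redraw on string collision)
      repeat {
        ndom <- sample(1:4, 1L, prob = c(0.4, 0.3, 0.2, 0.1))
        ids <- sample(universe, ndom, replace = TRUE)
        if (is_ca) ids[sample.int(ndom, 1L)] <- sample(reg_ids, 1L)
        toks <- character(0)
        for (d in seq_len(ndom)) {
          toks <- c(toks, as.character(ids[d]))
          if (stats::runif(1) < config$gap_prob) toks <- c(toks, GAP_TOKEN)
        }
        s <- paste(toks, collapse = ",")
        if (is.null(used[[s]])) { used[[s]] <- TRUE; break }
      }
      arch_string[j] <- s
      # gain and loss history (redraw if no leaf survives)
      repeat {
        gain <- switch(config$gain_placement,
          uniform = internals[sample.int(length(internals), 1L)],
          root_biased = if (stats::runif(1) < 0.5) root
                        else internals[sample.int(length(internals), 1L)]
        )
        present <- logical(ntot)
        present[gain] <- TRUE
        under <- logical(ntot)
        under[gain] <- TRUE
        for (e in seq_len(nrow(pre))) {
          p <- pre[e, 1]; ch <- pre[e, 2]
          if (under[p]) {
            under[ch] <- TRUE
            if (present[p]) {
              can_lose <- !config$terminal_losses_only || ch <= ntip
              lost <- can_lose && stats::runif(1) < config$loss_prob_per_branch
              present[ch] <- !lost
            }
          }
        }
        surv <- which(present[seq_len(ntip)])
        if (length(surv) == 0L) next
        if (!config$terminal_losses_only) break
        # The terminal-losses regime is the package's exact-recovery oracle:
        # keep only histories Dollo parsimony can identify, i.e. the
        # survivors' MRCA is the gain node and every present node retains a
        # surviving possessor in its subtree.
        cnt <- integer(ntot)
        cnt[surv] <- 1L
        for (e in seq_len(nrow(post))) {
          cnt[post[e, 1]] <- cnt[post[e, 1]] + cnt[post[e, 2]]
        }
        m <- if (length(surv) == 1L) surv else ape::getMRCA(tree, surv)
        if (m == gain && all(!present | cnt > 0L)) break
      }
      states[, j] <- present
      gain_nodes[j] <- gain
      # component labels
      eligible <- if (is_ca) catalog$component_id else comp_nonca
      k <- min(draw_law(config$component_count_law, 1L), length(eligible))
      comp_map[[j]] <- sort(sample(eligible, k))
      # copy numbers per possessing leaf, leaves in label order
      leaves <- which(present[seq_len(ntip)])
      leaves <- leaves[order(tree$tip.label[leaves])]
      if (length(leaves) > 0L) {
        copies <- draw_law(config$copy_number_law, length(leaves))
        copy_rows[[j]] <- tibble(genome_id = tree$tip.label[leaves],
                                  arch_index = j, n_copies = as.integer(copies))
      }
    })
  }

  copy_tbl <- dplyr::bind_rows(copy_rows)
  copy_tbl$architecture <- arch_string[copy_tbl$arch_index]

  # materialize proteomes: per genome, architectures in arch_index order
  copy_tbl <- dplyr::arrange(copy_tbl, .data$genome_id, .data$arch_index)
  genomes <- copy_tbl |>
    dplyr::reframe(architecture = rep(.data$architecture, .data$n_copies),
                   arch_index = rep(.data$arch_index, .data$n_copies),
                   .by = "genome_id") |>
    dplyr::group_by(.data$genome_id) |>
    dplyr::mutate(protein_id = sprintf("%s_P%04d", .data$genome_id,
                                       dplyr::row_number())) |>
    dplyr::ungroup()

  # one representative protein per (architecture, genome) carries the labels
  reps <- genomes |>
    dplyr::distinct(.data$genome_id, .data$arch_index, .keep_all = TRUE)
  pct <- reps |>
    dplyr::reframe(component_id = comp_map[[.data$arch_index[1]]],
                   .by = c("genome_id", "arch_index", "protein_id")) |>
    dplyr::select("protein_id", "genome_id", "component_id") |>
    dplyr::arrange(.data$genome_id, .data$protein_id, .data$component_id)

  genomes <- dplyr::select(genomes, "genome_id", "protein_id", "architecture")

  colnames(states) <- arch_string
  recon_like <- structure(list(tree = tree, states = states), # for event mapping
                          class = "dollo_reconstruction")
  truth_events <- branch_events(recon_like)

  metadata <- genomes |>
    dplyr::count(.data$genome_id, name = "n") |>
    dplyr::transmute(.data$genome_id, taxon_group = "synthetic",
                     total_gene_count = as.integer(.data$n))

  structure(list(
    tree = tree,
    config = config,
    genomes = genomes,
    metadata = metadata,
    protein_components = pct,
    registry = registry,
    catalog = catalog,
    truth = list(
      states = states,
      gain_nodes = tibble(architecture = arch_string,
                          gain_node = labs[gain_nodes]),
      events = truth_events,
      component_map = tibble(architecture = arch_string,
                             components = comp_map,
                             n_components = lengths(comp_map)),
      copy_numbers = dplyr::select(copy_tbl, "genome_id", "architecture",
                                   "n_copies"),
      ca_architectures = arch_string[seq_len(n_ca)]
    )
  ), class = "ca_simulation")
}

#' @rdname simulate_repertoire_evolution
#' @details `simulate_toolkit()` is the one-call form: simulates the tree
#'   from the configuration and evolves the repertoire on it.
#' @export
simulate_toolkit <- function(config = sim_config(),
                             registry = ca_builtin_registry(),
                             catalog = ca_example_catalog()) {
  simulate_repertoire_evolution(NULL, config, registry, catalog)
}

#' @export
print.ca_simulation <- function(x, ...) {
  cat(sprintf("<ca_simulation> %d genomes, %d architectures, %d proteins (seed %d)\n",
              ape::Ntip(x$tree), ncol(x$truth$states), nrow(x$genomes),
              x$config$seed))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits the full file bundle the pipeline consumes: one proteome TSV per
#' genome under `proteomes/`, `metadata.tsv`, `tree.nwk`, `registry.csv`,
#' `catalog.tsv`, `protein_components.tsv`, and a `truth.json` with the
#' planted states, events, component map, and copy numbers. Emission is
#' deterministic: re-running the same simulation writes byte-identical
#' files.
#'
#' @param sim A `ca_simulation`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a character vector of the files written.
#' @export
emit_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "ca_simulation"))
  dir.create(file.path(dir, "proteomes"), recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (g in sort(unique(sim$genomes$genome_id))) {
    p <- file.path(dir, "proteomes", paste0(g, ".tsv"))
    write_genome_table(sim$genomes[sim$genomes$genome_id == g, ], p)
    files <- c(files, p)
  }
  readr::write_tsv(sim$metadata, file.path(dir, "metadata.tsv"), progress = FALSE)
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  readr::write_csv(sim$registry$entries, file.path(dir, "registry.csv"),
                   progress = FALSE)
  readr::write_tsv(sim$catalog, file.path(dir, "catalog.tsv"), progress = FALSE)
  readr::write_tsv(sim$protein_components,
                   file.path(dir, "protein_components.tsv"), progress = FALSE)
  truth <- list(
    seed = sim$config$seed,
    architectures = colnames(sim$truth$states),
    nodes = rownames(sim$truth$states),
    states = unname(lapply(seq_len(ncol(sim$truth$states)),
                           function(j) as.integer(sim$truth$states[, j]))),
    gain_nodes = sim$truth$gain_nodes,
    events = sim$truth$events,
    component_map = list(
      architecture = sim$truth$component_map$architecture,
      components = sim$truth$component_map$components
    ),
    copy_numbers = sim$truth$copy_numbers,
    ca_architectures = sim$truth$ca_architectures
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, file.path(dir, c("metadata.tsv", "tree.nwk", "registry.csv",
                                     "catalog.tsv", "protein_components.tsv",
                                     "truth.json")))
  invisible(files)
}
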