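test_that("species trees read with deterministic internal labels", {
  tr <- read_species_tree("((A,B),C);")
  expect_identical(ape::Ntip(tr), 3L)
  expect_identical(tr$Nnode, 2L)
  expect_identical(tr$node.label[1], "N1")  # root gets the first preorder id

  tr4 <- read_species_tree("((A,B),(C,D));")
  expect_identical(ape::Ntip(tr4), 4L)
  expect_identical(tr4$node.label, c("N1", "N2", "N3"))

  named <- read_species_tree("((A,B)X,(C,D))LECA;")
  expect_identical(named$node.label[1], "LECA")
  expect_true("X" %in% named$node.label)

  expect_error(read_species_tree("(A,B,C);"), "rooted",
               class = "catoolkit_tree_error")
  expect_error(read_species_tree("((A,A),B);"), "Duplicate",
               class = "catoolkit_tree_error")
  polytomy <- read_species_tree("((A,B,C),D);")  # internal polytomy is fine
  expect_identical(ape::Ntip(polytomy), 4L)
})

test_that("Dollo reconstruction places the gain at the MRCA and minimizes losses", {
  tr3 <- read_species_tree("((A,B),C);")
  one <- dollo_reconstruct(tr3, list(x = "A"))
  expect_identical(rownames(one$states)[one$states[, "x"]], "A")
  expect_identical(one$gains$gain_node, "A")
  expect_identical(one$losses$n_losses, 0L)

  tr4 <- read_species_tree("((A,B),(C,D));")
  two <- dollo_reconstruct(tr4, list(x = c("A", "C")))
  expect_setequal(rownames(two$states)[two$states[, "x"]],
                  c("N1", "N2", "N3", "A", "C"))
  expect_identical(two$gains$gain_node, "N1")
  expect_identical(two$losses$n_losses, 2L)

  all4 <- dollo_reconstruct(tr4, list(x = c("A", "B", "C", "D")))
  expect_true(all(all4$states[, "x"]))
  expect_identical(all4$losses$n_losses, 0L)

  expect_error(dollo_reconstruct(tr4, list(x = "Z")), "Unknown leaf",
               class = "catoolkit_tree_error")
  expect_error(dollo_reconstruct(tr4, list(x = character())),
               class = "catoolkit_tree_error")
})

test_that("reconstructed loss counts equal the brute-force minimum on small shapes", {
  for (nwk in tree_shapes_upto6(5)) {
    tr <- read_species_tree(nwk)
    tips <- tr$tip.label
    for (mask in 1:(2^length(tips) - 1)) {
      leaves <- tips[bitwAnd(mask, 2^(seq_along(tips) - 1)) > 0]
      rec <- dollo_reconstruct(tr, list(a = leaves))
      expect_identical(rec$losses$n_losses, as.integer(
        oracle_min_losses(tr, leaves)))
      # leaf fidelity and single-gain invariant
      expect_setequal(tips[rec$states[seq_along(tips), "a"]], leaves)
      ev <- branch_events(rec)
      expect_identical(sum(ev$event == "gain"), 1L)
    }
  }
})

test_that("branch events map state changes with the gain on the root's branch", {
  tr4 <- read_species_tree("((A,B),(C,D));")
  ev <- branch_events(dollo_reconstruct(tr4, list(x = c("A", "C"))))
  gain <- ev[ev$event == "gain", ]
  expect_true(is.na(gain$parent))  # gained at the root => root's incoming branch
  expect_identical(gain$child, "N1")
  losses <- ev[ev$event == "loss", ]
  expect_setequal(losses$child, c("B", "D"))

  ev_all <- branch_events(dollo_reconstruct(tr4, list(x = LETTERS[1:4])))
  expect_identical(nrow(ev_all), 1L)
  expect_true(is.na(ev_all$parent) && ev_all$child == "N1" &&
                ev_all$event == "gain")
})

test_that("event parity equals state flips along every root-to-leaf path", {
  sim <- simulate_toolkit(sim_config(n_leaves = 10, n_architectures = 40,
                                     seed = 13))
  rec <- dollo_reconstruct(sim$tree, presence_from_genomes(sim$genomes))
  ev <- branch_events(rec)
  labs <- c(sim$tree$tip.label, sim$tree$node.label)
  root_lab <- sim$tree$node.label[1]
  for (leaf in sim$tree$tip.label[1:4]) {
    path <- labs[catoolkit:::root_to_leaf_path(sim$tree, leaf)]
    for (a in colnames(rec$states)[1:10]) {
      st <- rec$states[path, a]
      flips <- sum(abs(diff(st)))
      on_path <- sum(ev$architecture == a & !is.na(ev$parent) &
                       ev$parent %in% path & ev$child %in% path)
      expect_identical(as.integer(flips), as.integer(on_path))
    }
  }
})

test_that("lineage trajectories walk the root-to-leaf path with repertoires", {
  tr4 <- read_species_tree("((A,B),(C,D));")
  rec <- dollo_reconstruct(tr4, list("47473" = c("A", "C")))
  ann <- tibble::tibble(architecture = "47473",
                        components = list("decoding-calmodulin"),
                        n_components = 1L)
  traj <- lineage_trajectory(rec, "A", ann)
  expect_identical(nrow(traj), 3L)           # root, N2, A
  expect_identical(traj$depth, 0:2)
  expect_identical(traj$node[1], "N1")
  expect_identical(traj$node[3], "A")
  # trajectory states match reconstructed states on the path
  expect_identical(traj$n_present, as.integer(rec$states[traj$node, "47473"]))
  expect_error(lineage_trajectory(rec, "Z", ann), "Unknown leaf")
})

test_that("the root entry reports the repertoire of root-present architectures", {
  sim <- simulate_toolkit(sim_config(n_leaves = 8, n_architectures = 120,
                                     seed = 29, gain_placement = "root_biased",
                                     loss_prob_per_branch = 0))
  ann <- build_annotation_map(sim$protein_components, sim$genomes,
                              sim$catalog, sim$registry)
  rec <- dollo_reconstruct(sim$tree, presence_from_genomes(sim$genomes))
  traj <- lineage_trajectory(rec, sim$tree$tip.label[1], ann)
  root_archs <- colnames(rec$states)[rec$states[ape::Ntip(sim$tree) + 1L, ]]
  ann_root <- ann[ann$architecture %in% root_archs, ]
  expect_identical(traj$n_annotated[1], nrow(ann_root))
  expect_identical(traj$n_multipurpose[1], sum(ann_root$n_components >= 2))
  singles <- ann_root[ann_root$n_components == 1L, ]
  expect_setequal(traj$single_purpose[[1]]$component_id,
                  unique(unlist(singles$components)))
  # with root-biased gains and no losses, the root repertoire spans all four
  # functional categories
  root_comps <- unique(unlist(ann_root$components))
  cats <- unique(sim$catalog$category[sim$catalog$component_id %in% root_comps])
  expect_setequal(intersect(cats, c("influx", "efflux", "decoding", "relay")),
                  c("influx", "efflux", "decoding", "relay"))
})

test_that("treemap tables give percentages that are consistent and normalized", {
  tr4 <- read_species_tree("((A,B),(C,D));")
  # constructed node: 2 multipurpose + 2 single-purpose at the root
  ann <- tibble::tibble(
    architecture = c("1001", "1002", "1003", "1004"),
    components = list(c("influx-channel", "efflux-atpase"),
                      c("decoding-CDPK", "relay-calmodulin-kinase"),
                      "influx-channel", "decoding-calmodulin"),
    n_components = c(2L, 2L, 1L, 1L)
  )
  rec <- dollo_reconstruct(tr4, list("1001" = LETTERS[1:4],
                                     "1002" = LETTERS[1:4],
                                     "1003" = LETTERS[1:4],
                                     "1004" = LETTERS[1:4],
                                     "9999" = "A"))
  tm <- treemap_tables(rec, ann)
  root <- tm$multipurpose[tm$multipurpose$node == "N1", ]
  expect_equal(root$pct_multipurpose, 50.0, tolerance = 1e-12)
  expect_false(root$empty)
  # per-node single-purpose percentages sum to 100
  sums <- tapply(tm$single_purpose$pct, tm$single_purpose$node, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  # node with no annotated architecture is flagged empty
  rec2 <- dollo_reconstruct(tr4, list("9999" = "A"))
  tm2 <- treemap_tables(rec2, ann)
  expect_true(all(tm2$multipurpose$empty))
  expect_true(all(is.na(tm2$multipurpose$pct_multipurpose)))
})

test_that("tidy, glance and autoplot summarize a reconstruction", {
  tr4 <- read_species_tree("((A,B),(C,D));")
  rec <- dollo_reconstruct(tr4, list(x = c("A", "C"), y = LETTERS[1:4]))
  td <- tidy(rec)
  expect_identical(nrow(td), 14L)  # 7 nodes x 2 architectures
  expect_identical(sum(td$present[td$architecture == "y"]), 7L)
  gl <- glance(rec)
  expect_identical(gl$n_gains, 2L)
  expect_identical(gl$n_losses, 2L)
  expect_identical(gl$n_root_architectures, 2L)
  expect_s3_class(autoplot(rec), "ggplot")
})
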