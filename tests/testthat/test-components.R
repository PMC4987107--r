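# Small constructed dataset around the worked multipurpose example: a
# myosin light chain kinase architecture labeled with both a relay and a
# decoding component.
mlck_dataset <- function() {
  genomes <- tibble::tibble(
    genome_id = c("pyy", "hs", "hs"),
    protein_id = c("Q7RTG4", "O96013", "P11111"),
    architecture = c("47473,_gap_,50729,56112,_gap_", "_gap_,56112",
                     "89837,89837,56112")
  )
  pct <- tibble::tibble(
    protein_id = c("Q7RTG4", "Q7RTG4", "O96013"),
    genome_id = c("pyy", "pyy", "hs"),
    component_id = c("relay-muscle-contraction", "decoding-CDPK",
                     "relay-muscle-contraction")
  )
  list(genomes = genomes, pct = pct)
}

test_that("component labels are inferred onto architectures, union over proteins", {
  d <- mlck_dataset()
  ann <- build_annotation_map(d$pct, d$genomes, example_catalog,
                              builtin_registry)
  expect_identical(nrow(ann), 2L)
  m <- ann[ann$architecture == "47473,_gap_,50729,56112,_gap_", ]
  expect_identical(m$n_components, 2L)
  expect_identical(m$components[[1]],
                   sort(c("decoding-CDPK", "relay-muscle-contraction")))
})

test_that("calcium-binding component labels are dropped from non-registry architectures", {
  d <- mlck_dataset()
  # decoding-CDPK binds calcium; _gap_,56112 has no registry domain
  bad <- tibble::tibble(protein_id = "O96013", genome_id = "hs",
                        component_id = "decoding-CDPK")
  expect_warning(
    expect_error(
      build_annotation_map(bad, d$genomes, example_catalog, builtin_registry),
      class = "catoolkit_annotation_error"
    ),
    "dropped"
  )
  # the same protein under a non-binding relay component is kept
  ok <- tibble::tibble(protein_id = "O96013", genome_id = "hs",
                       component_id = "relay-muscle-contraction")
  ann <- build_annotation_map(ok, d$genomes, example_catalog, builtin_registry)
  expect_identical(ann$architecture, "_gap_,56112")
  # every surviving calcium-binding label sits on a registry architecture
  d2 <- mlck_dataset()
  ann2 <- build_annotation_map(d2$pct, d2$genomes, example_catalog,
                               builtin_registry)
  binds <- example_catalog$component_id[example_catalog$binds_calcium]
  has_binding <- vapply(ann2$components, function(v) any(v %in% binds),
                        logical(1))
  expect_true(all(arch_is_ca(ann2$architecture[has_binding],
                             builtin_registry)))
})

test_that("annotations deduplicate across genomes and reject unknowns", {
  genomes <- tibble::tibble(
    genome_id = c("g1", "g2"), protein_id = c("p1", "p2"),
    architecture = "_gap_,56112"
  )
  pct <- tibble::tibble(protein_id = c("p1", "p2"), genome_id = c("g1", "g2"),
                        component_id = "relay-muscle-contraction")
  ann <- build_annotation_map(pct, genomes, example_catalog, builtin_registry)
  expect_identical(nrow(ann), 1L)

  expect_error(
    build_annotation_map(
      tibble::tibble(protein_id = "p1", genome_id = "g1",
                     component_id = "no-such-component"),
      genomes, example_catalog, builtin_registry),
    class = "catoolkit_catalog_error")

  expect_warning(
    build_annotation_map(
      dplyr::bind_rows(pct, tibble::tibble(protein_id = "ghost",
                                           genome_id = "g1",
                                           component_id = "decoding-CDPK")),
      genomes, example_catalog, builtin_registry),
    "absent")
})

test_that("purpose classification splits at the component-count threshold", {
  d <- mlck_dataset()
  ann <- classify_purpose(build_annotation_map(d$pct, d$genomes,
                                               example_catalog,
                                               builtin_registry))
  expect_identical(
    ann$purpose[ann$architecture == "47473,_gap_,50729,56112,_gap_"], "multi")
  expect_identical(ann$purpose[ann$architecture == "_gap_,56112"], "single")
  expect_identical(count_multipurpose(ann, 2), 1L)
  expect_identical(count_multipurpose(ann, 3), 0L)
})

test_that("multipurpose counting matches exhaustive counting on synthetic maps", {
  sim <- simulate_toolkit(sim_config(n_leaves = 8, n_architectures = 80,
                                     seed = 37))
  ann <- build_annotation_map(sim$protein_components, sim$genomes,
                              sim$catalog, sim$registry)
  for (k in 2:4) {
    brute <- sum(vapply(ann$components, function(v) length(v) >= k,
                        logical(1)))
    expect_identical(count_multipurpose(ann, k), brute)
  }
  # the planted component map is recovered exactly (labels are constructed
  # consistently with the registry restriction)
  planted <- sim$truth$component_map[
    match(ann$architecture, sim$truth$component_map$architecture), ]
  expect_identical(ann$components, lapply(planted$components, sort))
})

test_that("core toolkit is coverage counting, antitone in the threshold", {
  one <- tibble::tibble(genome_id = "g1", protein_id = "p1",
                        architecture = "_gap_,56112")
  ann1 <- tibble::tibble(architecture = "_gap_,56112",
                         components = list("relay-muscle-contraction"),
                         n_components = 1L)
  expect_identical(core_toolkit(ann1, one, 1.0), "relay-muscle-contraction")

  # component present in 9 of 10 genomes
  genomes <- dplyr::bind_rows(lapply(1:10, function(i) tibble::tibble(
    genome_id = sprintf("g%02d", i), protein_id = "p",
    architecture = if (i < 10) "_gap_,56112" else "11111"
  )))
  expect_identical(core_toolkit(ann1, genomes, 1.0), character(0))
  expect_identical(core_toolkit(ann1, genomes, 0.9), "relay-muscle-contraction")

  withr::with_seed(59, {
    for (i in seq_len(30)) {
      d <- random_annotation_dataset()
      t1 <- runif(1, 0.3, 0.9); t2 <- runif(1, t1, 1)
      c1 <- core_toolkit(d$annotations, d$genomes, t1)
      c2 <- core_toolkit(d$annotations, d$genomes, t2)
      expect_true(all(c2 %in% c1))
      expect_identical(c1, oracle_core(d$annotations, d$genomes, t1))
    }
  })
})

test_that("an all-covering catalog gives the same core at 100% and 90% coverage", {
  genomes <- dplyr::bind_rows(lapply(1:6, function(i) tibble::tibble(
    genome_id = sprintf("g%02d", i), protein_id = c("a", "b"),
    architecture = c("47473", "_gap_,56112")
  )))
  ann <- tibble::tibble(
    architecture = c("47473", "_gap_,56112"),
    components = list("decoding-calmodulin", "relay-muscle-contraction"),
    n_components = 1L
  )
  expect_identical(core_toolkit(ann, genomes, 1.0),
                   core_toolkit(ann, genomes, 0.9))
  sweep <- core_toolkit_sweep(ann, genomes, c(1.0, 0.9))
  expect_identical(sweep$components[[1]], sweep$components[[2]])
})

test_that("component breakdown reports per-component single-purpose counts", {
  ann <- tibble::tibble(
    architecture = c("_gap_,56112", "47473,_gap_,50729,56112,_gap_"),
    components = list("relay-muscle-contraction",
                      c("decoding-CDPK", "relay-muscle-contraction")),
    n_components = c(1L, 2L)
  )
  g <- tibble::tibble(genome_id = "g", protein_id = "p",
                      architecture = "_gap_,56112")
  br <- component_breakdown(g, ann, example_catalog)
  expect_identical(br$single_purpose$n[
    br$single_purpose$component_id == "relay-muscle-contraction"], 1L)
  expect_true(all(br$single_purpose$n[
    br$single_purpose$component_id != "relay-muscle-contraction"] == 0L))
  expect_identical(nrow(br$multipurpose), 0L)

  br0 <- component_breakdown(g[0, ], ann, example_catalog)
  expect_true(all(br0$single_purpose$n == 0L))
})

test_that("breakdown totals equal planted composition on simulated genomes", {
  sim <- simulate_toolkit(sim_config(n_leaves = 6, n_architectures = 50,
                                     seed = 71))
  ann <- build_annotation_map(sim$protein_components, sim$genomes,
                              sim$catalog, sim$registry)
  for (g in unique(sim$genomes$genome_id)[1:3]) {
    gt <- sim$genomes[sim$genomes$genome_id == g, ]
    br <- component_breakdown(gt, ann)
    # sum of single-purpose counts = number of distinct single-purpose
    # annotated architectures present (each has exactly one component)
    singles <- ann$architecture[ann$n_components == 1L]
    expect_identical(sum(br$single_purpose$n),
                     length(intersect(unique(gt$architecture), singles)))
    # planted composition: multipurpose architectures present in the genome
    planted_multi <- sim$truth$component_map$architecture[
      sim$truth$component_map$n_components >= 2L]
    expect_setequal(br$multipurpose$architecture,
                    intersect(unique(gt$architecture), planted_multi))
  }
})
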