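# Shared fixtures, built in code.

builtin_registry <- ca_builtin_registry()
example_catalog <- ca_example_catalog()

# Five-protein toy genome: 4 distinct architectures, 3 of them
# calcium-binding (47473 = EF-hand, 49562 = C2 domain; 56112 is not in the
# registry).
toy_genome <- function(genome_id = "toy") {
  tibble::tibble(
    genome_id = genome_id,
    protein_id = c("A", "B", "C", "D", "E"),
    architecture = c("47473", "47473,_gap_", "56112", "47473", "49562,56112")
  )
}

# Random valid architecture string (>= 1 domain token, optional gaps).
random_arch <- function() {
  ndom <- sample(1:5, 1)
  ids <- sample(1:99999, ndom, replace = TRUE)
  toks <- character(0)
  if (runif(1) < 0.2) toks <- "_gap_"
  for (d in seq_len(ndom)) {
    toks <- c(toks, as.character(ids[d]))
    if (runif(1) < 0.25) toks <- c(toks, "_gap_")
  }
  paste(toks, collapse = ",")
}

# Every rooted bifurcating tree shape with n <= 6 leaves, as newick strings.
tree_shapes_upto6 <- function(max_leaves = 6) {
  shapes <- list(
    "(A,B);",
    "((A,B),C);",
    "((A,B),(C,D));",
    "(((A,B),C),D);",
    "((((A,B),C),D),E);",
    "(((A,B),(C,D)),E);",
    "(((A,B),C),(D,E));",
    "(((((A,B),C),D),E),F);",
    "((((A,B),(C,D)),E),F);",
    "((((A,B),C),(D,E)),F);",
    "((((A,B),C),D),(E,F));",
    "(((A,B),(C,D)),(E,F));",
    "(((A,B),C),((D,E),F));"
  )
  nl <- vapply(shapes, function(s) length(ape::read.tree(text = s)$tip.label),
               integer(1))
  shapes[nl <= max_leaves]
}
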