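bitnames <- function(v) sort(names(which(v$bits)))

test_that("worked examples collapse as expected", {
  bz <- build_reduced_graph(typed_mol("c1ccccc1"))
  expect_length(bz$vertices, 1)
  expect_equal(bz$vertices[[1]]$ac, 6L)
  expect_identical(bitnames(bz$vertices[[1]]), c("R", "ring"))

  py <- build_reduced_graph(typed_mol("c1ccncc1"))
  expect_identical(bitnames(py$vertices[[1]]), c("A", "R", "ring"))
  expect_equal(py$vertices[[1]]$ac, 6L)

  naph <- build_reduced_graph(typed_mol("c1ccc2ccccc2c1"))
  expect_length(naph$vertices, 2)
  expect_equal(naph$edges$order, 2L)

  biph <- build_reduced_graph(typed_mol("c1ccc(-c2ccccc2)cc1"))
  expect_length(biph$vertices, 2)
  expect_equal(biph$edges$order, 1L)

  # 1H-phenalene: central atom sits in three SSSR rings -> amalgamated vertex
  phen <- build_reduced_graph(typed_mol("C1c2cccc3cccc(c23)C=C1"))
  expect_length(phen$vertices, 1)
  expect_true(phen$vertices[[1]]$bits[["amalg"]])
  expect_true(phen$vertices[[1]]$bits[["ring"]])
  expect_equal(phen$vertices[[1]]$ac, 13L)
})

test_that("vertex similarity follows the penalty-times-Tanimoto form", {
  expect_equal(tanimoto_bits(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE)), 1)
  expect_equal(tanimoto_bits(c(TRUE, FALSE, FALSE), c(FALSE, TRUE, FALSE)), 0)
  expect_equal(tanimoto_bits(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, TRUE)), 1 / 3)

  expect_equal(sd_factor(6, 6), 1)
  expect_equal(sd_factor(10, 4), 0)
  d1 <- sd_factor(6, 5); d3 <- sd_factor(6, 3)
  expect_gt(d1, 0); expect_lt(d1, 1); expect_gte(d1, d3)

  bz <- build_reduced_graph(typed_mol("c1ccccc1"))$vertices[[1]]
  py <- build_reduced_graph(typed_mol("c1ccncc1"))$vertices[[1]]
  expect_equal(vertex_similarity(bz, bz), 1)
  expect_equal(vertex_similarity(bz, py), 2 / 3)
  big <- bz; big$ac <- 12L
  expect_equal(vertex_similarity(big, py), 0)   # count difference 6 kills it
})

test_that("reduced graphs are acyclic partitions of the molecule", {
  smis <- c("c1ccccc1", "c1ccc2ccccc2c1", "CCc1ccccc1C(=O)O", "NCCO",
            "CC(=O)CCC(=O)c1ccccc1", "C1CCC2(CC1)CCCCC2", "Cc1nc2c([nH]1)cccc2",
            "O=C(NCCOC(=O)c1ccccc1)c1ccccc1", "C1c2cccc3cccc(c23)C=C1")
  for (smi in smis) {
    m <- typed_mol(smi)
    rg <- build_reduced_graph(m)
    # atom conservation: the vertices partition the heavy atoms
    members <- unlist(lapply(rg$vertices, function(v) v$member_atoms))
    expect_identical(sort(members), seq_len(rxndesign:::n_atoms(m)), info = smi)
    expect_equal(sum(vapply(rg$vertices, function(v) v$ac, 1L)),
                 rxndesign:::n_atoms(m), info = smi)
    # acyclicity: |E| = |V| - components
    g <- igraph::graph_from_edgelist(as.matrix(rg$edges[, c("v1", "v2")]),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0, length(rg$vertices) - igraph::vcount(g)))
    ncomp <- igraph::components(g)$no
    expect_equal(nrow(rg$edges), length(rg$vertices) - ncomp, info = smi)
    # amalgamated bit implies ring bit; order-2 edges connect two ring vertices
    for (v in rg$vertices) if (v$bits[["amalg"]]) expect_true(v$bits[["ring"]])
    for (k in seq_len(nrow(rg$edges))) {
      if (rg$edges$order[k] == 2L) {
        expect_true(rg$vertices[[rg$edges$v1[k]]]$bits[["ring"]])
        expect_true(rg$vertices[[rg$edges$v2[k]]]$bits[["ring"]])
      }
    }
  }
})

test_that("vertex similarity is symmetric and bounded over many pairs", {
  mols <- lapply(c("c1ccccc1", "c1ccncc1", "CCO", "CC(=O)[O-]", "NCCO",
                   "c1ccc2ccccc2c1"), typed_mol)
  verts <- unlist(lapply(mols, function(m) build_reduced_graph(m)$vertices),
                  recursive = FALSE)
  for (i in seq_along(verts)) for (j in seq_along(verts)) {
    s <- vertex_similarity(verts[[i]], verts[[j]])
    expect_gte(s, 0); expect_lte(s, 1)
    expect_equal(s, vertex_similarity(verts[[j]], verts[[i]]))
  }
})

test_that("the degree-6 limit flags dense reduced graphs instead of erroring", {
  # a central carbon bearing six separate rings exceeds the vertex degree cap
  smi <- paste0("C(", paste(rep("C1CCCC1", 2), collapse = ""), ")(C1CCCC1)C1CCCC1")
  m <- typed_mol("C(C1CCC1)(C1CCC1)(C1CCC1)C1CCC1")
  rg <- build_reduced_graph(m)
  expect_true(rg$valid)   # degree 4 is fine
  expect_equal(rg$max_degree, 4L)
})

test_that("the debug writer emits GraphML and a vertex table", {
  rg <- build_reduced_graph(typed_mol("CCc1ccccc1C(=O)O"))
  gml <- tempfile(fileext = ".graphml"); tab <- tempfile(fileext = ".tsv")
  out <- write_reduced_graph(rg, gml, tab)
  expect_true(file.exists(gml))
  expect_match(readLines(gml, n = 2)[2], "graphml", fixed = TRUE)
  expect_equal(nrow(utils::read.delim(tab)), length(rg$vertices))
  expect_equal(nrow(out), length(rg$vertices))
})
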