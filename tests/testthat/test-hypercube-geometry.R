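test_that("induced graphs have hypercube edge counts and regularity", {
  g64 <- build_graph(all_codons())
  expect_equal(igraph::gorder(g64), 64)
  expect_equal(igraph::gsize(g64), 192)
  expect_true(all(igraph::degree(g64) == 6))
  expect_true(igraph::bipartite_mapping(g64)$res)
  for (pat in c("RNY", "YNY", "RNR", "YNR")) {
    g <- build_graph(pattern_set(pat))
    expect_equal(igraph::gsize(g), 32)             # Q4
    expect_true(all(igraph::degree(g) == 4))
    expect_true(igraph::is_connected(g))
  }
  for (cube in ry_partition()) {
    g <- build_graph(cube)
    expect_equal(igraph::gsize(g), 12)             # 3-cube
    expect_true(all(igraph::degree(g) == 3))
  }
})

test_that("nucleotide adjacency gives the denser one-substitution graph", {
  g <- build_graph(all_codons(), adjacency = "nucleotide")
  expect_equal(igraph::gsize(g), 64 * 9 / 2)  # 3 positions x 3 changes
})

test_that("subspace reports agree with the brute-force GF(2) oracle", {
  sets <- c(ry_partition(),
            lapply(c("RNY", "YNY", "RNR", "YNR", "NNY", "NNR"), pattern_set))
  for (s in sets) {
    rep <- subspace_report(s)
    idx <- codon_index(s)
    expect_identical(rep$is_affine, oracle_is_affine(idx))
    expect_identical(rep$is_coordinate_aligned, oracle_is_aligned(idx))
    expect_identical(rep$dimension, as.integer(log2(length(s))))
    expect_equal(2^rep$dimension, length(s))
  }
})

test_that("named pattern subspaces have the stated structure", {
  rny <- subspace_report(pattern_set("RNY"))
  expect_true(rny$is_affine && rny$is_coordinate_aligned)
  expect_identical(rny$dimension, 4L)
  nny <- subspace_report(pattern_set("NNY"))
  expect_identical(nny$dimension, 5L)
  expect_true(nny$is_coordinate_aligned)
  # under the pyrimidine-identity scheme NNY is linear (contains CCC = 0)
  nny_c <- subspace_report(pattern_set("NNY"), "CUAG")
  expect_true(nny_c$contains_zero)
  # the hyperprism is affine but not a hyperface
  prism <- subspace_report(c(pattern_set("RRR"), pattern_set("YYY")))
  expect_true(prism$is_affine)
  expect_identical(prism$dimension, 4L)
  expect_false(prism$is_coordinate_aligned)
  # a non-subspace set is reported as such
  expect_false(subspace_report(c("AAA", "AAC", "AAG"))$is_affine)
})

test_that("the hyperprism has two 3-cubes at nucleotide distance 3", {
  rep <- component_distance_report(c(pattern_set("RRR"), pattern_set("YYY")))
  expect_identical(rep$n_components, 2L)
  expect_identical(sort(rep$component_sizes), c(8L, 8L))
  expect_identical(rep$min_nt_distance, 3L)
  expect_identical(rep$min_bit_distance, 3L)
})

test_that("amino-acid incidence classifies edges and singleton vertices", {
  ryr <- amino_acid_incidence(pattern_set("RYR"))
  expect_setequal(ryr$label[ryr$role == "edge"], c("Thr", "Ala", "Val"))
  expect_setequal(ryr$label[ryr$role == "singleton"], c("Met", "Ile"))
  yrr <- amino_acid_incidence(pattern_set("YRR"))
  stop_row <- yrr[yrr$label == "STOP", ]
  expect_identical(stop_row$n_edges, 2L)
  expect_identical(stop_row$n_components, 1L)
  expect_setequal(yrr$label[yrr$role == "singleton"], "Trp")
  # in RYY every amino acid occupies exactly one full edge
  ryy <- amino_acid_incidence(pattern_set("RYY"))
  expect_true(all(ryy$role == "edge"))
  expect_error(amino_acid_incidence(pattern_set("RNY")), "8 codons")
  expect_error(amino_acid_incidence(all_codons()[1:8]), "pattern")
})

test_that("layouts are deterministic, injective, and translate with the set", {
  g_rny <- build_graph(pattern_set("RNY"))
  l1 <- layout_coordinates(g_rny)
  l2 <- layout_coordinates(g_rny)
  expect_identical(l1, l2)
  expect_identical(anyDuplicated(l1[, c("x", "y")]), 0L)
  # RNY and YNY are parallel 4-faces: pairing each RNY codon with its
  # first-position transversion image, the layouts differ by one
  # constant translation
  l_yny <- layout_coordinates(build_graph(pattern_set("YNY")))
  partner <- transversion(l1$codon, 1, "ry")
  j <- match(partner, l_yny$codon)
  expect_length(unique(l_yny$x[j] - l1$x), 1)
  expect_length(unique(l_yny$y[j] - l1$y), 1)
  # per-figure-4D needs a 4-face and gives 16 distinct grid points
  l4 <- layout_coordinates(g_rny, "per-figure-4D")
  expect_identical(anyDuplicated(l4[, c("x", "y")]), 0L)
  expect_error(layout_coordinates(build_graph(all_codons()), "per-figure-4D"),
               "4 free")
})

test_that("graph export writes GraphML and edge lists", {
  g <- build_graph(pattern_set("RRR"), table = standard_genetic_code())
  gml <- tempfile(fileext = ".graphml")
  export_graph(g, gml)
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gsize(g2), 12)
  expect_setequal(igraph::V(g2)$codon, pattern_set("RRR"))
  tsv <- tempfile(fileext = ".tsv")
  export_graph(g, tsv, "edgelist")
  el <- read.delim(tsv, header = FALSE)
  expect_equal(nrow(el), 12)
})
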