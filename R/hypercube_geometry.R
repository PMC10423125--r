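# Induced subgraphs of the 6-cube on codon sets, GF(2) affine-subspace
# tests, per-amino-acid incidence structure inside the 3-cubes, and
# deterministic 2D layouts for figure export.

#' Induced hypercube graph on a codon set
#'
#' Vertices are codons; edges join codons at the chosen unit distance.
#' The default adjacency is bit Hamming distance 1 (the 6-cube metric);
#' `adjacency = "nucleotide"` instead joins codons differing in exactly
#' one nucleotide (the "square with diagonals" arrangement, where every
#' single-nucleotide change is one step).
#'
#' @param codons Codon character vector (subset of the 64).
#' @param scheme An [encoding_scheme()] or its name.
#' @param adjacency `"bit"` or `"nucleotide"`.
#' @param table Optional `genetic_code`; when given, vertex attributes
#'   `amino_acid`, `aars_class` and `color` are attached.
#' @param classification An `aars_classification` for the vertex colors.
#' @return An [igraph::graph] with vertex attribute `codon` (vertex names
#'   are codons, in canonical order).
#' @examples
#' g <- build_graph(pattern_set("RRR"))
#' igraph::gsize(g)  # 12 edges of the cube
#' @export
build_graph <- function(codons, scheme = encoding_scheme(),
                        adjacency = c("bit", "nucleotide"),
                        table = NULL,
                        classification = aars_classification("class_II")) {
  adjacency <- match.arg(adjacency)
  codons <- sort(unique(validate_codons(codons)))
  n <- length(codons)
  if (adjacency == "bit") {
    bits <- codon_bits(codons, scheme)
    d <- as.matrix(stats::dist(bits, method = "manhattan"))
  } else {
    ch <- codon_chars(codons)
    d <- matrix(0L, n, n)
    for (p in 1:3) d <- d + outer(ch[, p], ch[, p], "!=")
  }
  adj <- d == 1
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  g <- igraph::set_vertex_attr(g, "name", value = codons)
  g <- igraph::set_vertex_attr(g, "codon", value = codons)
  if (!is.null(table)) {
    labels <- unclass(table)[codons]
    col <- color_codons(codons, table, classification)
    g <- igraph::set_vertex_attr(g, "amino_acid", value = unname(labels))
    g <- igraph::set_vertex_attr(g, "aars_class", value = unname(unclass(col)))
  }
  g
}

#' GF(2) affine-subspace report for a codon set
#'
#' Tests whether the set of 6-bit words is an affine subspace (a translate
#' of a linear subspace closed under GF(2) addition), and whether it is
#' coordinate-aligned: a translate obtained by fixing some of the six
#' coordinates, i.e. a hyperface of the 6-cube.
#'
#' @param codons Nonempty codon character vector.
#' @param scheme An [encoding_scheme()] or its name.
#' @return Object of class `subspace_report`: list with `is_affine`,
#'   `dimension` (`NA` if not affine), `is_coordinate_aligned`,
#'   `fixed_coords` (indices of constant bit coordinates), `fixed_values`,
#'   and `contains_zero` (whether the scheme's zero codon is in the set,
#'   i.e. whether the subspace is linear).
#' @examples
#' subspace_report(pattern_set("RNY"))  # affine, dimension 4, aligned
#' @export
subspace_report <- function(codons, scheme = encoding_scheme()) {
  codons <- unique(validate_codons(codons))
  if (length(codons) == 0) stop("codon set must be nonempty")
  idx <- codon_index(codons, scheme)
  # translate so the set contains 0, then test closure under XOR
  t0 <- idx[1]
  shifted <- sort(bitwXor(idx, t0))
  closed <- all(outer(shifted, shifted, bitwXor) %in% shifted)
  k <- log2(length(idx))
  is_affine <- closed && k == round(k)
  bits <- codon_bits(codons, scheme)
  fixed <- which(apply(bits, 2, function(col) length(unique(col)) == 1))
  aligned <- is_affine && length(fixed) == 6 - round(k)
  structure(
    list(is_affine = is_affine,
         dimension = if (is_affine) as.integer(round(k)) else NA_integer_,
         is_coordinate_aligned = aligned,
         fixed_coords = fixed,
         fixed_values = if (length(fixed)) bits[1, fixed] else integer(),
         contains_zero = 0L %in% idx,
         scheme = as_scheme(scheme)$name),
    class = "subspace_report")
}

#' @export
print.subspace_report <- function(x, ...) {
  cat("Subspace report [scheme ", x$scheme, "]: ",
      if (x$is_affine) paste0("affine, dimension ", x$dimension)
      else "not affine",
      if (isTRUE(x$is_coordinate_aligned)) ", coordinate-aligned" else "",
      if (x$contains_zero) ", contains zero" else "", "\n", sep = "")
  if (length(x$fixed_coords))
    cat("  fixed coordinates: ",
        paste0(x$fixed_coords, "=", x$fixed_values, collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Amino-acid incidence structure of an 8-codon pattern cube
#'
#' For one of the eight pure R/Y cubes, classifies every label occurring
#' in the cube (amino acids, and STOP if present) by the structure of the
#' subgraph its codons induce: a single vertex, a full edge, or a larger
#' connected structure.
#'
#' @param cube An 8-codon pure R/Y pattern set (see [ry_partition()]).
#' @param table A `genetic_code` table.
#' @param scheme An [encoding_scheme()] or its name.
#' @return Data frame with one row per label: `label`, `n_vertices`,
#'   `n_edges`, `n_components`, and `role` (`"singleton"`, `"edge"` or
#'   `"multi"`).
#' @examples
#' inc <- amino_acid_incidence(pattern_set("RYR"))
#' inc[inc$role == "singleton", "label"]  # Ile and Met
#' @export
amino_acid_incidence <- function(cube, table = standard_genetic_code(),
                                 scheme = encoding_scheme()) {
  cube <- sort(unique(validate_codons(cube)))
  if (length(cube) != 8)
    stop("cube must contain exactly 8 codons")
  ch <- codon_chars(cube)
  ry <- matrix(ifelse(ch %in% PURINES, "R", "Y"), ncol = 3)
  if (nrow(unique(ry)) != 1)
    stop("cube is not a pure R/Y pattern set")
  g <- build_graph(cube, scheme)
  labels <- unclass(table)[cube]
  out <- lapply(sort(unique(labels)), function(lab) {
    sub <- igraph::induced_subgraph(g, igraph::V(g)[labels == lab])
    nv <- as.integer(igraph::gorder(sub)); ne <- as.integer(igraph::gsize(sub))
    data.frame(label = lab, n_vertices = nv, n_edges = ne,
               n_components = as.integer(igraph::count_components(sub)),
               role = if (nv == 1) "singleton"
                      else if (nv == 2 && ne == 1) "edge" else "multi",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Minimum distances between components of an induced graph
#'
#' Used for the "hyperprism" complement of the extended code type 1
#' (RRR U YYY): two 3-cubes whose closest codons differ at all three
#' nucleotide positions.
#'
#' @param codons Codon character vector.
#' @param scheme An [encoding_scheme()] or its name.
#' @return List with `n_components`, `component_sizes`,
#'   `min_nt_distance` and `min_bit_distance` between distinct
#'   components (`NA` when the graph is connected).
#' @export
component_distance_report <- function(codons, scheme = encoding_scheme()) {
  codons <- sort(unique(validate_codons(codons)))
  g <- build_graph(codons, scheme)
  comp <- igraph::components(g)
  if (comp$no < 2)
    return(list(n_components = as.integer(comp$no),
                component_sizes = as.integer(unname(comp$csize)),
                min_nt_distance = NA_integer_,
                min_bit_distance = NA_integer_))
  member <- comp$membership[codons]
  cross <- outer(member, member, "!=")
  nt <- outer(seq_along(codons), seq_along(codons),
              function(i, j) hamming_nt(codons[i], codons[j]))
  bt <- outer(seq_along(codons), seq_along(codons),
              function(i, j) hamming_bit(codons[i], codons[j], scheme))
  list(n_components = as.integer(comp$no),
       component_sizes = as.integer(unname(comp$csize)),
       min_nt_distance = as.integer(min(nt[cross])),
       min_bit_distance = as.integer(min(bt[cross])))
}

#' Deterministic 2D layout of a codon graph
#'
#' `"parallel-projection-6to2"` projects the 6-bit word linearly:
#' `x = 4 b1 + 2 b3 + 1 b5`, `y = 4 b2 + 2 b4 + 1 b6`, which is injective
#' on all 64 codons and maps translates of a codon set to translated
#' layouts. `"per-figure-4D"` lays out a coordinate 4-face by its four
#' free coordinates on a 4 x 4 grid.
#'
#' @param graph A graph from [build_graph()].
#' @param projection Layout rule.
#' @param scheme The [encoding_scheme()] the graph was built under.
#' @return Data frame `codon`, `x`, `y` in canonical codon order.
#' @export
layout_coordinates <- function(graph,
                               projection = c("parallel-projection-6to2",
                                              "per-figure-4D"),
                               scheme = encoding_scheme()) {
  projection <- match.arg(projection)
  codons <- igraph::V(graph)$codon
  bits <- codon_bits(codons, scheme)
  if (projection == "parallel-projection-6to2") {
    x <- bits %*% c(4, 0, 2, 0, 1, 0)
    y <- bits %*% c(0, 4, 0, 2, 0, 1)
  } else {
    free <- which(apply(bits, 2, function(col) length(unique(col)) > 1))
    if (length(free) != 4)
      stop("per-figure-4D layout requires a coordinate 4-face ",
           "(4 free coordinates), found ", length(free))
    x <- bits[, free[1]] * 2 + bits[, free[3]]
    y <- bits[, free[2]] * 2 + bits[, free[4]]
  }
  data.frame(codon = codons, x = as.numeric(x), y = as.numeric(y),
             stringsAsFactors = FALSE)
}

#' Export a codon graph with layout
#'
#' @param graph A graph from [build_graph()].
#' @param path Output file path.
#' @param format `"graphml"` or `"edgelist"` (TSV of codon pairs).
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(graph)
    utils::write.table(el, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
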