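# Isometries of the n-bit Hamming space acting on the codon hypercube.
#
# An isometry is a pair (perm, t): x -> perm(x) XOR t, i.e. a coordinate
# permutation followed by coordinate flips. The full group on n bits is
# the hyperoctahedral group of order 2^n * n! (46,080 at n = 6); the
# codon-structured subgroup restricts to codon-position permutations
# combined with per-position 2-bit isometries (order 6 * 8^3 = 3,072).
# Groups are enumerated explicitly as an element table plus the action of
# every element on the 2^n vertex indices, so stabilizers, color-
# preserving subgroups and Class I/II swap cosets are exhaustive filters.

lex_permutations <- function(v) {
  if (length(v) == 1L) return(matrix(v, 1, 1))
  do.call(rbind, lapply(seq_along(v), function(i)
    cbind(v[i], lex_permutations(v[-i]), deparse.level = 0)))
}

bit_rows <- function(n) {
  t(vapply(0:(2^n - 1), function(i) as.integer(intToBits(i)[n:1]),
           integer(n)))
}

# action table: element e maps vertex x (0-based) to
# action[e, x + 1] - 1; y[j] = x[perm[j]] XOR flip[j]
action_table <- function(perms, flips, n) {
  w <- as.integer(2^((n - 1):0))
  B <- bit_rows(n)
  tvals <- drop(flips %*% w)
  m <- nrow(perms)
  act <- matrix(0L, m, 2^n)
  for (e in seq_len(m)) {
    base <- drop(B[, perms[e, ], drop = FALSE] %*% w)
    act[e, ] <- bitwXor(base, tvals[e]) + 1L
  }
  act
}

new_isometry_group <- function(perms, flips, n_bits, flavor,
                               parent_order = NULL) {
  structure(
    list(n_bits = n_bits, flavor = flavor,
         perms = perms, flips = flips,
         action = action_table(perms, flips, n_bits),
         order = nrow(perms),
         parent_order = parent_order),
    class = "isometry_group")
}

#' Enumerate an isometry group of the n-bit Hamming space
#'
#' @param n_bits Number of bit coordinates (6 for the codon space; small
#'   values are useful for exhaustive checks). Full enumeration is
#'   refused above 6 bits (the element count 2^n * n! grows too fast for
#'   an explicit table).
#' @param flavor `"full"` — the complete hyperoctahedral group, order
#'   `2^n * n!`; or `"codon_structured"` (n = 6 only) — codon-position
#'   permutations times per-position 2-bit isometries, order
#'   `3! * 8^3 = 3072`, a subgroup of the full group.
#' @return Object of class `isometry_group`: list with `perms` (m x n,
#'   row e gives the source coordinate for each target position), `flips`
#'   (m x n 0/1), `action` (m x 2^n table of 1-based vertex images),
#'   `order`, `n_bits`, `flavor`. Elements are in lexicographic
#'   (permutation, flip) order; the identity is element 1.
#' @examples
#' isometry_group(2)$order       # 8
#' @export
isometry_group <- function(n_bits = 6, flavor = c("full", "codon_structured")) {
  flavor <- match.arg(flavor)
  if (flavor == "full") {
    if (n_bits > 6)
      stop("full enumeration refused for n_bits > 6 (order 2^n * n! = ",
           format(2^n_bits * factorial(n_bits), big.mark = ","), ")")
    perms1 <- lex_permutations(seq_len(n_bits))
    flips1 <- bit_rows(n_bits)
    perms <- perms1[rep(seq_len(nrow(perms1)), each = nrow(flips1)), ,
                    drop = FALSE]
    flips <- flips1[rep(seq_len(nrow(flips1)), times = nrow(perms1)), ,
                    drop = FALSE]
    return(new_isometry_group(perms, flips, n_bits, flavor))
  }
  if (n_bits != 6)
    stop("codon_structured flavor is defined for n_bits = 6 only")
  sigma <- lex_permutations(1:3)
  b2_perms <- matrix(c(1L, 2L, 2L, 1L), 2, 2, byrow = TRUE)
  b2_flips <- bit_rows(2)
  # per-position B2 elements in lex (perm, flip) order
  e_perm <- b2_perms[rep(1:2, each = 4), , drop = FALSE]
  e_flip <- b2_flips[rep(1:4, times = 2), , drop = FALSE]
  combos <- expand.grid(e3 = 1:8, e2 = 1:8, e1 = 1:8, s = 1:6)
  combos <- combos[, c("s", "e1", "e2", "e3")]
  m <- nrow(combos)
  perms <- matrix(0L, m, 6)
  flips <- matrix(0L, m, 6)
  for (i in 1:3) {
    src <- sigma[combos$s, i]             # source position for target block i
    ei <- combos[[paste0("e", i)]]
    perms[, 2 * i - 1] <- 2L * (src - 1L) + e_perm[ei, 1]
    perms[, 2 * i]     <- 2L * (src - 1L) + e_perm[ei, 2]
    flips[, 2 * i - 1] <- e_flip[ei, 1]
    flips[, 2 * i]     <- e_flip[ei, 2]
  }
  new_isometry_group(perms, flips, 6, "codon_structured")
}

#' @export
print.isometry_group <- function(x, ...) {
  cat("Isometry group (", x$flavor, ") on ", x$n_bits, " bits: order ",
      format(x$order, big.mark = ","),
      if (!is.null(x$parent_order))
        paste0(" (subgroup of order-", format(x$parent_order, big.mark = ","),
               " universe)"),
      "\n", sep = "")
  invisible(x)
}

subset_group <- function(group, rows, flavor_note) {
  structure(
    list(n_bits = group$n_bits, flavor = paste0(group$flavor, ":", flavor_note),
         perms = group$perms[rows, , drop = FALSE],
         flips = group$flips[rows, , drop = FALSE],
         action = group$action[rows, , drop = FALSE],
         order = length(rows),
         elements = rows,
         parent_order = group$order),
    class = "isometry_group")
}

# rows of the element table whose action leaves a vertex labeling
# invariant: labels[g(x)] == labels[x] for every vertex x. Because every
# element permutes the whole vertex set, this is exactly "g maps every
# label class onto itself".
label_invariant_rows <- function(group, labels) {
  img <- matrix(labels[group$action], nrow = group$order)
  ref <- matrix(labels, nrow = group$order, ncol = length(labels),
                byrow = TRUE)
  which(rowSums(img != ref) == 0L)
}

codons_to_labels <- function(codons, scheme, values = NULL) {
  lab <- rep("OUTSIDE", 64)
  idx <- codon_index(validate_codons(codons), scheme) + 1L
  lab[idx] <- if (is.null(values)) "IN" else values
  lab
}

#' Apply one group element to codons
#'
#' @param group An `isometry_group` (on 6 bits).
#' @param i Element row index.
#' @param codons Codon character vector.
#' @param scheme An [encoding_scheme()] or its name.
#' @return The image codons, in input order.
#' @export
apply_isometry <- function(group, i, codons, scheme = encoding_scheme()) {
  stopifnot(group$n_bits == 6)
  idx <- codon_index(codons, scheme) + 1L
  decode_codon(group$action[i, idx] - 1L, scheme)
}

#' Stabilizer of a codon set in an isometry group
#'
#' All elements `g` with `g(S) = S`, by exhaustive filtering of the
#' element table.
#'
#' @param codons Codon character vector (for a 6-bit group), or 0-based
#'   vertex indices for groups on other bit counts.
#' @param group An `isometry_group`.
#' @param scheme An [encoding_scheme()] or its name (6-bit groups only).
#' @return An `isometry_group` holding the stabilizer subgroup.
#' @export
stabilizer_of_set <- function(codons, group, scheme = encoding_scheme()) {
  labels <- set_labels(codons, group, scheme)
  rows <- label_invariant_rows(group, labels)
  subset_group(group, rows, "set-stabilizer")
}

set_labels <- function(codons, group, scheme) {
  if (is.numeric(codons)) {
    lab <- rep("OUT", 2^group$n_bits)
    lab[codons + 1L] <- "IN"
    lab
  } else {
    stopifnot(group$n_bits == 6)
    codons_to_labels(codons, scheme)
  }
}

#' Color-preserving subgroup of a coloring
#'
#' All elements mapping the colored codon set onto itself and every color
#' class (including STOP and AMBIGUOUS) onto itself. Always a subgroup of
#' the set stabilizer.
#'
#' @param coloring An `aars_coloring` (named codon -> color vector), or
#'   any named character vector of colors.
#' @param group An `isometry_group` on 6 bits.
#' @param scheme An [encoding_scheme()] or its name.
#' @return An `isometry_group` holding the color-preserving subgroup.
#' @export
color_preserving_group <- function(coloring, group,
                                   scheme = encoding_scheme()) {
  stopifnot(group$n_bits == 6)
  labels <- codons_to_labels(names(coloring), scheme,
                             values = unclass(coloring))
  rows <- label_invariant_rows(group, labels)
  subset_group(group, rows, "color-preserving")
}

#' Class I / Class II swap isometries of a coloring
#'
#' All elements exchanging the Class I and Class II codon sets while
#' fixing every other color class (STOP, AMBIGUOUS) and the colored set
#' itself. A nonempty result is a coset of the color-preserving subgroup,
#' so its size is either 0 or that subgroup's order. Emptiness is a
#' valid, reported outcome; when the two class sets have different
#' cardinalities no isometry can swap them and the search is skipped.
#'
#' @inheritParams color_preserving_group
#' @return Object of class `isometry_coset`: list with `count`,
#'   `elements` (row indices into `group`), `perms`, `flips`, and
#'   `reason` (`NA` when nonempty, otherwise why the result is empty).
#' @export
class_swap_isometries <- function(coloring, group,
                                  scheme = encoding_scheme()) {
  stopifnot(group$n_bits == 6)
  cols <- unclass(coloring)
  n1 <- sum(cols == "I"); n2 <- sum(cols == "II")
  if (n1 == 0 || n2 == 0)
    return(new_coset(integer(), group, "a class is empty"))
  if (n1 != n2)
    return(new_coset(integer(), group,
                     paste0("cardinality mismatch (|I| = ", n1,
                            ", |II| = ", n2, ")")))
  labels <- codons_to_labels(names(coloring), scheme, values = cols)
  swapped <- labels
  swapped[labels == "I"] <- "II"
  swapped[labels == "II"] <- "I"
  # g swaps the classes iff swap(labels)[g(x)] == labels[x] for all x
  img <- matrix(swapped[group$action], nrow = group$order)
  ref <- matrix(labels, nrow = group$order, ncol = 64, byrow = TRUE)
  rows <- which(rowSums(img != ref) == 0L)
  new_coset(rows, group,
            if (length(rows)) NA_character_ else "no isometry swaps the classes")
}

new_coset <- function(rows, group, reason) {
  structure(
    list(count = length(rows), elements = rows,
         perms = group$perms[rows, , drop = FALSE],
         flips = group$flips[rows, , drop = FALSE],
         universe_order = group$order, reason = reason),
    class = "isometry_coset")
}

#' @export
print.isometry_coset <- function(x, ...) {
  if (x$count == 0)
    cat("Empty isometry coset (", x$reason, ")\n", sep = "")
  else
    cat("Isometry coset of ", x$count, " elements (universe order ",
        x$universe_order, ")\n", sep = "")
  invisible(x)
}

#' Isometries mapping one codon partition onto another
#'
#' Finds all elements `g` such that the image of every block of
#' `partition_a` is exactly some block of `partition_b` (any block
#' bijection). Used to ask whether the Rodin-Ohno middle-base partition
#' {NAN, NGN, NUN, NCN} corresponds to the R/Y partition
#' {RNR, YNR, RNY, YNY} through a Hamming isometry. An empty result is
#' reported honestly (the correspondence may exist only outside the
#' isometry group, e.g. as a piecewise-defined map).
#'
#' @param partition_a,partition_b Lists of codon sets covering the same
#'   codon universe, with equal block-size multisets.
#' @param group An `isometry_group` on 6 bits.
#' @param scheme An [encoding_scheme()] or its name.
#' @return List with `count`, `elements` (row indices) and `bijections`
#'   (character descriptions "a-block -> b-block" per element), plus
#'   `reason` when empty.
#' @export
partition_correspondence <- function(partition_a, partition_b, group,
                                     scheme = encoding_scheme()) {
  stopifnot(group$n_bits == 6)
  ua <- sort(unlist(partition_a)); ub <- sort(unlist(partition_b))
  if (anyDuplicated(ua) || anyDuplicated(ub))
    stop("partition blocks must be disjoint")
  if (!identical(ua, ub))
    stop("partitions must cover the same codon universe")
  sa <- sort(lengths(partition_a)); sb <- sort(lengths(partition_b))
  if (!identical(sa, sb))
    return(list(count = 0L, elements = integer(), bijections = character(),
                reason = "block-size multisets differ"))
  la <- rep(0L, 64); lb <- rep(0L, 64)
  for (k in seq_along(partition_a))
    la[codon_index(partition_a[[k]], scheme) + 1L] <- k
  for (k in seq_along(partition_b))
    lb[codon_index(partition_b[[k]], scheme) + 1L] <- k
  m <- group$order
  ok <- rep(TRUE, m)
  target <- matrix(0L, m, length(partition_a))
  for (k in seq_along(partition_a)) {
    cols <- which(la == k)
    imgs <- matrix(lb[group$action[, cols, drop = FALSE]], nrow = m)
    const <- rowSums(imgs == imgs[, 1]) == length(cols)
    in_b <- imgs[, 1] > 0L
    ok <- ok & const & in_b
    target[, k] <- imgs[, 1]
  }
  # block map must be injective
  ok <- ok & apply(target, 1, function(r) !anyDuplicated(r))
  rows <- which(ok)
  bij <- vapply(rows, function(r)
    paste(seq_along(partition_a), "->", target[r, ], collapse = ", "),
    character(1))
  list(count = length(rows), elements = rows, bijections = bij,
       reason = if (length(rows)) NA_character_ else
         "no isometry maps partition_a onto partition_b")
}

# order of each element (as a permutation of the vertex set)
#' Element orders of a group or subgroup
#'
#' @param group An `isometry_group` (or subgroup).
#' @return Integer vector: the multiplicative order of each element's
#'   action on the vertex set.
#' @export
element_orders <- function(group) {
  lcm2 <- function(a, b) a / gcd2(a, b) * b
  gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
  apply(group$action, 1, function(p) {
    seen <- logical(length(p)); ord <- 1
    for (s in seq_along(p)) {
      if (seen[s]) next
      len <- 0L; x <- s
      repeat {
        seen[x] <- TRUE; x <- p[x]; len <- len + 1L
        if (x == s) break
      }
      ord <- lcm2(ord, len)
    }
    ord
  })
}

#' Full symmetry report for one code stage
#'
#' Aggregates, for one evolutionary stage under one configuration: the
#' codon-level class counts, the stabilizer of the stage's codon set, the
#' color-preserving subgroup of its aaRS coloring, the Class I/II swap
#' coset, and cheap isomorphism invariants (element-order multisets) of
#' the subgroups.
#'
#' @param stage A `code_stage` or stage name (see [build_stage()]).
#' @param table A `genetic_code` table.
#' @param classification An `aars_classification` (fixes the Lys
#'   convention).
#' @param group The isometry universe to search, from [isometry_group()]
#'   (built on demand when `NULL`).
#' @param scheme An [encoding_scheme()] or its name.
#' @return Object of class `symmetry_report`: list of scalar fields and
#'   order multisets, serializable with [report_to_json()].
#' @export
mirror_symmetry_report <- function(stage,
                                   table = standard_genetic_code(),
                                   classification = aars_classification("class_II"),
                                   group = NULL,
                                   scheme = encoding_scheme()) {
  if (!inherits(stage, "code_stage")) stage <- build_stage(stage, table)
  if (is.null(group)) group <- isometry_group(6, "full")
  scheme <- as_scheme(scheme)
  coloring <- color_codons(stage$codons, table, classification)
  counts <- codon_class_counts(stage$codons, table, classification)
  stab <- stabilizer_of_set(stage$codons, group, scheme)
  colg <- color_preserving_group(coloring, group, scheme)
  swap <- class_swap_isometries(coloring, group, scheme)
  structure(
    list(stage = stage$name,
         scheme = scheme$name,
         universe = group$flavor,
         universe_order = group$order,
         lys_convention = attr(classification, "lys_convention"),
         n_codons = length(stage$codons),
         codon_class_counts = as.list(counts),
         stabilizer_order = stab$order,
         color_preserving_order = colg$order,
         swap_element_count = swap$count,
         swap_reason = swap$reason,
         stabilizer_order_multiset = order_multiset(stab),
         color_preserving_order_multiset = order_multiset(colg)),
    class = "symmetry_report")
}

order_multiset <- function(subgroup) {
  tab <- table(element_orders(subgroup))
  stats::setNames(as.list(as.integer(tab)), names(tab))
}

#' @export
print.symmetry_report <- function(x, ...) {
  cat("Symmetry report for stage ", x$stage, " [universe ", x$universe,
      ", order ", format(x$universe_order, big.mark = ","),
      "; Lys -> ", x$lys_convention, "]\n", sep = "")
  cat("  codons: ", x$n_codons, " (",
      paste(names(x$codon_class_counts), unlist(x$codon_class_counts),
            sep = "=", collapse = ", "), ")\n", sep = "")
  cat("  set stabilizer order:        ", x$stabilizer_order, "\n")
  cat("  color-preserving order:      ", x$color_preserving_order, "\n")
  cat("  Class I<->II swap elements:  ", x$swap_element_count,
      if (x$swap_element_count == 0) paste0(" (", x$swap_reason, ")"), "\n",
      sep = "")
  invisible(x)
}

#' Serialize a report to deterministic JSON
#'
#' @param report A `symmetry_report` (or any list).
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
report_to_json <- function(report, path = NULL) {
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null", na = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
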