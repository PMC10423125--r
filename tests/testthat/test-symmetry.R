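test_that("group orders follow the hyperoctahedral closed form", {
  expect_identical(isometry_group(2)$order, 8L)     # 2^2 * 2!
  expect_identical(isometry_group(3)$order, 48L)    # 2^3 * 3!
  expect_identical(full_group()$order, 46080L)      # 2^6 * 6!
  expect_identical(isometry_group(6, "codon_structured")$order, 3072L)
  expect_error(isometry_group(7), "refused")
  expect_error(isometry_group(3, "codon_structured"), "n_bits = 6")
})

test_that("small groups satisfy the group axioms exhaustively", {
  for (n in 2:3) {
    g <- isometry_group(n)
    keys <- apply(g$action, 1, paste, collapse = ",")
    expect_identical(anyDuplicated(keys), 0L)        # distinct elements
    id <- paste(seq_len(2^n), collapse = ",")
    expect_identical(keys[1], id)                    # identity first
    # closure and inverses
    inv_found <- logical(g$order)
    for (i in seq_len(g$order)) {
      for (j in seq_len(g$order)) {
        comp <- g$action[i, g$action[j, ]]
        k <- paste(comp, collapse = ",")
        expect_true(k %in% keys)
        if (k == id) inv_found[i] <- TRUE
      }
    }
    expect_true(all(inv_found))
  }
})

test_that("the full 6-bit group is closed and distance-preserving (spot checks)", {
  g <- full_group()
  keys <- apply(g$action, 1, paste, collapse = ",")
  expect_identical(anyDuplicated(keys), 0L)
  set.seed(11)
  cods <- all_codons()
  for (rep in 1:25) {
    i <- sample(g$order, 1); j <- sample(g$order, 1)
    comp <- g$action[i, g$action[j, ]]
    expect_true(paste(comp, collapse = ",") %in% keys)
    a <- sample(cods, 1); b <- sample(cods, 1)
    expect_identical(
      hamming_bit(apply_isometry(g, i, a), apply_isometry(g, i, b)),
      hamming_bit(a, b))
  }
})

test_that("the codon-structured flavor is a subgroup of the full group", {
  g <- full_group()
  gc <- isometry_group(6, "codon_structured")
  keys <- apply(g$action, 1, paste, collapse = ",")
  set.seed(5)
  rows <- sample(gc$order, 40)
  for (i in rows)
    expect_true(paste(gc$action[i, ], collapse = ",") %in% keys)
})

test_that("set stabilizers match the naive oracle on the 8 pattern cubes", {
  g <- full_group()
  for (cube in ry_partition()) {
    fast <- stabilizer_of_set(cube, g)
    # Lagrange: subgroup order divides the group order
    expect_identical(g$order %% fast$order, 0L)
    slow <- oracle_stabilizer_rows(cube, g)
    expect_identical(sort(fast$elements), slow)
  }
})

test_that("stabilizer of the full space is the whole group", {
  g <- full_group()
  expect_identical(stabilizer_of_set(all_codons(), g)$order, g$order)
})

test_that("color-preserving subgroups match the naive oracle", {
  g <- full_group()
  tab <- standard_genetic_code()
  for (pat in c("RRY", "YRR")) {
    cube <- pattern_set(pat)
    col <- color_codons(cube, tab)
    fast <- color_preserving_group(col, g)
    slow <- oracle_color_rows(col, g)
    expect_identical(sort(fast$elements), slow)
    expect_identical(g$order %% fast$order, 0L)
    # constant coloring: color-preserving = set stabilizer
    const <- structure(setNames(rep("I", length(cube)), cube),
                       class = "aars_coloring")
    expect_identical(color_preserving_group(const, g)$order,
                     stabilizer_of_set(cube, g)$order)
  }
})

test_that("a coloring by one bit is preserved by all elements fixing that bit", {
  g <- full_group()
  bit1 <- codon_bits(all_codons())[, 1]
  col <- structure(setNames(ifelse(bit1 == 0, "I", "II"), all_codons()),
                   class = "aars_coloring")
  cp <- color_preserving_group(col, g)
  # elements with perm fixing coordinate 1 and no flip of bit 1 preserve it
  fix1 <- g$perms[, 1] == 1 & g$flips[, 1] == 0
  expect_true(all(which(fix1) %in% cp$elements))
  # and the bit-1 flip element swaps the classes
  sw <- class_swap_isometries(col, g)
  expect_gt(sw$count, 0)
  flip1 <- which(apply(g$perms, 1, function(p) all(p == 1:6)) &
                 g$flips[, 1] == 1 &
                 rowSums(g$flips[, -1, drop = FALSE]) == 0)
  expect_true(flip1 %in% sw$elements)
  # nonempty swap sets are cosets: size equals the color-preserving order
  expect_identical(sw$count, cp$order)
})

test_that("swap searches report cardinality mismatches without searching", {
  g <- full_group()
  col <- structure(setNames(c("I", "II", "II"), c("AAA", "AAC", "AAG")),
                   class = "aars_coloring")
  sw <- class_swap_isometries(col, g)
  expect_identical(sw$count, 0L)
  expect_match(sw$reason, "cardinality mismatch")
})

test_that("swap results are empty or coset-sized for the stage colorings", {
  g <- full_group()
  tab <- standard_genetic_code()
  for (lys in c("class_I", "class_II", "ambiguous")) {
    cls <- aars_classification(lys)
    for (stage in c("RNY", "EXT1", "EXT2", "SGC")) {
      col <- color_codons(build_stage(stage, tab)$codons, tab, cls)
      sw <- class_swap_isometries(col, g)
      if (sw$count > 0) {
        cp <- color_preserving_group(col, g)
        expect_identical(sw$count, cp$order)
      } else {
        expect_false(is.na(sw$reason))
      }
    }
  }
})

test_that("Watson-Crick complementation is a group element mapping RNY to YNR", {
  g <- full_group()
  # the translation by the constant pair-sum vector (1,0) per position
  row <- which(apply(g$perms, 1, function(p) all(p == 1:6)) &
               apply(g$flips, 1, function(f) all(f == c(1, 0, 1, 0, 1, 0))))
  expect_length(row, 1)
  cods <- all_codons()
  expect_identical(apply_isometry(g, row, cods), wc_complement(cods))
  expect_setequal(apply_isometry(g, row, pattern_set("RNY")),
                  pattern_set("YNR"))
})

test_that("partition correspondence finds isometries from the middle-base to the R/Y partition", {
  g <- full_group()
  ro <- lapply(c("NAN", "NGN", "NUN", "NCN"), pattern_set)
  ry <- lapply(c("RNR", "YNR", "RNY", "YNY"), pattern_set)
  same <- partition_correspondence(ro, ro, g)
  expect_true(1 %in% same$elements)                 # identity qualifies
  cross <- partition_correspondence(ro, ry, g)
  expect_gt(cross$count, 0)
  # verify one reported element really maps blocks onto blocks
  e <- cross$elements[1]
  img <- lapply(ro, function(b) sort(apply_isometry(g, e, b)))
  expect_true(all(vapply(img, function(s)
    any(vapply(ry, function(b) setequal(s, b), logical(1))), logical(1))))
  # unequal block sizes are rejected up front
  bad <- partition_correspondence(
    list(all_codons()[1:32], all_codons()[33:64]),
    list(all_codons()[1:16], all_codons()[17:64]), g)
  expect_identical(bad$count, 0L)
  expect_match(bad$reason, "block-size")
})

test_that("mirror symmetry reports are complete and deterministic", {
  g <- full_group()
  rep1 <- mirror_symmetry_report("RNY", group = g)
  expect_identical(rep1$n_codons, 16L)
  expect_identical(sum(unlist(rep1$codon_class_counts)), 16L)
  expect_identical(sum(unlist(rep1$stabilizer_order_multiset)),
                   rep1$stabilizer_order)
  rep2 <- mirror_symmetry_report("RNY", group = g)
  expect_identical(report_to_json(rep1), report_to_json(rep2))
  # EXT2 and SGC reports carry the swap-element field
  for (st in c("EXT2", "SGC")) {
    r <- mirror_symmetry_report(st, group = g)
    expect_true(is.numeric(r$swap_element_count))
    expect_identical(r$universe_order, 46080L)
  }
})
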