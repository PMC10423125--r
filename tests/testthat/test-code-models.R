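test_that("the built-in code table matches an independent reference", {
  skip_if_not_installed("Biostrings")
  tab <- standard_genetic_code()
  ref <- Biostrings::GENETIC_CODE  # DNA codons, one-letter codes
  one_to_three <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
                    Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
                    L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
                    S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
                    `*` = "STOP")
  ref3 <- setNames(unname(one_to_three[ref]),
                   gsub("T", "U", names(ref)))
  expect_identical(unname(unclass(tab)[names(ref3)]), unname(ref3))
})

test_that("the built-in table has the SGC shape", {
  tab <- standard_genetic_code()
  expect_length(tab, 64)
  expect_identical(sum(unclass(tab) == "STOP"), 3L)
  expect_length(unique(unclass(tab)[unclass(tab) != "STOP"]), 20)
})

test_that("pattern sets have the predicted cardinalities and identities", {
  expect_length(pattern_set("NNN"), 64)
  expect_length(pattern_set("RNY"), 16)
  expect_length(pattern_set("RRR"), 8)
  expect_length(pattern_set("AUG"), 1)
  expect_setequal(c(pattern_set("RYY"), pattern_set("RRY")),
                  pattern_set("RNY"))
  expect_error(pattern_set("RNX"), "'X'")
  expect_error(pattern_set("RN"), "length 3")
})

test_that("the 8 pure R/Y patterns partition the codon space", {
  part <- ry_partition()
  expect_length(part, 8)
  expect_true(all(lengths(part) == 8))
  all64 <- sort(unlist(part))
  expect_identical(unname(all64), all_codons())  # disjoint union of all 64
})

test_that("the four 16-codon transversion patterns partition the space", {
  sets <- lapply(c("RNY", "YNY", "RNR", "YNR"), pattern_set)
  expect_identical(sort(unlist(sets)), all_codons())
})

test_that("stages carry the published codon and amino-acid accounting", {
  rny <- build_stage("RNY")
  expect_length(rny$codons, 16)
  expect_setequal(rny$amino_acids,
                  c("Asn", "Ser", "Thr", "Ile", "Asp", "Gly", "Ala", "Val"))
  # every RNY amino acid has exactly two RNY codons
  labs <- unclass(standard_genetic_code())[rny$codons]
  expect_true(all(table(labs) == 2))

  ext1 <- build_stage("EXT1")
  expect_length(ext1$codons, 48)
  expect_identical(ext1$stop_codons, c("UAA", "UAG", "UGA"))
  expect_setequal(ext1$complement,
                  c(pattern_set("RRR"), pattern_set("YYY")))

  ext2 <- build_stage("EXT2")
  expect_length(ext2$codons, 48)
  expect_length(ext2$amino_acids, 18)
  expect_true("AUG" %in% ext2$codons)
  expect_length(ext2$stop_codons, 0)
  expect_setequal(ext2$complement,
                  c(pattern_set("YYR"), pattern_set("YRR")))

  expect_error(build_stage("XYZ"), "unknown stage")
})

test_that("amino-acid accounting of codon subsets matches the code table", {
  expect_identical(amino_acids_of(character())$amino_acids, character())
  nny <- amino_acids_of(pattern_set("NNY"))
  expect_length(nny$amino_acids, 15)
  expect_identical(nny$stop_count, 0L)
  yny <- amino_acids_of(pattern_set("YNY"))
  expect_length(yny$amino_acids, 8)
  # additivity: |NNY| = |RNY| + |new in YNY|
  expect_length(new_amino_acids(pattern_set("YNY"), pattern_set("RNY")), 7)
  expect_identical(length(nny$amino_acids),
                   8L + 7L)
})

test_that("new-amino-acid counts reproduce the stage-wise accounting", {
  nny <- pattern_set("NNY")
  expect_setequal(new_amino_acids(pattern_set("RNR"), nny),
                  c("Lys", "Met", "Glu"))
  expect_length(new_amino_acids(pattern_set("YNR"), nny), 2)
  expect_length(new_amino_acids(pattern_set("NNR"), nny), 5)
})

test_that("duplication reports partition each complement's amino acids", {
  for (name in c("RNY", "EXT1", "EXT2")) {
    stage <- build_stage(name)
    rep <- duplication_report(stage)
    expect_length(intersect(rep$duplicated, rep$new), 0)
    expect_setequal(c(rep$duplicated, rep$new), rep$complement_amino_acids)
    # stage plus complement covers all 20 amino acids
    expect_setequal(union(stage$amino_acids, rep$complement_amino_acids),
                    aars_classification()$amino_acid)
  }
  ext1 <- duplication_report(build_stage("EXT1"))
  expect_setequal(ext1$complement_amino_acids,
                  c("Lys", "Arg", "Glu", "Gly", "Pro", "Leu", "Ser", "Phe"))
  expect_setequal(ext1$new, c("Lys", "Glu", "Phe"))
  ext2 <- duplication_report(build_stage("EXT2"))
  expect_setequal(ext2$complement_amino_acids,
                  c("Gln", "Arg", "Trp", "Pro", "Leu", "Ser"))
  expect_identical(ext2$complement_stop_codons, c("UAA", "UAG", "UGA"))
  # the SGC has an empty complement and an explicitly empty report
  sgc_rep <- duplication_report(build_stage("SGC"))
  expect_length(sgc_rep$complement_amino_acids, 0)
})

test_that("degeneracy profile matches the code and conserves 64 codons", {
  prof <- degeneracy_profile()
  expect_identical(unname(prof[c("Leu", "Ser", "Arg")]), c(6L, 6L, 6L))
  expect_identical(unname(prof["Ile"]), 3L)
  expect_identical(unname(prof["Met"]), 1L)
  expect_identical(sum(prof) + 3L, 64L)
})

test_that("the TSV loader validates and is order-independent", {
  path <- system.file("extdata", "standard_genetic_code.tsv",
                      package = "codonsym")
  tab <- load_code_table(path)
  expect_identical(as.vector(unclass(tab)),
                   as.vector(unclass(standard_genetic_code())))

  df <- as.data.frame(standard_genetic_code())
  shuffled <- tempfile(fileext = ".tsv")
  set.seed(42)
  write.table(df[sample(nrow(df)), ], shuffled, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  expect_identical(unclass(load_code_table(shuffled))[all_codons()],
                   unclass(tab)[all_codons()])

  truncated <- tempfile(fileext = ".tsv")
  write.table(df[df$codon != "AUG", ], truncated, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  expect_error(load_code_table(truncated), "missing codon: AUG")

  duped <- tempfile(fileext = ".tsv")
  write.table(rbind(df, df[1, ]), duped, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  expect_error(load_code_table(duped), "duplicate codon")
})
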