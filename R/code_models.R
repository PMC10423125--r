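# Genetic code tables, R/Y/N pattern sets, and the four evolutionary
# stages of the code (RNY, extended RNA codes type 1 and 2, SGC), with
# amino-acid accounting (coded / new / duplicated) for each stage and its
# complement.

# one- <-> three-letter amino-acid codes
AA_ONE_TO_THREE <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
  Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
  L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
  S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
  `*` = "STOP")

AA_THREE <- unname(AA_ONE_TO_THREE[1:20])

normalize_label <- function(label) {
  label <- as.character(label)
  up <- toupper(label)
  out <- character(length(label))
  for (i in seq_along(label)) {
    l <- label[i]
    if (up[i] %in% c("STOP", "*", "TER")) {
      out[i] <- "STOP"
    } else if (nchar(l) == 1 && l %in% names(AA_ONE_TO_THREE)) {
      out[i] <- AA_ONE_TO_THREE[[l]]
    } else {
      m <- AA_THREE[match(tolower(l), tolower(AA_THREE))]
      if (is.na(m))
        stop("unknown amino-acid label '", l, "'")
      out[i] <- m
    }
  }
  out
}

.SGC_LABELS <- c(
  AAA = "Lys", AAC = "Asn", AAG = "Lys", AAU = "Asn",
  ACA = "Thr", ACC = "Thr", ACG = "Thr", ACU = "Thr",
  AGA = "Arg", AGC = "Ser", AGG = "Arg", AGU = "Ser",
  AUA = "Ile", AUC = "Ile", AUG = "Met", AUU = "Ile",
  CAA = "Gln", CAC = "His", CAG = "Gln", CAU = "His",
  CCA = "Pro", CCC = "Pro", CCG = "Pro", CCU = "Pro",
  CGA = "Arg", CGC = "Arg", CGG = "Arg", CGU = "Arg",
  CUA = "Leu", CUC = "Leu", CUG = "Leu", CUU = "Leu",
  GAA = "Glu", GAC = "Asp", GAG = "Glu", GAU = "Asp",
  GCA = "Ala", GCC = "Ala", GCG = "Ala", GCU = "Ala",
  GGA = "Gly", GGC = "Gly", GGG = "Gly", GGU = "Gly",
  GUA = "Val", GUC = "Val", GUG = "Val", GUU = "Val",
  UAA = "STOP", UAC = "Tyr", UAG = "STOP", UAU = "Tyr",
  UCA = "Ser", UCC = "Ser", UCG = "Ser", UCU = "Ser",
  UGA = "STOP", UGC = "Cys", UGG = "Trp", UGU = "Cys",
  UUA = "Leu", UUC = "Phe", UUG = "Leu", UUU = "Phe")

new_genetic_code <- function(labels, source) {
  labels <- labels[sort(names(labels))]
  structure(labels, class = "genetic_code", source = source)
}

#' The built-in standard genetic code table
#'
#' The canonical mapping of the 64 RNA codons to the 20 amino acids
#' (three-letter codes) and the three stop codons (label `"STOP"`),
#' ordered alphabetically.
#'
#' @return A named character vector of class `genetic_code` (names are
#'   codons, values amino-acid labels), with a `source` attribute.
#' @examples
#' tab <- standard_genetic_code()
#' tab["AUG"]
#' @export
standard_genetic_code <- function() {
  new_genetic_code(.SGC_LABELS, source = "built-in SGC")
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code table (", attr(x, "source"), "): ",
      sum(x != "STOP"), " sense codons, ", sum(x == "STOP"),
      " stops, ", length(unique(x[x != "STOP"])),
      " amino acids\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.genetic_code <- function(x, ...) {
  data.frame(codon = names(x), label = unname(unclass(x)),
             stringsAsFactors = FALSE)
}

validate_code_table <- function(labels) {
  problems <- character()
  dup <- unique(names(labels)[duplicated(names(labels))])
  if (length(dup))
    problems <- c(problems, paste0("duplicate codon: ", dup))
  missing <- setdiff(codons64(), names(labels))
  if (length(missing))
    problems <- c(problems, paste0("missing codon: ", missing))
  extra <- setdiff(names(labels), codons64())
  if (length(extra))
    problems <- c(problems, paste0("invalid codon: ", extra))
  problems
}

#' Load a genetic code table from a TSV file
#'
#' Expects 64 data lines `codon<TAB>label` (RNA alphabet; label a one- or
#' three-letter amino-acid code or `STOP`); lines starting with `#` are
#' ignored. Duplicate, missing or invalid codons are rejected with a
#' message naming each offender.
#'
#' @param path Path to the TSV file.
#' @return A `genetic_code` object.
#' @export
load_code_table <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE,
                           col.names = c("codon", "label"))
  codons <- validate_codons(raw$codon)
  labels <- stats::setNames(normalize_label(raw$label), codons)
  problems <- validate_code_table(labels)
  if (length(problems))
    stop("invalid code table '", path, "':\n  ",
         paste(problems, collapse = "\n  "))
  new_genetic_code(labels, source = path)
}

# --- pattern sets ----------------------------------------------------------

PATTERN_ALPHABET <- c("R", "Y", "N", "A", "C", "G", "U")

expand_pattern_char <- function(ch) {
  switch(ch, R = PURINES, Y = PYRIMIDINES, N = NUCLEOTIDES, ch)
}

#' Codons matching an R/Y/N pattern
#'
#' A pattern is a length-3 string over `{R, Y, N, A, C, G, U}`; `R`
#' matches the purines A and G, `Y` the pyrimidines C and U, `N` any
#' nucleotide, and a literal matches itself. The returned set has
#' cardinality equal to the product of the per-position match counts.
#'
#' @param pattern Length-3 pattern string, e.g. `"RNY"`.
#' @return Sorted character vector of matching codons, with the pattern
#'   stored in attribute `pattern`.
#' @examples
#' length(pattern_set("RNY"))  # 16
#' @export
pattern_set <- function(pattern) {
  if (length(pattern) != 1L || !is.character(pattern))
    stop("pattern must be a single string")
  pattern <- toupper(pattern)
  if (nchar(pattern) != 3L)
    stop("pattern must have length 3, got '", pattern, "'")
  ch <- strsplit(pattern, "")[[1]]
  bad <- setdiff(ch, PATTERN_ALPHABET)
  if (length(bad))
    stop("invalid pattern character '", bad[1], "' in '", pattern, "'")
  g <- expand.grid(p3 = expand_pattern_char(ch[3]),
                   p2 = expand_pattern_char(ch[2]),
                   p1 = expand_pattern_char(ch[1]),
                   stringsAsFactors = FALSE)
  structure(sort(paste0(g$p1, g$p2, g$p3)), pattern = pattern)
}

#' The eight pure R/Y pattern cubes partitioning the codon space
#'
#' The eight patterns over `{R, Y}^3` each match 8 codons; the sets are
#' pairwise disjoint and their union is the full 64-codon space. Each is a
#' 3-dimensional coordinate-aligned affine subspace of the 6-cube (a
#' cube with 12 edges).
#'
#' @return Named list of eight codon sets, names `RRR`, `RRY`, ...,
#'   `YYY`.
#' @export
ry_partition <- function() {
  pats <- apply(expand.grid(c("R", "Y"), c("R", "Y"), c("R", "Y"))[, 3:1],
                1, paste0, collapse = "")
  pats <- sort(pats)
  stats::setNames(lapply(pats, pattern_set), pats)
}

# --- amino-acid accounting -------------------------------------------------

#' Amino acids coded by a codon set
#'
#' @param codons Character vector of codons (a subset of the 64).
#' @param table A `genetic_code` table.
#' @return List with `amino_acids` (sorted distinct labels, stops
#'   excluded) and `stop_count` (number of stop codons in the set).
#' @export
amino_acids_of <- function(codons, table = standard_genetic_code()) {
  if (length(codons) == 0)
    return(list(amino_acids = character(), stop_count = 0L))
  codons <- validate_codons(codons)
  labels <- unclass(table)[codons]
  list(amino_acids = sort(unique(labels[labels != "STOP"])),
       stop_count = sum(labels == "STOP"))
}

#' Amino acids coded by a set but not by a baseline set
#'
#' @param codons,baseline Codon sets.
#' @param table A `genetic_code` table.
#' @return Sorted character vector of the amino acids coded by `codons`
#'   that no codon of `baseline` codes for.
#' @export
new_amino_acids <- function(codons, baseline,
                            table = standard_genetic_code()) {
  setdiff(amino_acids_of(codons, table)$amino_acids,
          amino_acids_of(baseline, table)$amino_acids)
}

#' Codon-count degeneracy profile of a code table
#'
#' @param table A `genetic_code` table.
#' @return Named integer vector, amino acid -> number of codons; the
#'   counts plus the stop count total 64.
#' @export
degeneracy_profile <- function(table = standard_genetic_code()) {
  labels <- unclass(table)
  tab <- table(labels[labels != "STOP"])
  stats::setNames(as.integer(tab), names(tab))
}

# --- evolutionary stages ---------------------------------------------------

STAGE_NAMES <- c("RNY", "EXT1", "EXT2", "NNY", "NNR", "SGC")

stage_patterns <- function(name) {
  switch(name,
         RNY  = "RNY",
         EXT1 = c("RNY", "NYR", "YRN"),
         EXT2 = c("RNY", "YNY", "RNR"),
         NNY  = "NNY",
         NNR  = "NNR",
         SGC  = "NNN",
         stop("unknown stage name '", name, "'; expected one of ",
              paste(STAGE_NAMES, collapse = ", ")))
}

#' Build an evolutionary stage of the genetic code
#'
#' The stages model the hypothesized trajectory from a primeval RNY code
#' to the standard genetic code:
#' \describe{
#'   \item{RNY}{the 16 purine-N-pyrimidine codons of the primeval RNA
#'     code}
#'   \item{EXT1}{extended RNA code type 1: RNY plus the frameshift
#'     reading-frame sets NYR and YRN (48 codons; contains the three stop
#'     codons)}
#'   \item{EXT2}{extended RNA code type 2: RNY plus the first- and
#'     third-position transversion sets YNY and RNR (48 codons; contains
#'     AUG, no stops)}
#'   \item{NNY, NNR}{the 32-codon half-spaces ending in pyrimidine or
#'     purine}
#'   \item{SGC}{the full 64-codon standard code}
#' }
#'
#' @param name Stage name, one of `"RNY"`, `"EXT1"`, `"EXT2"`, `"NNY"`,
#'   `"NNR"`, `"SGC"`.
#' @param table A `genetic_code` table used for the amino-acid accounting.
#' @return Object of class `code_stage`: list with `name`, `codons`,
#'   `amino_acids`, `stop_codons` (stops inside the stage), `complement`
#'   (codons outside the stage), `patterns`, and `definition_source`.
#' @examples
#' ext2 <- build_stage("EXT2")
#' length(ext2$codons)       # 48
#' length(ext2$amino_acids)  # 18
#' @export
build_stage <- function(name, table = standard_genetic_code()) {
  name <- toupper(name)
  pats <- stage_patterns(name)
  codons <- sort(unique(unlist(lapply(pats, pattern_set))))
  labels <- unclass(table)[codons]
  aa <- amino_acids_of(codons, table)
  structure(
    list(name = name,
         patterns = pats,
         codons = codons,
         amino_acids = aa$amino_acids,
         stop_codons = sort(codons[labels == "STOP"]),
         complement = setdiff(codons64(), codons),
         definition_source = "introduction"),
    class = "code_stage")
}

#' @export
print.code_stage <- function(x, ...) {
  cat("Code stage ", x$name, " (", paste(x$patterns, collapse = " U "),
      "): ", length(x$codons), " codons, ", length(x$amino_acids),
      " amino acids, ", length(x$stop_codons), " stops; complement ",
      length(x$complement), " codons\n", sep = "")
  invisible(x)
}

#' Duplicated vs newly introduced amino acids in a stage's complement
#'
#' Partitions the amino acids coded by the codons outside a stage into
#' those already coded inside the stage (duplicated when the complement
#' is added) and those first appearing in the complement.
#'
#' @param stage A `code_stage`.
#' @param table A `genetic_code` table.
#' @return List with `complement_amino_acids`, `duplicated`, `new`
#'   (sorted label vectors) and `complement_stop_codons`.
#' @export
duplication_report <- function(stage, table = standard_genetic_code()) {
  stopifnot(inherits(stage, "code_stage"))
  if (length(stage$complement) == 0)
    return(list(complement_amino_acids = character(),
                duplicated = character(), new = character(),
                complement_stop_codons = character()))
  comp_aa <- amino_acids_of(stage$complement, table)$amino_acids
  labels <- unclass(table)[stage$complement]
  list(complement_amino_acids = comp_aa,
       duplicated = intersect(comp_aa, stage$amino_acids),
       new = setdiff(comp_aa, stage$amino_acids),
       complement_stop_codons = sort(stage$complement[labels == "STOP"]))
}
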