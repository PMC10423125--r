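# Aminoacyl-tRNA synthetase (aaRS) Class I/II and subclass a-c
# assignments of the twenty amino acids, and class colorings of codon
# sets. Lysine is the one amino acid served by synthetases of both
# structural classes (LysRS-I and LysRS-II); its resolution is a
# configuration choice ("Lys convention").

.AARS_BASE <- data.frame(
  amino_acid = c("Met", "Val", "Leu", "Ile", "Cys", "Arg",
                 "Glu", "Gln",
                 "Tyr", "Trp",
                 "Ser", "Thr", "Ala", "Gly", "Pro", "His",
                 "Asp", "Asn",
                 "Phe",
                 "Lys"),
  class = c(rep("I", 6), rep("I", 2), rep("I", 2),
            rep("II", 6), rep("II", 2), "II",
            "BOTH"),
  subclass = c(rep("a", 6), rep("b", 2), rep("c", 2),
               rep("a", 6), rep("b", 2), "c",
               "b"),
  notes = c(rep("", 10),
            "SerRS recognizes the tRNA variable arm, not the anticodon",
            rep("", 2),
            "GlyRS occurs as alpha2 (IIa) and alpha2beta2 (IIc); class II either way",
            rep("", 4), "",
            "LysRS has class I and class II forms"),
  stringsAsFactors = FALSE)

LYS_CONVENTIONS <- c("ambiguous", "class_I", "class_II")

#' The built-in aaRS classification of the twenty amino acids
#'
#' Class I subclasses: Ia (Met, Val, Leu, Ile, Cys, Arg), Ib (Glu, Gln,
#' Lys-I), Ic (Tyr, Trp). Class II: IIa (Ser, Thr, Ala, Gly, Pro, His),
#' IIb (Asp, Asn, Lys-II), IIc (Phe). SepRS and PylRS charge
#' non-canonical amino acids absent from the standard code table and are
#' excluded by default.
#'
#' @param lys_convention How to resolve lysine, whose synthetase exists in
#'   both classes: `"ambiguous"` keeps class `BOTH` (the default for
#'   per-stage counts), `"class_I"` or `"class_II"` force one class
#'   (`"class_II"` is the only choice yielding the symmetric 10 + 10
#'   split of the twenty synthetases).
#' @param extended If `TRUE`, append Sep (SepRS, IIc) and Pyl (PylRS,
#'   IIc) records.
#' @return Data frame of class `aars_classification` with columns
#'   `amino_acid`, `class`, `subclass`, `notes`, plus attribute
#'   `lys_convention`.
#' @examples
#' cls <- aars_classification("class_II")
#' table(cls$class)  # 10 + 10
#' @export
aars_classification <- function(lys_convention = LYS_CONVENTIONS,
                                extended = FALSE) {
  lys_convention <- match.arg(lys_convention)
  df <- .AARS_BASE
  if (lys_convention != "ambiguous")
    df$class[df$amino_acid == "Lys"] <-
      sub("class_", "", lys_convention)
  if (extended)
    df <- rbind(df, data.frame(
      amino_acid = c("Sep", "Pyl"), class = "II", subclass = "c",
      notes = c("SepRS; non-canonical (phosphoserine)",
                "PylRS; non-canonical (pyrrolysine)"),
      stringsAsFactors = FALSE))
  df <- df[order(df$amino_acid), ]
  rownames(df) <- NULL
  structure(df, class = c("aars_classification", "data.frame"),
            lys_convention = lys_convention)
}

#' Class and subclass of one amino acid
#'
#' @param amino_acid Amino-acid label (one- or three-letter code).
#' @inheritParams aars_classification
#' @return List with `class` (`"I"`, `"II"` or `"BOTH"`) and `subclass`
#'   (`"a"`, `"b"` or `"c"`).
#' @examples
#' classify("Val")                   # class I, subclass a
#' classify("Lys", "ambiguous")      # class BOTH
#' @export
classify <- function(amino_acid, lys_convention = LYS_CONVENTIONS,
                     extended = FALSE) {
  lys_convention <- match.arg(lys_convention)
  aa <- if (amino_acid %in% c("Sep", "Pyl")) amino_acid
        else normalize_label(amino_acid)
  if (aa == "STOP") stop("STOP is not an amino acid")
  cls <- aars_classification(lys_convention, extended = extended)
  i <- match(aa, cls$amino_acid)
  if (is.na(i))
    stop("no aaRS record for '", aa, "'",
         if (aa %in% c("Sep", "Pyl")) " (enable extended = TRUE)" else "")
  list(class = cls$class[i], subclass = cls$subclass[i])
}

#' Load an aaRS classification from a TSV file
#'
#' Expects lines `amino_acid<TAB>class<TAB>subclass` covering each of the
#' twenty amino acids exactly once; class is `I`, `II` or `BOTH` (BOTH is
#' allowed only for Lys), subclass `a`, `b` or `c`.
#'
#' @param path Path to the TSV file.
#' @return An `aars_classification` data frame (Lys convention
#'   `"ambiguous"` unless the file resolves it).
#' @export
load_aars_classification <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE,
                           col.names = c("amino_acid", "class", "subclass"))
  raw$amino_acid <- normalize_label(raw$amino_acid)
  problems <- character()
  dup <- unique(raw$amino_acid[duplicated(raw$amino_acid)])
  if (length(dup)) problems <- c(problems, paste0("duplicate record: ", dup))
  missing <- setdiff(AA_THREE, raw$amino_acid)
  if (length(missing)) problems <- c(problems, paste0("missing amino acid: ", missing))
  bad_class <- raw$amino_acid[!raw$class %in% c("I", "II", "BOTH")]
  if (length(bad_class)) problems <- c(problems, paste0("invalid class for: ", bad_class))
  both <- raw$amino_acid[raw$class == "BOTH" & raw$amino_acid != "Lys"]
  if (length(both)) problems <- c(problems, paste0("class BOTH only allowed for Lys, not: ", both))
  bad_sub <- raw$amino_acid[!raw$subclass %in% c("a", "b", "c")]
  if (length(bad_sub)) problems <- c(problems, paste0("invalid subclass for: ", bad_sub))
  if (length(problems))
    stop("invalid aaRS classification '", path, "':\n  ",
         paste(problems, collapse = "\n  "))
  df <- raw[order(raw$amino_acid), ]
  df$notes <- ""
  rownames(df) <- NULL
  structure(df, class = c("aars_classification", "data.frame"),
            lys_convention = if (any(raw$class == "BOTH")) "ambiguous" else "file")
}

class_of <- function(amino_acids, classification) {
  cl <- classification$class[match(amino_acids, classification$amino_acid)]
  ifelse(cl == "BOTH", "AMBIGUOUS", cl)
}

#' Amino-acid-level aaRS class counts for a code stage
#'
#' Counts the distinct amino acids coded by a stage that fall in each
#' class; stops are excluded, and codon multiplicity is irrelevant.
#'
#' @param stage A `code_stage` (or codon character vector).
#' @param table A `genetic_code` table.
#' @param classification An `aars_classification`; its Lys convention
#'   determines whether Lys counts toward class I, class II, or an
#'   `ambiguous` bin.
#' @return Named integer vector `c(I = , II = , ambiguous = )`.
#' @examples
#' class_counts(build_stage("RNY"))  # 2 class I, 6 class II
#' @export
class_counts <- function(stage, table = standard_genetic_code(),
                         classification = aars_classification("ambiguous")) {
  codons <- if (inherits(stage, "code_stage")) stage$codons else stage
  aa <- amino_acids_of(codons, table)$amino_acids
  cl <- class_of(aa, classification)
  c(I = sum(cl == "I"), II = sum(cl == "II"),
    ambiguous = sum(cl == "AMBIGUOUS"))
}

#' Color a codon set by aaRS class
#'
#' Every codon is colored by the class of the amino acid it codes for
#' (`"I"`, `"II"`, or `"AMBIGUOUS"` for Lys under the ambiguous
#' convention); stop codons get color `"STOP"`. Stops are kept because
#' they are part of the code structure whose symmetry is analyzed.
#'
#' @param codons Codon character vector.
#' @param table A `genetic_code` table.
#' @param classification An `aars_classification`. The default resolves
#'   Lys to class II, the convention that yields the 10 + 10 synthetase
#'   split.
#' @return Named character vector of class `aars_coloring` (names =
#'   codons in canonical order, values = colors), with provenance
#'   attributes `lys_convention` and `table_source`.
#' @export
color_codons <- function(codons, table = standard_genetic_code(),
                         classification = aars_classification("class_II")) {
  codons <- sort(validate_codons(codons))
  labels <- unclass(table)[codons]
  colors <- ifelse(labels == "STOP", "STOP",
                   class_of(labels, classification))
  structure(stats::setNames(colors, codons), class = "aars_coloring",
            lys_convention = attr(classification, "lys_convention"),
            table_source = attr(table, "source"))
}

#' @export
print.aars_coloring <- function(x, ...) {
  cat("aaRS class coloring of ", length(x), " codons (Lys convention: ",
      attr(x, "lys_convention"), "): ",
      paste(names(table(unclass(x))), as.integer(table(unclass(x))),
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Codon-level aaRS class counts
#'
#' Unlike [class_counts()], counts codons (hypercube vertices), not
#' distinct amino acids — the granularity at which stage colorings are
#' drawn and symmetry searches run.
#'
#' @inheritParams color_codons
#' @return Named integer vector over colors `I`, `II`, `AMBIGUOUS`,
#'   `STOP`.
#' @export
codon_class_counts <- function(codons, table = standard_genetic_code(),
                               classification = aars_classification("class_II")) {
  col <- color_codons(codons, table, classification)
  out <- c(I = 0L, II = 0L, AMBIGUOUS = 0L, STOP = 0L)
  tab <- table(unclass(col))
  out[names(tab)] <- as.integer(tab)
  out
}
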