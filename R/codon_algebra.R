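# Klein four-group encoding of nucleotides and the 6-bit codon space.
#
# Each nucleotide is a 2-bit vector over GF(2); a codon is the
# concatenation of its three nucleotide vectors (position 1 first,
# purine/pyrimidine bit before the within-class bit), giving a bijection
# between the 64 codons and {0,1}^6 and hence between codons and the
# vertices of the 6-dimensional hypercube.

#' RNA nucleotide symbols in canonical order
#' @keywords internal
NUCLEOTIDES <- c("A", "C", "G", "U")

PURINES     <- c("A", "G")
PYRIMIDINES <- c("C", "U")

#' All 64 RNA codons in canonical (alphabetical, position-major) order
#'
#' @return Character vector of length 64, sorted A < C < G < U.
#' @examples
#' head(all_codons())
#' @export
all_codons <- function() {
  g <- expand.grid(p3 = NUCLEOTIDES, p2 = NUCLEOTIDES, p1 = NUCLEOTIDES,
                   stringsAsFactors = FALSE)
  sort(paste0(g$p1, g$p2, g$p3))
}

# memoised codon universe
.CODONS <- NULL
codons64 <- function() {
  if (is.null(.CODONS)) utils::assignInMyNamespace(".CODONS", all_codons())
  .CODONS
}

#' Nucleotide-to-bit encoding schemes (square arrangements)
#'
#' An encoding scheme assigns the four nucleotides bijectively to the four
#' elements of the Klein four-group \eqn{Z_2 \times Z_2}. Every shipped
#' scheme keeps the first bit as the purine/pyrimidine (R/Y) class bit, so
#' that the R/Y pattern sets (RNY, YNY, ...) are coordinate-aligned
#' subspaces of the 6-cube. Schemes are named by the nucleotide order
#' assigned to the Klein elements (00, 01, 10, 11):
#' \describe{
#'   \item{AGUC}{default; A is the group identity, second bit separates
#'     weak (A,U) from strong (C,G) pairs}
#'   \item{AGCU}{A identity, second bit separates amino (A,C) from keto
#'     (G,U) bases}
#'   \item{CUAG}{C identity (pyrimidine identity), weak/strong second bit;
#'     under this scheme sets of codons ending in a pyrimidine contain the
#'     zero codon CCC and pattern subspaces through it are linear}
#'   \item{CUGA}{C identity, amino/keto second bit}
#' }
#' Under every scheme the two Watson-Crick pair sums A+U and G+C equal the
#' same constant Klein element, as required for complementation to act by
#' translation.
#'
#' @param name Scheme name, one of `"AGUC"`, `"AGCU"`, `"CUAG"`, `"CUGA"`.
#' @return An object of class `encoding_scheme`: list with `name`, `bits`
#'   (4 x 2 0/1 matrix, rows named by nucleotide), `identity_nt`, and
#'   `r_bit_value` (the value of the R/Y bit on purines).
#' @examples
#' sch <- encoding_scheme()
#' sch$bits["A", ]   # the Klein identity under the default scheme
#' @export
encoding_scheme <- function(name = c("AGUC", "AGCU", "CUAG", "CUGA")) {
  name <- match.arg(name)
  order <- strsplit(name, "")[[1]]
  bits <- matrix(c(0L, 0L, 0L, 1L, 1L, 0L, 1L, 1L), ncol = 2, byrow = TRUE)
  rownames(bits) <- order
  bits <- bits[NUCLEOTIDES, , drop = FALSE]
  r_vals <- unique(bits[PURINES, 1])
  y_vals <- unique(bits[PYRIMIDINES, 1])
  stopifnot(length(r_vals) == 1, length(y_vals) == 1, r_vals != y_vals)
  structure(
    list(name = name,
         bits = bits,
         identity_nt = order[1],
         r_bit_value = r_vals),
    class = "encoding_scheme")
}

#' @export
print.encoding_scheme <- function(x, ...) {
  cat("Klein encoding scheme '", x$name, "' (identity: ", x$identity_nt,
      ", purine R/Y-bit value: ", x$r_bit_value, ")\n", sep = "")
  print(x$bits)
  invisible(x)
}

as_scheme <- function(scheme) {
  if (inherits(scheme, "encoding_scheme")) scheme else encoding_scheme(scheme)
}

# --- codon validation ------------------------------------------------------

validate_codons <- function(codons, dna = FALSE) {
  codons <- toupper(as.character(codons))
  if (dna) codons <- gsub("T", "U", codons, fixed = TRUE)
  bad_len <- nchar(codons) != 3L
  if (any(bad_len))
    stop("codon(s) of length != 3: ", paste(codons[bad_len], collapse = ", "))
  chars <- strsplit(codons, "")
  for (i in seq_along(chars)) {
    unknown <- setdiff(chars[[i]], NUCLEOTIDES)
    if (length(unknown))
      stop("invalid nucleotide symbol '", unknown[1], "' in codon '",
           codons[i], "'", if (!dna && unknown[1] == "T")
             " (use dna = TRUE to accept T)" else "")
  }
  codons
}

codon_chars <- function(codons) {
  matrix(unlist(strsplit(codons, "")), ncol = 3, byrow = TRUE)
}

# --- encoding --------------------------------------------------------------

#' Bit matrix of codons under a scheme
#'
#' @param codons Character vector of codons.
#' @param scheme An [encoding_scheme()] or its name.
#' @param dna If `TRUE`, accept `T` and map it to `U`.
#' @return Integer 0/1 matrix with one row per codon and 6 columns
#'   (position-major, R/Y bit first within each position).
#' @export
codon_bits <- function(codons, scheme = encoding_scheme(), dna = FALSE) {
  scheme <- as_scheme(scheme)
  codons <- validate_codons(codons, dna = dna)
  ch <- codon_chars(codons)
  out <- matrix(0L, nrow = length(codons), ncol = 6)
  for (p in 1:3) {
    out[, 2 * p - 1] <- scheme$bits[ch[, p], 1]
    out[, 2 * p]     <- scheme$bits[ch[, p], 2]
  }
  rownames(out) <- codons
  out
}

BIT_WEIGHTS <- as.integer(2^(5:0))

#' Integer index (0-63) of codons in the 6-bit word order
#'
#' The index reads the 6-bit word most-significant-bit first, so the zero
#' codon (the scheme's identity nucleotide repeated) has index 0.
#'
#' @inheritParams codon_bits
#' @return Integer vector in `0:63`.
#' @export
codon_index <- function(codons, scheme = encoding_scheme(), dna = FALSE) {
  as.integer(drop(codon_bits(codons, scheme, dna = dna) %*% BIT_WEIGHTS))
}

#' Decode 6-bit indices or bit rows back to codons
#'
#' @param x Integer vector of indices in `0:63`, or a 0/1 matrix with 6
#'   columns.
#' @param scheme An [encoding_scheme()] or its name.
#' @return Character vector of codons.
#' @export
decode_codon <- function(x, scheme = encoding_scheme()) {
  scheme <- as_scheme(scheme)
  if (is.matrix(x)) {
    bits <- x
  } else {
    stopifnot(all(x >= 0 & x <= 63))
    bits <- t(vapply(as.integer(x),
                     function(i) as.integer(intToBits(i)[6:1]),
                     integer(6)))
  }
  key <- paste0(scheme$bits[, 1], scheme$bits[, 2])
  lut <- stats::setNames(rownames(scheme$bits), key)
  nt <- function(p) lut[paste0(bits[, 2 * p - 1], bits[, 2 * p])]
  unname(paste0(nt(1), nt(2), nt(3)))
}

#' Encode a single codon as a codon vector object
#'
#' @param codon A single codon string.
#' @inheritParams codon_bits
#' @return Object of class `codon_vector`: list with `codon`, `bits`
#'   (length-6 integer vector) and `index` (0-63).
#' @examples
#' encode_codon("AUG")
#' @export
encode_codon <- function(codon, scheme = encoding_scheme(), dna = FALSE) {
  stopifnot(length(codon) == 1L)
  scheme <- as_scheme(scheme)
  b <- codon_bits(codon, scheme, dna = dna)
  structure(
    list(codon = rownames(b), bits = drop(b),
         index = as.integer(drop(b %*% BIT_WEIGHTS)),
         scheme = scheme$name),
    class = "codon_vector")
}

#' @export
print.codon_vector <- function(x, ...) {
  cat(x$codon, " -> (", paste(x$bits, collapse = ","), ")  index ",
      x$index, "  [scheme ", x$scheme, "]\n", sep = "")
  invisible(x)
}

# --- Klein addition --------------------------------------------------------

#' Klein four-group addition of nucleotides
#'
#' Componentwise GF(2) addition of the 2-bit encodings. The group is
#' abelian, every element is its own inverse, and the sums of the two
#' Watson-Crick pairs (A+U and G+C) are the same constant element.
#'
#' @param n1,n2 Nucleotide symbols (vectorized).
#' @inheritParams codon_bits
#' @return Nucleotide symbol vector of the sums.
#' @export
klein_add <- function(n1, n2, scheme = encoding_scheme()) {
  scheme <- as_scheme(scheme)
  b1 <- scheme$bits[n1, , drop = FALSE]
  b2 <- scheme$bits[n2, , drop = FALSE]
  s <- (b1 + b2) %% 2L
  key <- paste0(scheme$bits[, 1], scheme$bits[, 2])
  lut <- stats::setNames(rownames(scheme$bits), key)
  unname(lut[paste0(s[, 1], s[, 2])])
}

# --- metrics ---------------------------------------------------------------

#' Nucleotide Hamming distance between codons
#'
#' Number of positions (0-3) at which two codons carry different
#' nucleotides; this is the edge metric of the codon graphs in which
#' adjacent codons differ by a single nucleotide.
#'
#' @param c1,c2 Codon character vectors (recycled to common length).
#' @param dna Accept `T` as `U`.
#' @return Integer vector of distances in `0:3`.
#' @export
hamming_nt <- function(c1, c2, dna = FALSE) {
  c1 <- validate_codons(c1, dna); c2 <- validate_codons(c2, dna)
  n <- max(length(c1), length(c2))
  c1 <- rep_len(c1, n); c2 <- rep_len(c2, n)
  as.integer(rowSums(codon_chars(c1) != codon_chars(c2)))
}

#' Bit Hamming distance between codons in the 6-cube
#'
#' Number of differing bits (0-6) of the 6-bit encodings; the graph metric
#' of the 6-dimensional hypercube. Satisfies
#' `hamming_nt <= hamming_bit <= 2 * hamming_nt`.
#'
#' @inheritParams hamming_nt
#' @param scheme An [encoding_scheme()] or its name (both codons must use
#'   the same scheme).
#' @return Integer vector of distances in `0:6`.
#' @export
hamming_bit <- function(c1, c2, scheme = encoding_scheme(), dna = FALSE) {
  scheme <- as_scheme(scheme)
  n <- max(length(c1), length(c2))
  b1 <- codon_bits(rep_len(c1, n), scheme, dna)
  b2 <- codon_bits(rep_len(c2, n), scheme, dna)
  as.integer(rowSums(b1 != b2))
}

# --- complement and transversions -----------------------------------------

#' Positionwise Watson-Crick complement of codons
#'
#' A <-> U and G <-> C at every position, without strand reversal. In the
#' Klein encoding this is addition of the constant Watson-Crick pair-sum
#' vector at each position, hence an involution and a translation (an
#' isometry) of the 6-cube. It maps the RNY pattern set onto YNR.
#'
#' @param codons Codon character vector.
#' @param dna Accept `T` as `U`.
#' @return Complemented codons.
#' @examples
#' wc_complement("AUG")  # "UAC"
#' @export
wc_complement <- function(codons, dna = FALSE) {
  codons <- validate_codons(codons, dna)
  chartr("AUGC", "UACG", codons)
}

#' Transversion operator at one codon position
#'
#' A transversion exchanges a purine for a pyrimidine. `kind = "ry"`
#' applies the Watson-Crick-type exchange (A <-> U, G <-> C), which under
#' the default scheme toggles exactly the R/Y bit of that position;
#' `kind = "full"` applies A <-> C, G <-> U, toggling both bits. Applying
#' the `"ry"` flip at position 1 to every RNY codon yields the YNY set;
#' flips at positions 1 and 3 map RNY onto YNR.
#'
#' @param codons Codon character vector.
#' @param position Codon position, 1, 2 or 3.
#' @param kind `"ry"` (single-bit flip) or `"full"` (double-bit flip).
#' @param dna Accept `T` as `U`.
#' @return Transformed codons.
#' @export
transversion <- function(codons, position, kind = c("ry", "full"),
                         dna = FALSE) {
  kind <- match.arg(kind)
  if (!(length(position) == 1L && position %in% 1:3))
    stop("position must be 1, 2 or 3")
  codons <- validate_codons(codons, dna)
  ch <- codon_chars(codons)
  map <- if (kind == "ry") c(A = "U", U = "A", G = "C", C = "G")
         else               c(A = "C", C = "A", G = "U", U = "G")
  ch[, position] <- map[ch[, position]]
  paste0(ch[, 1], ch[, 2], ch[, 3])
}
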