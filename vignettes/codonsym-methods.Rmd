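---
title: "Methods: codon-space symmetry of the aaRS class distribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon-space symmetry of the aaRS class distribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonsym)
```

## The model

`codonsym` treats the genetic code as a metric, algebraic object. Each
nucleotide is assigned an element of the Klein four-group
$\mathbb{Z}_2 \times \mathbb{Z}_2$; a codon is the concatenation of its
three 2-bit images, an element of $\mathbb{F}_2^6$. Two codons are
adjacent when they differ in exactly one bit, which makes the 64 codons
the vertices of the hypercube $Q_6$. On top of this geometry sit three
biological layers:

1. **Code stages.** A hypothesized evolutionary trajectory from a
   16-codon RNY code to the standard genetic code (SGC), through two
   48-codon intermediates: EXT1 = RNY ∪ NYR ∪ YRN, the codons read from
   the second and third reading frames of RNY messages, and EXT2 =
   RNY ∪ YNY ∪ RNR, the codons produced by transversions in the first or
   third position. EXT1 contains the three stop codons; EXT2 contains the
   start codon AUG and no stops.
2. **aaRS classes.** The twenty amino acids partitioned by the structural
   class of their aminoacyl-tRNA synthetase (Class I / Class II, with
   subclasses a–c). Lysine is served by synthetases of both classes and
   is resolved by an explicit convention.
3. **Symmetry.** The isometry group of the 6-bit Hamming space — the
   hyperoctahedral group $B_6$ of signed coordinate permutations
   $x \mapsto \pi(x) \oplus t$, order $2^6 \cdot 6! = 46{,}080$ —
   enumerated explicitly and filtered exhaustively against codon sets and
   their class colorings.

The package's central question is operational: for each stage, how large
is the subgroup of isometries preserving the stage's codon set, how large
the subgroup additionally preserving its Class I/II coloring, and does
any isometry *exchange* the Class I and Class II codon sets (a mirror
symmetry)?

## Encoding schemes and their one consequential choice

Any bijection from the four nucleotides to the four Klein elements works,
but only bijections in which one bit separates purines from pyrimidines
make the R/Y pattern sets (RNY, NNY, ...) coordinate-aligned subspaces.
All four shipped schemes ("AGUC", "AGCU", "CUAG", "CUGA", named by the
nucleotide order on the Klein elements 00, 01, 10, 11) have this
property, and all make the two Watson–Crick pair sums A+U and G+C equal
the same constant element, so positionwise complementation is a
translation of the cube — itself a group element.

The default scheme "AGUC" puts A at the group identity. One statement in
this literature — that the 32-codon NNY set is a *vector* subspace, i.e.
contains the zero codon — cannot hold under an A-identity scheme, because
AAA ends in a purine. It holds exactly when the identity nucleotide is a
pyrimidine, e.g. under "CUAG" where the zero codon is CCC. We therefore
report `contains_zero` as an explicit field of `subspace_report()` and
treat the affine/linear distinction as scheme-relative; dimension,
affineness and coordinate alignment are invariant across the shipped
schemes. This was a genuinely open design point: we chose to keep the
A-identity default (it makes the primeval RNY code's "ancestral" codon
AAA the origin) and expose the pyrimidine-identity scheme by name.

## Tunable parameters

* `scheme` (default `"AGUC"`): the Klein assignment, as above. Unitless;
  affects bit coordinates, never nucleotide-level facts.
* `lys_convention` (default `"ambiguous"` for per-stage amino-acid
  counts, `"class_II"` for colorings): how lysine's dual synthetase is
  resolved. `"class_II"` is the only resolution that yields the
  symmetric 10 + 10 split of the twenty synthetases given the subclass
  listing, so it is the default wherever the mirror question is asked;
  `"ambiguous"` keeps Lys visible as its own category in accounting.
* `universe` (default `"full"`): the symmetry search space. The full
  hyperoctahedral group (46,080 elements) is the default because the
  mirror question is about arbitrary isometries; the biologically
  structured subgroup (codon-position permutations × per-position 2-bit
  isometries, order $3! \cdot 8^3 = 3{,}072$) restricts to symmetries
  that respect codon positions, and every report records which universe
  was searched.
* `adjacency` (default `"bit"`): `"bit"` gives the $Q_6$ metric;
  `"nucleotide"` joins codons differing in one nucleotide regardless of
  bit distance (the "square with diagonals" arrangement, 288 edges). The
  published cube figures are consistent with bit adjacency under a fixed
  square arrangement, but the alternative is provided because the source
  text does not pin the convention down.

## Colorings are codon-level, stops included

Symmetry searches color *vertices* (codons), not amino acids: a codon's
color is the class of the amino acid it codes for, stop codons form their
own color class, and under the ambiguous convention the two Lys codons
form an `AMBIGUOUS` class. Stop and ambiguous classes must be preserved
setwise by every admissible isometry; only Class I and Class II may be
exchanged by a swap isometry. Two consequences worth stating plainly,
both computed, not assumed:

* A swap isometry can exist only if the Class I and Class II codon sets
  have equal cardinality. In the SGC the split is 29 vs 32 codons (Lys →
  II; 31 vs 30 under Lys → I; 29 vs 30 plus 2 ambiguous under the
  ambiguous convention), so at codon level no exhaustive search is even
  needed: the swap coset is empty for the SGC under every convention, and
  `class_swap_isometries()` reports the cardinality mismatch as the
  reason. Claims of Class I ↔ II interconvertibility in this literature
  evidently live at a different granularity (amino-acid identities, or
  maps outside the isometry group); the package reports the exhaustive
  codon-level outcome honestly rather than reproducing a number it
  cannot derive.
* Nonempty swap results are automatically cosets of the color-preserving
  subgroup, so their size equals that subgroup's order — a structural
  invariant the tests verify on constructed colorings where swaps do
  exist (e.g. coloring by the value of one bit).

## Exhaustive enumeration and its numerical choices

The group is materialized as an element table (permutation, flip vector)
plus the action of every element on the 64 vertex indices. All searches
are exact integer computations; there are no tolerances anywhere in the
package. Choices fixed for reproducibility:

* Elements are enumerated in lexicographic (permutation, flip) order;
  the identity is always element 1; subgroup listings inherit parent
  order, so reports are byte-stable across runs.
* Stabilizer and color filters use the label-invariance identity: a
  bijection of the vertex set preserves every label class iff
  `label[g(x)] == label[x]` for all x. The test suite checks this fast
  filter against a naive per-element set-image oracle on all eight R/Y
  cubes.
* The affine test translates the set by its first element (canonical
  codon order) and checks closure under XOR over all pairs; degenerate
  inputs (empty sets, non-power-of-two sizes) are rejected or reported
  not-affine rather than guessed at.
* Canonical codon order everywhere is alphabetical A < C < G < U,
  position-major. Ties never arise; every output list is sorted.
* Layouts are linear projections of the bit coordinates (weights 4/2/1
  per axis), injective on all 64 codons, so identical graphs always get
  identical, translation-consistent coordinates.

## The synthetic null module

The only "data-like" object in this analysis is a coloring of the codon
space, so the null generator produces randomized colorings under two
models:

* **shuffle-classes**: a uniformly random assignment of exactly 10 amino
  acids to Class I and 10 to Class II. This preserves the one structural
  constant the mirror hypothesis takes for granted (the 10 + 10 split)
  and destroys everything else.
* **shuffle-code-table**: amino-acid labels permuted among synonym
  blocks *of equal size* in the standard table, so every amino acid keeps
  its exact codon count and the degeneracy profile is unchanged as a
  named map (a free permutation over blocks would change it). Stop
  codons are never moved in either mode; stop placement is treated as a
  fixed feature of code structure, not a degree of freedom.

Reproducibility contract: sample *k* of a run is generated from a
substream seed mixed from (seed, *k*) by multiplicative hashing modulo
$2^{31}-1$, so any sample can be regenerated in isolation and the full
stream is a pure function of the base seed. The default of 200 null
samples makes the exhaustive 46,080-element filter per sample finish in
well under a minute in total; the acceptance script uses 200 samples for
the subgroup-order null and 500 independent partitions for the
class-frequency calibration.

What the null does and does not emulate: shuffled partitions share the
real classification's marginal structure (10 + 10 over amino acids
mapped through the real degeneracy), but they do not model the chemical
coherence of the true classes (subclasses grouping related amino acids),
correlated codon assignments, or any evolutionary process. A pass against
these nulls therefore says "more ordered than random relabeling", not
"explained".

## Problem sizes

All computations run on the full objects the analysis is about: the
64-codon space, the 46,080-element group, 200-sample nulls. Nothing is
scaled down; the complete test suite, including every exhaustive search
and a duplicated 200-sample null run, executes in a few minutes on one
CPU, and the acceptance script in under a minute.

## Known limitations

* Symmetry comparison across stages uses subgroup order and
  element-order multisets — cheap isomorphism invariants — not full
  abstract-group identification.
* Extended-code definitions follow the frameshift/transversion
  derivations (EXT1 frameshifts, EXT2 transversions); the literature
  also contains the reversed labeling, and stage reports record
  `definition_source` so downstream consumers can tell which convention
  produced them.
* Amino-acid-level mirror maps (as opposed to codon-level isometries)
  are out of scope, as are wobble rules, anticodon pairing, and
  physicochemical encodings of the amino acids.
* The non-canonical synthetases SepRS and PylRS are excluded by default
  (their amino acids do not appear in the standard table); an `extended`
  flag admits them for completeness.
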