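# Randomized null models for the aaRS symmetry analysis: shuffled 10+10
# class partitions of the twenty amino acids and degeneracy-preserving
# random code tables. Sample k of a stream is derived from (seed, k) by
# integer mixing, so any sample is reproducible in isolation.

#' Derive a per-sample substream seed
#'
#' Mixes a base seed with a sample counter (Knuth multiplicative hashing
#' modulo 2^31 - 1) so that sample `k` can be regenerated without drawing
#' samples `1..k-1`.
#'
#' @param seed Base integer seed.
#' @param k Sample counter (0 reserved for the run itself).
#' @return An integer seed.
#' @export
mix_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 2654435761 + as.numeric(k) * 40503 + 1) %%
               2147483647)
}

#' Random 10 + 10 aaRS class partition of the amino acids
#'
#' Uniformly assigns 10 of the twenty amino acids to Class I and 10 to
#' Class II; subclasses are filled round-robin (a, b, c) within each
#' class — the symmetry pipeline only consumes the class column.
#'
#' @param seed Integer seed (fully determines the partition).
#' @return An `aars_classification` data frame with attribute
#'   `lys_convention = "shuffled"`.
#' @examples
#' p <- random_class_partition(1)
#' table(p$class)  # always 10 + 10
#' @export
random_class_partition <- function(seed) {
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  class_I <- withr_seed(sample(AA_THREE, 10))
  df <- data.frame(
    amino_acid = sort(AA_THREE),
    class = ifelse(sort(AA_THREE) %in% class_I, "I", "II"),
    stringsAsFactors = FALSE)
  df$subclass <- ""
  for (cl in c("I", "II"))
    df$subclass[df$class == cl] <- rep_len(c("a", "b", "c"),
                                           sum(df$class == cl))
  df$notes <- ""
  structure(df, class = c("aars_classification", "data.frame"),
            lys_convention = "shuffled", seed = seed)
}

#' Random genetic code table
#'
#' With `preserve_degeneracy = TRUE` (default), amino-acid labels are
#' permuted among the standard code's synonym blocks of equal size, so
#' every amino acid keeps its exact codon count and the stop codons stay
#' fixed. With preservation off, the 61 sense codons are relabeled by a
#' random surjection onto the twenty amino acids (every amino acid gets
#' at least one codon); stops remain {UAA, UAG, UGA} in either mode —
#' stop placement is treated as a fixed feature of code structure.
#'
#' @param seed Integer seed.
#' @param preserve_degeneracy Keep the per-amino-acid codon counts of the
#'   standard code.
#' @return A `genetic_code` object.
#' @export
random_code_table <- function(seed, preserve_degeneracy = TRUE) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sgc <- unclass(standard_genetic_code())
  labels <- sgc
  sense <- names(sgc)[sgc != "STOP"]
  if (preserve_degeneracy) {
    prof <- degeneracy_profile(standard_genetic_code())
    for (size in unique(prof)) {
      block_aas <- names(prof)[prof == size]
      relab <- stats::setNames(sample(block_aas), block_aas)
      labels[sense] <- ifelse(sgc[sense] %in% block_aas,
                              relab[sgc[sense]], labels[sense])
    }
  } else {
    new_lab <- character(length(sense))
    first <- sample(seq_along(sense), 20)
    new_lab[first] <- sample(AA_THREE)
    new_lab[-first] <- sample(AA_THREE, length(sense) - 20, replace = TRUE)
    labels[sense] <- new_lab
  }
  new_genetic_code(labels, source = sprintf(
    "random (seed %d, %s)", seed,
    if (preserve_degeneracy) "degeneracy-preserving" else "free surjection"))
}

#' Null distribution of symmetry statistics for a stage
#'
#' Draws `n_samples` randomized colorings of a stage — either by
#' shuffling the 10+10 class partition over the amino acids
#' (`mode = "shuffle-classes"`) or by shuffling the code table
#' (`mode = "shuffle-code-table"`, degeneracy-preserving) — and runs the
#' color-preserving-subgroup and Class I/II swap searches on each. The
#' observed statistic under the real classification is reported alongside.
#'
#' @param stage A `code_stage` or stage name.
#' @param mode Null model type.
#' @param seed Base seed; sample k uses [mix_seed()]`(seed, k)`.
#' @param n_samples Number of null samples.
#' @param group Isometry universe (built as the full 6-bit group when
#'   `NULL`).
#' @param table The real `genetic_code` table.
#' @param classification The real `aars_classification` used for the
#'   observed statistic (and for colorings in code-table mode).
#' @param scheme An [encoding_scheme()] or its name.
#' @return Object of class `symmetry_null`: list with `samples` (data
#'   frame: `sample`, `seed`, `color_preserving_order`, `swap_count`),
#'   `summary` (quantiles of subgroup orders, fraction of samples with a
#'   nonempty swap coset) and `observed`.
#' @export
symmetry_null_distribution <- function(stage,
                                       mode = c("shuffle-classes",
                                                "shuffle-code-table"),
                                       seed = 1L,
                                       n_samples = 200L,
                                       group = NULL,
                                       table = standard_genetic_code(),
                                       classification = aars_classification("class_II"),
                                       scheme = encoding_scheme()) {
  mode <- match.arg(mode)
  if (n_samples == 0)
    return(structure(list(samples = data.frame(), summary = list(empty = TRUE),
                          observed = NULL, mode = mode, seed = seed),
                     class = "symmetry_null"))
  if (!inherits(stage, "code_stage")) stage <- build_stage(stage, table)
  if (is.null(group)) group <- isometry_group(6, "full")
  scheme <- as_scheme(scheme)

  one <- function(tab, cls) {
    coloring <- color_codons(stage$codons, tab, cls)
    colg <- color_preserving_group(coloring, group, scheme)
    swap <- class_swap_isometries(coloring, group, scheme)
    c(order = colg$order, swap = swap$count)
  }
  obs <- one(table, classification)
  res <- vapply(seq_len(n_samples), function(k) {
    sk <- mix_seed(seed, k)
    if (mode == "shuffle-classes")
      one(table, random_class_partition(sk))
    else
      one(random_code_table(sk, preserve_degeneracy = TRUE), classification)
  }, c(order = 0, swap = 0))
  samples <- data.frame(sample = seq_len(n_samples),
                        seed = vapply(seq_len(n_samples),
                                      function(k) mix_seed(seed, k), 1L),
                        color_preserving_order = res["order", ],
                        swap_count = res["swap", ])
  structure(
    list(samples = samples,
         summary = list(
           n_samples = n_samples,
           order_quantiles = as.list(stats::quantile(
             samples$color_preserving_order, c(0, .25, .5, .75, 1))),
           mean_order = mean(samples$color_preserving_order),
           fraction_swap_nonempty = mean(samples$swap_count > 0),
           fraction_order_gt_observed =
             mean(samples$color_preserving_order > obs["order"])),
         observed = list(color_preserving_order = unname(obs["order"]),
                         swap_count = unname(obs["swap"])),
         mode = mode, seed = seed, stage = stage$name,
         universe = group$flavor, universe_order = group$order),
    class = "symmetry_null")
}

#' @export
print.symmetry_null <- function(x, ...) {
  if (isTRUE(x$summary$empty)) {
    cat("Empty symmetry null summary (n_samples = 0)\n")
    return(invisible(x))
  }
  cat("Symmetry null distribution, stage ", x$stage, ", mode ", x$mode,
      ", ", x$summary$n_samples, " samples (seed ", x$seed, ")\n", sep = "")
  cat("  observed color-preserving order: ", x$observed$color_preserving_order,
      "; observed swap count: ", x$observed$swap_count, "\n", sep = "")
  cat("  null order quantiles: ",
      paste(names(x$summary$order_quantiles),
            unlist(x$summary$order_quantiles), sep = "=", collapse = ", "),
      "\n  fraction of null samples with nonempty swap coset: ",
      x$summary$fraction_swap_nonempty, "\n", sep = "")
  invisible(x)
}
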