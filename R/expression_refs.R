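#' Constitutively and invariantly expressed genes
#'
#' A seed essential gene should be expressed everywhere: essentials are
#' filtered for genes that are switched on (mean log2(FPKM + pseudocount)
#' above a threshold) and stably expressed (per-gene standard deviation below
#' the across-gene mean of per-gene standard deviations) in *every* supplied
#' expression data set. A gene absent from any table is excluded.
#'
#' @param tables List of `"bf_expr"` tibbles (e.g. one per RNA-seq compendium),
#'   each with at least 2 samples.
#' @param mean_threshold Minimum mean log2 expression; default 0.
#' @return Character vector of genes passing both rules in every table.
#' @export
constitutive_invariant_genes <- function(tables, mean_threshold = 0) {
  stopifnot(length(tables) >= 1)
  per_table <- lapply(tables, function(expr) {
    s <- expression_summary(expr)
    if (any(s$n_samples < 2)) rlang::abort("each table needs >= 2 samples")
    mean_sd <- mean(s$sd_log2)
    s$gene[s$mean_log2 > mean_threshold & s$sd_log2 < mean_sd]
  })
  Reduce(intersect, per_table)
}

#' Nonessential reference genes from absent expression
#'
#' Genes never meaningfully expressed across tissues and cell lines cannot be
#' broadly essential, and make a usable nonessential reference. A gene
#' qualifies if its FPKM is below `fpkm_threshold` in at least `n - min_below_offset`
#' of the `n` samples of *every* table (the default offset of 1 reproduces
#' "15 of 16" and "16 of 17" style rules for any table width), intersected
#' with the set of genes actually assayed by the screening library.
#'
#' @param tables List of `"bf_expr"` tibbles.
#' @param assayed Character vector of genes targeted by the reagent library.
#' @param fpkm_threshold Positive FPKM cutoff; default 0.1.
#' @param min_below_offset How many samples per table may exceed the cutoff;
#'   default 1.
#' @return Character vector of nonessential reference genes.
#' @export
nonessential_genes <- function(tables, assayed, fpkm_threshold = 0.1,
                               min_below_offset = 1) {
  stopifnot(length(tables) >= 1)
  if (!is.numeric(fpkm_threshold) || fpkm_threshold <= 0) {
    rlang::abort("fpkm_threshold must be positive")
  }
  per_table <- lapply(tables, function(expr) {
    x <- tibble::as_tibble(expr) |>
      dplyr::group_by(.data$gene) |>
      dplyr::summarise(n_below = sum(.data$fpkm < fpkm_threshold),
                       n = dplyr::n(), .groups = "drop")
    if (any(x$n <= min_below_offset)) {
      rlang::abort("table has too few samples for the required sample rule")
    }
    x$gene[x$n_below >= x$n - min_below_offset]
  })
  intersect(Reduce(intersect, per_table), as.character(assayed))
}

#' Build both expression-derived reference resources in one call
#'
#' Convenience wrapper: seed essentials from [seed_enrichment()] filtered to
#' constitutive/invariant genes, plus the nonessential set.
#'
#' @param enrichment Tibble from [seed_enrichment()].
#' @param tables List of `"bf_expr"` tibbles.
#' @param assayed Genes assayed by the library.
#' @inheritParams nonessential_genes
#' @return A [reference_sets()] object: filtered seed essentials vs
#'   expression-nonessential genes.
#' @export
build_reference_sets <- function(enrichment, tables, assayed,
                                 fpkm_threshold = 0.1, min_below_offset = 1) {
  seeds <- enrichment$gene[enrichment$seed_essential]
  ci <- constitutive_invariant_genes(tables)
  ne <- nonessential_genes(tables, assayed, fpkm_threshold, min_below_offset)
  reference_sets(intersect(seeds, ci), setdiff(ne, seeds))
}
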