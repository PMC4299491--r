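#' Bayes Factor of one gene in one screen
#'
#' A gene's log2 Bayes Factor is the sum of per-observation log2 likelihood
#' ratios over all of its cognate reagents, replicates, and timepoints in the
#' screen: for the typical design of 5 reagents assayed in 3 replicates, that
#' is 15 terms at each of two timepoints. Missing observations contribute no
#' term.
#'
#' @param gene Gene id.
#' @param fc A `"bf_fc"` fold-change tibble.
#' @param map Reagent-to-gene tibble.
#' @param densities Named list of `"density_pair"` objects for one screen,
#'   names = timepoint labels (one per timepoint).
#' @return One-row tibble: `gene`, `bf`, `n_obs` (terms summed). Zero-length
#'   tibble if the gene has no non-missing observation.
#' @export
gene_bayes_factor <- function(gene, fc, map, densities) {
  reagents <- map$reagent[map$gene == gene]
  obs <- tibble::as_tibble(fc) |>
    dplyr::filter(.data$reagent %in% reagents, !is.na(.data$fold_change),
                  .data$timepoint %in% names(densities))
  if (nrow(obs) == 0) return(tibble::tibble(gene = character(),
                                            bf = numeric(), n_obs = integer()))
  terms <- purrr::map_dbl(seq_len(nrow(obs)), function(i) {
    loglik_ratio(obs$fold_change[i], densities[[obs$timepoint[i]]])
  })
  tibble::tibble(gene = gene, bf = sum(terms), n_obs = length(terms))
}

#' Score every gene of one screen against trained likelihoods
#'
#' Fits the essential/nonessential likelihood densities for each timepoint of
#' the screen from the training half of the reference split, then scores
#' every mapped gene *not* in the training sets (training genes are never
#' scored against densities they helped fit; the swapped split supplies their
#' scores under twofold cross-validation, see [swap_split()]). BFs are the
#' sum of log2 likelihood ratios across timepoints, reagents, and replicates;
#' an optional prior converts them to posterior log odds.
#'
#' @param fc A `"bf_fc"` fold-change tibble.
#' @param map Reagent-to-gene tibble.
#' @param split A `"reference_split"` from [split_reference_sets()].
#' @param screen Screen id to score.
#' @param prior Optional `"bf_prior"`; adds a `lod` column.
#' @param bounds [truncation_bounds()].
#' @param bw_adjust,min_obs Passed to [fit_densities()].
#' @return Tibble: `gene`, `screen`, `bf`, `n_obs` (+ `lod` with a prior),
#'   one row per scored gene.
#' @export
run_screen <- function(fc, map, split, screen, prior = NULL,
                       bounds = truncation_bounds(), bw_adjust = 1,
                       min_obs = 30) {
  stopifnot(inherits(fc, "bf_fc"), inherits(split, "reference_split"))
  ann <- fc_samples(fc)
  if (!screen %in% ann$screen) {
    rlang::abort(paste0("screen not present in fold-change table: ", screen))
  }
  timepoints <- sort(unique(ann$timepoint[ann$screen == screen]))
  densities <- lapply(timepoints, function(tp) {
    fit_densities(fc, map, split$train, screen, tp, bounds = bounds,
                  bw_adjust = bw_adjust, min_obs = min_obs)
  })
  names(densities) <- timepoints

  train_genes <- c(split$train$essentials, split$train$nonessentials)
  obs <- tibble::as_tibble(fc) |>
    dplyr::filter(.data$screen == !!screen, !is.na(.data$fold_change)) |>
    dplyr::inner_join(map, by = "reagent") |>
    dplyr::filter(!.data$gene %in% train_genes)
  if (nrow(obs) == 0) rlang::abort("no scorable observations in this screen")

  obs <- obs |>
    dplyr::group_by(.data$timepoint) |>
    dplyr::mutate(llr = loglik_ratio(.data$fold_change,
                                     densities[[.data$timepoint[1]]])) |>
    dplyr::ungroup()
  out <- obs |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(bf = sum(.data$llr), n_obs = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(screen = !!screen, .after = "gene")
  if (!is.null(prior)) {
    out$lod <- apply_prior(out$bf, prior, genes = out$gene)
  }
  out
}

#' Score every screen of a compendium
#'
#' Runs [run_screen()] for each screen in the fold-change table with the same
#' reference split and binds the results into a long gene-by-screen Bayes
#' Factor table.
#'
#' @inheritParams run_screen
#' @param screens Screens to score; default all screens in `fc`.
#' @return Tibble of class `"bf_table"`: `gene`, `screen`, `bf`, `n_obs`
#'   (+ `lod` with a prior).
#' @export
run_compendium <- function(fc, map, split, screens = NULL, prior = NULL,
                           bounds = truncation_bounds(), bw_adjust = 1,
                           min_obs = 30) {
  if (is.null(screens)) screens <- sort(unique(fc_samples(fc)$screen))
  out <- purrr::map(screens, function(s) {
    run_screen(fc, map, split, s, prior = prior, bounds = bounds,
               bw_adjust = bw_adjust, min_obs = min_obs)
  }) |> purrr::list_rbind()
  class(out) <- c("bf_table", class(tibble::tibble()))
  out
}

#' Pick the score column of a Bayes Factor table
#'
#' LOD when a prior was applied, otherwise the raw BF.
#'
#' @param bf_table A `"bf_table"` (or any tibble with `bf`/`lod`).
#' @return The table with an added `score` column.
#' @export
bf_scores <- function(bf_table) {
  bf_table$score <- if ("lod" %in% names(bf_table)) bf_table$lod else bf_table$bf
  bf_table
}
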