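#' Precision-recall curve against withheld reference sets
#'
#' Genes are ranked by descending score (ties broken lexicographically by
#' gene id so curves are reproducible); genes in neither test set are
#' skipped. At each rank, TP and FP count test essentials and test
#' nonessentials at or above that rank, recall = TP / (number of test
#' essentials scored), precision = TP / (TP + FP).
#'
#' @param scores Data frame with columns `gene` and `score` (one screen's
#'   BFs or LODs; see [bf_scores()]).
#' @param test A [reference_sets()] object: the withheld testing half.
#' @return Tibble of class `"pr_curve"`: `gene`, `score`, `tp`, `fp`,
#'   `recall`, `precision`.
#' @export
pr_curve <- function(scores, test) {
  stopifnot(is.data.frame(scores), all(c("gene", "score") %in% names(scores)),
            inherits(test, "reference_sets"))
  x <- tibble::as_tibble(scores)[, c("gene", "score")] |>
    dplyr::filter(.data$gene %in% c(test$essentials, test$nonessentials)) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$gene)
  n_ess <- sum(x$gene %in% test$essentials)
  if (n_ess == 0) rlang::abort("no test essential gene was scored")
  x$tp <- cumsum(x$gene %in% test$essentials)
  x$fp <- cumsum(x$gene %in% test$nonessentials)
  x$recall <- x$tp / n_ess
  x$precision <- x$tp / (x$tp + x$fp)
  class(x) <- c("pr_curve", class(tibble::tibble()))
  x
}

#' Plot a precision-recall curve
#'
#' @param object A `"pr_curve"`.
#' @param score_threshold Marks the curve point where the score crosses this
#'   threshold (default 0); `NA` to omit.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pr_curve <- function(object, score_threshold = 0, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$recall,
                                            y = .data$precision)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision") +
    ggplot2::theme_minimal()
  if (!is.na(score_threshold) && any(object$score >= score_threshold)) {
    at <- utils::tail(dplyr::filter(object, .data$score >= score_threshold), 1)
    p <- p + ggplot2::geom_point(data = at, colour = "red", size = 2)
  }
  p
}

#' F-measure of a screen at a score threshold
#'
#' Harmonic mean of precision and recall, F = 2PR / (P + R), evaluated at the
#' last ranked gene whose score is at or above the threshold (the point where
#' the BF crosses zero for the default threshold of 0). Defined as 0 when
#' P + R = 0 or no gene reaches the threshold.
#'
#' @param curve A `"pr_curve"`.
#' @param score_threshold Score at which to read off P and R; default 0.
#' @return A single F value in \[0, 1\].
#' @export
f_measure <- function(curve, score_threshold = 0) {
  stopifnot(inherits(curve, "pr_curve"))
  at <- which(curve$score >= score_threshold)
  if (length(at) == 0) return(0)
  i <- max(at)
  p <- curve$precision[i]
  r <- curve$recall[i]
  if (p + r == 0) return(0)
  2 * p * r / (p + r)
}

#' Per-screen quality from a compendium Bayes Factor table
#'
#' Builds each screen's PR curve against the withheld test sets, computes the
#' F-measure at the score threshold, and flags screens at or above the
#' performance cutoff.
#'
#' @param bf_table A `"bf_table"` from [run_compendium()].
#' @param test A [reference_sets()] testing half.
#' @param score_threshold Threshold for the F-measure; default 0.
#' @param cutoff Screens with F >= `cutoff` are flagged performing; default
#'   0.75.
#' @return Tibble: `screen`, `f_measure`, `performing`, sorted by descending
#'   F-measure (ties by screen id).
#' @export
screen_quality <- function(bf_table, test, score_threshold = 0, cutoff = 0.75) {
  bf_table <- bf_scores(bf_table)
  out <- bf_table |>
    dplyr::group_by(.data$screen) |>
    dplyr::group_modify(function(df, key) {
      tibble::tibble(f_measure = f_measure(pr_curve(df, test), score_threshold))
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(performing = .data$f_measure >= cutoff) |>
    dplyr::arrange(dplyr::desc(.data$f_measure), .data$screen)
  out
}

#' Screens meeting the F-measure performance cutoff
#'
#' @param qualities Tibble from [screen_quality()] (columns `screen`,
#'   `f_measure`).
#' @param cutoff Inclusive F-measure cutoff; default 0.75.
#' @return Character vector of performing screen ids.
#' @export
classify_screens <- function(qualities, cutoff = 0.75) {
  qualities$screen[qualities$f_measure >= cutoff]
}

#' Count in how many screens each gene is a hit
#'
#' A hit is a score strictly above the threshold. Restricting to a stated
#' screen set gives the observation histogram used for core/total essential
#' calling and binwise FDR estimation.
#'
#' @param bf_table A `"bf_table"`.
#' @param screens Screens to count over.
#' @param score_threshold Hit threshold; default 0.
#' @param exclude_genes Genes to drop before counting (e.g. genes already hit
#'   in an earlier screen set, for exclusive histograms).
#' @return Tibble: `gene`, `n_screens` (>= 1; only genes hit somewhere
#'   appear).
#' @export
observation_counts <- function(bf_table, screens, score_threshold = 0,
                               exclude_genes = character()) {
  bf_table <- bf_scores(bf_table)
  bf_table |>
    dplyr::filter(.data$screen %in% screens,
                  .data$score > score_threshold,
                  !.data$gene %in% exclude_genes) |>
    dplyr::count(.data$gene, name = "n_screens")
}

#' Histogram of observation counts
#'
#' @param counts Tibble from [observation_counts()].
#' @param max_bin Largest bin (number of screens considered); counts are
#'   tabulated over 1..`max_bin`.
#' @return Tibble: `n_screens`, `n_genes`, `fraction` (of unique hit genes).
#' @export
observation_histogram <- function(counts, max_bin = max(counts$n_screens)) {
  tab <- counts |>
    dplyr::count(.data$n_screens, name = "n_genes") |>
    tidyr::complete(n_screens = seq_len(max_bin), fill = list(n_genes = 0L))
  tab$fraction <- tab$n_genes / sum(tab$n_genes)
  tab
}

#' Core essential genes: hits in at least half the performing screens
#'
#' @param bf_table A `"bf_table"`.
#' @param performing Character vector of performing screen ids.
#' @param score_threshold Hit threshold; default 0.
#' @param majority Fraction of performing screens required; default 0.5
#'   ("at least half": the boundary count ceiling(majority * n) is included).
#' @return Character vector of core essential genes.
#' @export
call_core_essentials <- function(bf_table, performing, score_threshold = 0,
                                 majority = 0.5) {
  if (length(performing) == 0) rlang::abort("no performing screens")
  counts <- observation_counts(bf_table, performing, score_threshold)
  need <- ceiling(majority * length(performing))
  sort(counts$gene[counts$n_screens >= need])
}

#' Total essential genes: hits in several of the top-ranked screens
#'
#' Genes hit (score above threshold) in at least `min_obs` of the first `k`
#' screens of the supplied ranking (screens ordered by descending F-measure).
#'
#' @param bf_table A `"bf_table"`.
#' @param ranked_screens Screens ordered best first (e.g.
#'   `screen_quality(...)$screen`).
#' @param k Number of top screens considered; default 12.
#' @param min_obs Minimum hit count; default 3.
#' @param score_threshold Hit threshold; default 0.
#' @return Character vector of total essential genes.
#' @export
call_total_essentials <- function(bf_table, ranked_screens, k = 12,
                                  min_obs = 3, score_threshold = 0) {
  if (k > length(ranked_screens)) {
    rlang::abort("k exceeds the number of available screens")
  }
  counts <- observation_counts(bf_table, ranked_screens[seq_len(k)],
                               score_threshold)
  sort(counts$gene[counts$n_screens >= min_obs])
}

#' Binwise false discovery rate from later screen sets
#'
#' If the primary screen set were saturated, every hit exclusive to a later,
#' disjoint set of screens would be a false positive; the later sets'
#' exclusive-hit histograms therefore model the frequency distribution of
#' false positives per observation-count bin. The expected false positives in
#' a bin is the mean of the later sets' exclusive counts there, and
#' FDR = min(1, expected / observed). Bins with no primary hits have
#' undefined FDR (`NA`).
#'
#' @param primary_hist Tibble from [observation_histogram()] for the primary
#'   screen set.
#' @param later_exclusive_hists List of such tibbles, one per later screen
#'   set, computed with the primary hits excluded
#'   (`observation_counts(..., exclude_genes = primary_hits)`).
#' @return Tibble: `n_screens`, `observed`, `expected_fp`, `fdr`.
#' @export
binwise_fdr <- function(primary_hist, later_exclusive_hists) {
  stopifnot(length(later_exclusive_hists) >= 1)
  bins <- primary_hist$n_screens
  expected <- rowMeans(sapply(later_exclusive_hists, function(h) {
    h$n_genes[match(bins, h$n_screens)] |> (\(x) ifelse(is.na(x), 0, x))()
  }))
  tibble::tibble(
    n_screens = bins,
    observed = primary_hist$n_genes,
    expected_fp = expected,
    fdr = ifelse(primary_hist$n_genes > 0,
                 pmin(1, expected / primary_hist$n_genes), NA_real_)
  )
}

#' Background error rate from trace-expression genes
#'
#' Genes with trace expression (mean log2 FPKM below the threshold,
#' default −2) cannot be essential in that context, so the fraction of them
#' called as hits estimates a screen's background error rate.
#'
#' @param hits Character vector of hit genes.
#' @param expr A `"bf_expr"` expression table.
#' @param trace_threshold Mean log2 FPKM below which a gene counts as trace;
#'   default −2.
#' @return Fraction of trace-expression genes found in `hits`.
#' @export
background_error_rate <- function(hits, expr, trace_threshold = -2) {
  s <- expression_summary(expr)
  trace <- s$gene[s$mean_log2 < trace_threshold]
  if (length(trace) == 0) rlang::abort("no trace-expression genes in table")
  mean(trace %in% hits)
}
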