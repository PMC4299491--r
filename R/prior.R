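#' Uniform prior on gene essentiality
#'
#' A flat prior odds ratio P(essential)/P(nonessential) applied identically
#' to every gene; the default 0.1 encodes a background expectation that about
#' 10% of assayed genes are essential, and adds log2(0.1) = −3.32 to each
#' log2 Bayes Factor.
#'
#' @param ratio Positive prior odds ratio; default 0.1.
#' @return A list of class `"bf_prior"` with `kind = "uniform"`.
#' @export
uniform_prior <- function(ratio = 0.1) {
  if (!is.numeric(ratio) || length(ratio) != 1 || ratio <= 0) {
    rlang::abort("prior ratio must be a positive scalar")
  }
  structure(list(kind = "uniform", ratio = ratio), class = "bf_prior")
}

#' Expression-based informative prior
#'
#' Wraps a fitted [fit_expression_prior()] model plus the expression table
#' used to look up each gene's level, for use in [run_screen()] /
#' [apply_prior()].
#'
#' @param model An `"expr_prior"` model.
#' @param expr A `"bf_expr"` expression table supplying per-gene mean
#'   log2(FPKM + pseudocount).
#' @return A list of class `"bf_prior"` with `kind = "expression"`.
#' @export
expression_prior <- function(model, expr) {
  stopifnot(inherits(model, "expr_prior"), inherits(expr, "bf_expr"))
  structure(list(kind = "expression", model = model,
                 expression = expression_summary(expr)),
            class = "bf_prior")
}

#' Convert Bayes Factors to posterior log odds (LOD)
#'
#' LOD = BF + log2(prior odds). Under the uniform prior the additive term is
#' the same for every gene (log2 of the ratio); under the expression prior it
#' is the model's emitted log2 prior for that gene's expression level.
#'
#' @param bf Numeric vector of log2 Bayes Factors.
#' @param prior A `"bf_prior"` from [uniform_prior()] or [expression_prior()].
#' @param expression Per-gene log2 expression, required (and recycled against
#'   `bf`) when `prior$kind == "expression"` and gene lookup is not used.
#' @param genes Optional gene ids; with an expression prior these are looked
#'   up in the prior's expression table when `expression` is not given.
#' @return Numeric vector of LOD scores.
#' @export
apply_prior <- function(bf, prior, expression = NULL, genes = NULL) {
  stopifnot(inherits(prior, "bf_prior"))
  if (prior$kind == "uniform") {
    return(bf + log2(prior$ratio))
  }
  if (is.null(expression)) {
    if (is.null(genes)) rlang::abort("expression prior needs expression or genes")
    expression <- prior$expression$mean_log2[match(genes, prior$expression$gene)]
  }
  bf + expression_prior_for_gene(prior$model, expression)
}

#' Fit the expression-vs-essentiality prior model
#'
#' Genes are rank-ordered by expression and cut into consecutive bins of
#' `bin_size` genes. Per bin the model records the mean expression level and
#' log2(fraction of the bin in the training essential set + pseudocount); the
#' pseudocount (default 0.001) prevents −Inf in empty bins. A least-squares
#' line is fitted over bins with mean expression above
#' `fit_min_mean_expression` (default 1 log2 FPKM), where the relation is
#' approximately linear; sparsely expressed bins are excluded from the fit.
#'
#' @param expr A `"bf_expr"` expression table (per-gene mean expression over
#'   its samples is used).
#' @param train_essentials Character vector: the training essential set.
#' @param bin_size Genes per bin; default 500 (must be >= 2).
#' @param pseudocount Added to the essential fraction before the log; default
#'   0.001.
#' @param fit_min_mean_expression Bins with mean expression at or below this
#'   are excluded from the linear fit; default 1.
#' @return A list of class `"expr_prior"`: `slope`, `intercept`, `bins`
#'   (tibble: `bin`, `mean_expression`, `n_genes`, `n_essential`,
#'   `log2_fraction`, `in_fit`), `pseudocount`, `floor`, `cap`.
#' @export
fit_expression_prior <- function(expr, train_essentials, bin_size = 500,
                                 pseudocount = 0.001,
                                 fit_min_mean_expression = 1) {
  stopifnot(inherits(expr, "bf_expr"))
  if (bin_size < 2) rlang::abort("bin_size must be >= 2")
  s <- expression_summary(expr)
  if (!any(s$gene %in% train_essentials)) {
    rlang::abort("no training essential gene is present in the expression table")
  }
  s <- dplyr::arrange(s, dplyr::desc(.data$mean_log2), .data$gene)
  s$bin <- ceiling(seq_len(nrow(s)) / bin_size)
  bins <- s |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      mean_expression = mean(.data$mean_log2),
      n_genes = dplyr::n(),
      n_essential = sum(.data$gene %in% train_essentials),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      log2_fraction = log2(.data$n_essential / .data$n_genes + pseudocount),
      in_fit = .data$mean_expression > fit_min_mean_expression
    )
  if (sum(bins$in_fit) < 2) {
    rlang::abort("need >= 2 bins with mean expression above the fit threshold")
  }
  fit <- stats::lm(log2_fraction ~ mean_expression, data = bins[bins$in_fit, ])
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 bins = bins, pseudocount = pseudocount,
                 floor = log2(pseudocount), cap = 0),
            class = "expr_prior")
}

#' @export
print.expr_prior <- function(x, ...) {
  cat(sprintf(
    "Expression prior: log2 P(essential) = %.4f * log2(FPKM) + %.4f (fit on %d of %d bins)\n",
    x$slope, x$intercept, sum(x$bins$in_fit), nrow(x$bins)))
  invisible(x)
}

#' Tidy the bin table of an expression prior model
#'
#' @param x An `"expr_prior"`.
#' @param ... Unused.
#' @return The per-bin tibble used for the fit.
#' @export
tidy.expr_prior <- function(x, ...) x$bins

#' One-row summary of an expression prior model
#'
#' @param x An `"expr_prior"`.
#' @param ... Unused.
#' @return Tibble: `slope`, `intercept`, `n_bins`, `n_bins_fit`.
#' @export
glance.expr_prior <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 n_bins = nrow(x$bins), n_bins_fit = sum(x$bins$in_fit))
}

#' Plot the binned expression-vs-essentiality relation and its linear fit
#'
#' @param object An `"expr_prior"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.expr_prior <- function(object, ...) {
  ggplot2::ggplot(object$bins,
                  ggplot2::aes(x = .data$mean_expression,
                               y = .data$log2_fraction,
                               colour = .data$in_fit)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "grey40") +
    ggplot2::labs(x = "mean log2(FPKM + pc) of bin",
                  y = "log2(fraction essential + pc)",
                  colour = "used in fit") +
    ggplot2::theme_minimal()
}

#' Emit the log2 prior for a gene's expression level
#'
#' Applies the fitted line and clamps the result into
#' \[log2(pseudocount), 0\]: a prior probability can exceed neither 1 (cap 0)
#' nor fall below the pseudocount floor.
#'
#' @param model An `"expr_prior"` model.
#' @param expression Numeric vector of log2 expression values.
#' @return Numeric vector of log2 prior values.
#' @export
expression_prior_for_gene <- function(model, expression) {
  stopifnot(inherits(model, "expr_prior"))
  pmin(pmax(model$slope * expression + model$intercept, model$floor), model$cap)
}
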