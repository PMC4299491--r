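#' Fold-change truncation bounds
#'
#' Individual reagent observations with extreme fold-changes would otherwise
#' dominate a gene's Bayes Factor through a vanishing nonessential likelihood,
#' so log2 fold-changes are truncated at −4 and +0.5 both when training the
#' densities and when scoring: fold-changes beyond these bounds carry no
#' additional evidence for or against essentiality.
#'
#' @param lower,upper Truncation bounds in log2 fold-change units; `lower`
#'   must be below `upper`.
#' @return A list of class `"trunc_bounds"`.
#' @export
truncation_bounds <- function(lower = -4, upper = 0.5) {
  if (!is.numeric(lower) || !is.numeric(upper) || lower >= upper) {
    rlang::abort("need lower < upper")
  }
  structure(list(lower = lower, upper = upper), class = "trunc_bounds")
}

clip_fc <- function(x, bounds) pmin(pmax(x, bounds$lower), bounds$upper)

#' Train the per-timepoint likelihood densities of a screen
#'
#' For one screen and timepoint, pools the (replicate-pooled, truncated)
#' fold-changes of all reagents targeting training-essential genes and fits a
#' Gaussian kernel density — the empirical likelihood
#' Pr(fold-change | essential) — and likewise for training nonessentials.
#' Densities are evaluated once on a fixed uniform grid (step 0.01, spanning
#' half a unit beyond the truncation bounds) and floored at 1e-6 of each
#' density's grid maximum so log-ratios stay finite; later lookups use linear
#' interpolation on this grid.
#'
#' @param fc A `"bf_fc"` fold-change tibble.
#' @param map Reagent-to-gene tibble.
#' @param train A [reference_sets()] object (the training half of a split).
#' @param screen,timepoint Which screen and timepoint to train on.
#' @param bounds [truncation_bounds()].
#' @param bw_adjust Scalar multiplier on the rule-of-thumb (Scott-type) kernel
#'   bandwidth; default 1.
#' @param min_obs Minimum training observations required per class; default 30.
#' @return A list of class `"density_pair"`: `screen`, `timepoint`, `grid`,
#'   `f_ess`, `f_non` (floored density values on the grid), `bounds`,
#'   `n_ess`, `n_non`.
#' @export
fit_densities <- function(fc, map, train, screen, timepoint,
                          bounds = truncation_bounds(), bw_adjust = 1,
                          min_obs = 30) {
  stopifnot(inherits(fc, "bf_fc"), inherits(train, "reference_sets"),
            inherits(bounds, "trunc_bounds"))
  obs <- tibble::as_tibble(fc) |>
    dplyr::filter(.data$screen == !!screen, .data$timepoint == !!timepoint,
                  !is.na(.data$fold_change)) |>
    dplyr::inner_join(map, by = "reagent")
  x_ess <- clip_fc(obs$fold_change[obs$gene %in% train$essentials], bounds)
  x_non <- clip_fc(obs$fold_change[obs$gene %in% train$nonessentials], bounds)
  if (length(x_ess) < min_obs || length(x_non) < min_obs) {
    rlang::abort(paste0(
      "too few training observations at screen ", screen, " timepoint ",
      timepoint, " (", length(x_ess), " essential / ", length(x_non),
      " nonessential, need ", min_obs,
      " each): enlarge the training reference sets"))
  }
  grid <- density_grid(bounds)
  structure(list(screen = screen, timepoint = timepoint, grid = grid,
                 f_ess = kde_on_grid(x_ess, grid, bw_adjust),
                 f_non = kde_on_grid(x_non, grid, bw_adjust),
                 bounds = bounds,
                 n_ess = length(x_ess), n_non = length(x_non)),
            class = "density_pair")
}

density_grid <- function(bounds, step = 0.01, pad = 0.5) {
  seq(bounds$lower - pad, bounds$upper + pad, by = step)
}

kde_on_grid <- function(x, grid, bw_adjust = 1, floor_frac = 1e-6) {
  bw <- tryCatch(stats::bw.nrd(x), error = function(e) NA_real_)
  if (!is.finite(bw) || bw <= 0) bw <- 0.01  # degenerate sample (all equal)
  d <- stats::density(x, bw = bw * bw_adjust, from = min(grid), to = max(grid),
                      n = length(grid))
  pmax(d$y, floor_frac * max(d$y))
}

#' @export
print.density_pair <- function(x, ...) {
  cat("Likelihood densities for screen ", x$screen, ", timepoint ",
      x$timepoint, " (", x$n_ess, " essential / ", x$n_non,
      " nonessential training observations)\n", sep = "")
  invisible(x)
}

#' Tidy a density pair into grid form
#'
#' @param x A `"density_pair"`.
#' @param ... Unused.
#' @return Tibble: `fold_change`, `class` ("essential"/"nonessential"),
#'   `density`.
#' @export
tidy.density_pair <- function(x, ...) {
  tibble::tibble(
    fold_change = rep(x$grid, 2),
    class = rep(c("essential", "nonessential"), each = length(x$grid)),
    density = c(x$f_ess, x$f_non)
  )
}

#' Plot the trained likelihood densities of a screen timepoint
#'
#' @param object A `"density_pair"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.density_pair <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fold_change, y = .data$density,
                                   colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(object$bounds$lower, object$bounds$upper),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "log2 fold-change", y = "density",
                  title = paste0("Screen ", object$screen, ", timepoint ",
                                 object$timepoint)) +
    ggplot2::theme_minimal()
}

#' Log2 likelihood ratio of one fold-change observation
#'
#' Evaluates log2 Pr(x | essential) − log2 Pr(x | nonessential) after
#' clipping `x` into the truncation bounds; the densities are looked up by
#' linear interpolation on the training grid. Non-finite observations are
#' treated as missing and return `NA` (they contribute no term to a Bayes
#' Factor).
#'
#' @param x Numeric vector of log2 fold-changes.
#' @param d A `"density_pair"` from [fit_densities()].
#' @return Numeric vector of log2 likelihood ratios (`NA` where `x` is not
#'   finite).
#' @export
loglik_ratio <- function(x, d) {
  stopifnot(inherits(d, "density_pair"))
  out <- rep(NA_real_, length(x))
  ok <- is.finite(x)
  if (any(ok)) {
    xc <- clip_fc(x[ok], d$bounds)
    fe <- stats::approx(d$grid, d$f_ess, xout = xc)$y
    fn <- stats::approx(d$grid, d$f_non, xout = xc)$y
    out[ok] <- log2(fe) - log2(fn)
  }
  out
}
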