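#' Configuration of the screen-saturation sampling model
#'
#' The model treats each screen as reporting a fixed number of hit genes: a
#' fixed count of true positives drawn uniformly without replacement from an
#' essential population of size `n_essential`, and the remainder — a fixed
#' fraction `fdr` of the hits — drawn uniformly from the nonessential rest of
#' the genome. Per screen, t = round(hits_per_screen * (1 − fdr)) true and
#' f = hits_per_screen − t false hits. The defaults mirror a large shRNA
#' compendium: 15,687 genes assayed and 606 hits reported per screen.
#'
#' @param n_essential Size of the essential-gene population.
#' @param fdr Per-screen false discovery fraction in \[0, 1).
#' @param total_genes Genes assayed; default 15,687.
#' @param hits_per_screen Genes reported essential per screen; default 606.
#' @param n_screens Screens simulated; default 36.
#' @param n_reps Monte-Carlo repetitions; default 100.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_essential, fdr, total_genes = 15687,
                       hits_per_screen = 606, n_screens = 36, n_reps = 100) {
  if (fdr < 0 || fdr >= 1) rlang::abort("fdr must be in [0, 1)")
  if (n_essential > total_genes) {
    rlang::abort("n_essential cannot exceed total_genes")
  }
  t_hits <- round(hits_per_screen * (1 - fdr))
  if (t_hits > n_essential) {
    rlang::abort("true hits per screen exceed the essential population")
  }
  if (hits_per_screen - t_hits > total_genes - n_essential) {
    rlang::abort("false hits per screen exceed the nonessential population")
  }
  structure(list(n_essential = n_essential, fdr = fdr,
                 total_genes = total_genes, hits_per_screen = hits_per_screen,
                 n_screens = n_screens, n_reps = n_reps,
                 true_hits = t_hits, false_hits = hits_per_screen - t_hits),
            class = "sim_config")
}

#' Simulate cumulative unique-essential curves
#'
#' For each repetition, draws the per-screen true and false hit sets and
#' accumulates the running union of unique reported genes over screens
#' 1..n_screens.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A list of class `"cumulative_sim"`: `mean` (tibble `k`,
#'   `cumulative`), `reps` (tibble `rep`, `k`, `cumulative`), `config`.
#' @export
simulate_cumulative <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  ess <- seq_len(config$n_essential)
  non <- config$n_essential + seq_len(config$total_genes - config$n_essential)
  curves <- withr::with_seed(seed, {
    vapply(seq_len(config$n_reps), function(r) {
      seen <- logical(config$total_genes)
      out <- integer(config$n_screens)
      for (k in seq_len(config$n_screens)) {
        hits <- c(sample(ess, config$true_hits),
                  if (config$false_hits > 0) sample(non, config$false_hits))
        seen[hits] <- TRUE
        out[k] <- sum(seen)
      }
      out
    }, integer(config$n_screens))
  })
  curves <- matrix(curves, nrow = config$n_screens)
  reps <- tibble::tibble(
    rep = rep(seq_len(config$n_reps), each = config$n_screens),
    k = rep(seq_len(config$n_screens), times = config$n_reps),
    cumulative = as.vector(curves)
  )
  structure(list(
    mean = tibble::tibble(k = seq_len(config$n_screens),
                          cumulative = rowMeans(curves)),
    reps = reps, config = config
  ), class = "cumulative_sim")
}

#' Closed-form expectation of the cumulative unique-essential curve
#'
#' Each essential gene is missed by one screen with probability
#' 1 − t/E, independently across screens, so after k screens
#' E\[unique essentials\] = E (1 − (1 − t/E)^k); the false-positive pool
#' contributes (G − E)(1 − (1 − f/(G − E))^k) analogously. This is the exact
#' expectation of the sampling model and serves as the analytic oracle for
#' the Monte-Carlo simulation.
#'
#' @param config A [sim_config()].
#' @param k Screen indices; default 1..n_screens.
#' @return Tibble: `k`, `cumulative` (expected unique genes after k screens).
#' @export
expected_cumulative <- function(config, k = seq_len(config$n_screens)) {
  stopifnot(inherits(config, "sim_config"))
  e_pop <- config$n_essential
  n_pop <- config$total_genes - e_pop
  ess_part <- e_pop * (1 - (1 - config$true_hits / e_pop)^k)
  fp_part <- if (config$false_hits > 0) {
    n_pop * (1 - (1 - config$false_hits / n_pop)^k)
  } else 0
  tibble::tibble(k = k, cumulative = ess_part + fp_part)
}

#' Fit the saturation model to an observed cumulative curve
#'
#' Evaluates the model over a grid of (essential population size, per-screen
#' FDR) pairs, computing the root-mean-squared deviation (RMSD, unweighted
#' over all screens) between the observed curve and the model curve — the
#' closed-form expectation by default, or the mean of `n_reps` Monte-Carlo
#' repetitions. Reports the grid minimum and the confidence region of grid
#' points whose RMSD is below 1.5 times the minimum.
#'
#' @param observed Data frame with columns `k`, `cumulative` (one row per
#'   screen rank), or a bare numeric vector of cumulative counts.
#' @param ess_grid Candidate essential-population sizes.
#' @param fdr_grid Candidate per-screen FDR values.
#' @param total_genes,hits_per_screen Fixed model parameters.
#' @param use_expectation Use the closed form (default) instead of
#'   Monte-Carlo means.
#' @param n_reps,seed Monte-Carlo settings when `use_expectation = FALSE`.
#' @param region_factor Region includes grid points with
#'   RMSD < `region_factor` * min RMSD; default 1.5.
#' @return A list of class `"cumulative_fit"`: `grid` (tibble `n_essential`,
#'   `fdr`, `rmsd`, `in_region`), `best` (one-row tibble), `region_bounds`,
#'   `observed`.
#' @export
fit_cumulative <- function(observed, ess_grid = seq(500, 2000, by = 25),
                           fdr_grid = seq(0, 0.30, by = 0.005),
                           total_genes = 15687, hits_per_screen = 606,
                           use_expectation = TRUE, n_reps = 100, seed = 1L,
                           region_factor = 1.5) {
  if (is.numeric(observed) && is.null(dim(observed))) {
    observed <- tibble::tibble(k = seq_along(observed), cumulative = observed)
  }
  stopifnot(all(c("k", "cumulative") %in% names(observed)))
  if (length(ess_grid) == 0 || length(fdr_grid) == 0) {
    rlang::abort("empty parameter grid")
  }
  n_screens <- nrow(observed)
  grid <- tidyr::expand_grid(n_essential = ess_grid, fdr = fdr_grid)
  grid$rmsd <- purrr::map2_dbl(grid$n_essential, grid$fdr, function(e, f) {
    cfg <- tryCatch(
      sim_config(e, f, total_genes = total_genes,
                 hits_per_screen = hits_per_screen, n_screens = n_screens,
                 n_reps = n_reps),
      error = function(err) NULL)
    if (is.null(cfg)) return(Inf)  # infeasible corner of the grid
    model <- if (use_expectation) {
      expected_cumulative(cfg, k = observed$k)$cumulative
    } else {
      simulate_cumulative(cfg, seed = seed)$mean$cumulative[observed$k]
    }
    sqrt(mean((observed$cumulative - model)^2))
  })
  min_rmsd <- min(grid$rmsd)
  # strict 1.5x-minimum rule, but the argmin always belongs to the region
  # (relevant when the minimum RMSD is exactly 0)
  grid$in_region <- grid$rmsd < region_factor * min_rmsd | grid$rmsd == min_rmsd
  best <- grid[which.min(grid$rmsd), ]
  region <- grid[grid$in_region, ]
  structure(list(
    grid = grid, best = best,
    region_bounds = tibble::tibble(
      n_essential_min = min(region$n_essential),
      n_essential_max = max(region$n_essential),
      fdr_min = min(region$fdr), fdr_max = max(region$fdr)
    ),
    observed = tibble::as_tibble(observed)
  ), class = "cumulative_fit")
}

#' @export
print.cumulative_fit <- function(x, ...) {
  cat(sprintf(
    "Saturation fit: %d essential genes at %.1f%% per-screen FDR (RMSD %.2f)\n",
    x$best$n_essential, 100 * x$best$fdr, x$best$rmsd))
  cat(sprintf("1.5x-min region: %d-%d essentials, %.1f-%.1f%% FDR\n",
              x$region_bounds$n_essential_min, x$region_bounds$n_essential_max,
              100 * x$region_bounds$fdr_min, 100 * x$region_bounds$fdr_max))
  invisible(x)
}

#' Tidy the RMSD grid of a saturation fit
#'
#' @param x A `"cumulative_fit"`.
#' @param ... Unused.
#' @return The grid tibble: `n_essential`, `fdr`, `rmsd`, `in_region`.
#' @export
tidy.cumulative_fit <- function(x, ...) x$grid

#' One-row summary of a saturation fit
#'
#' @param x A `"cumulative_fit"`.
#' @param ... Unused.
#' @return Tibble with the best-fit point and region bounds.
#' @export
glance.cumulative_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n_essential = x$best$n_essential, fdr = x$best$fdr,
                   rmsd = x$best$rmsd),
    x$region_bounds
  )
}

#' Plot the RMSD landscape of a saturation fit
#'
#' @param object A `"cumulative_fit"`.
#' @param ... Unused.
#' @return A ggplot: RMSD heat map with the 1.5x-minimum region outlined and
#'   the best fit marked.
#' @export
autoplot.cumulative_fit <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = .data$n_essential, y = .data$fdr)) +
    ggplot2::geom_tile(ggplot2::aes(fill = log10(.data$rmsd))) +
    ggplot2::geom_point(data = object$grid[object$grid$in_region, ],
                        size = 0.3, colour = "white") +
    ggplot2::geom_point(data = object$best, colour = "red", size = 2) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "essential population size", y = "per-screen FDR",
                  fill = "log10 RMSD") +
    ggplot2::theme_minimal()
}
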