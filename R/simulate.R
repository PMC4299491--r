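#' Configuration of the synthetic screen compendium generator
#'
#' Emulates a pooled dropout compendium with known ground truth: effective
#' reagents targeting essential genes deplete (left-shifted log2
#' fold-changes, with later timepoints shifted further, as dropout deepens
#' with cell doublings), all other reagents fluctuate around zero, and a
#' small per-reagent off-target rate makes some nonessential-gene reagents
#' behave as if their target were essential — consistently across screens, as
#' seed-sequence artifacts do.
#'
#' @param n_genes Genes in the library; default 1200.
#' @param n_essential Truly essential genes; default 120 (about 10%, the
#'   usual background expectation).
#' @param reagents_per_gene Reagents targeting each gene; default 5.
#' @param replicates Replicates per timepoint; default 3.
#' @param timepoints Timepoints per screen; default 2.
#' @param essential_shift Mean log2 fold-change of an effective reagent of an
#'   essential gene at the final timepoint (quality 1); default −2.
#' @param reagent_efficacy_fraction Fraction of an essential gene's reagents
#'   that are effective; default 0.8.
#' @param noise_sd Observation noise SD; default 0.5.
#' @param offtarget_rate Probability that a nonessential gene's reagent
#'   behaves as essential; default 0.01.
#' @param screen_quality Per-screen multiplier on `essential_shift`; scalar
#'   or length-`n_screens` vector; default 1.
#' @param n_screens Screens in the compendium; default 4.
#' @return A list of class `"compendium_config"`.
#' @export
compendium_config <- function(n_genes = 1200, n_essential = 120,
                              reagents_per_gene = 5, replicates = 3,
                              timepoints = 2, essential_shift = -2,
                              reagent_efficacy_fraction = 0.8, noise_sd = 0.5,
                              offtarget_rate = 0.01, screen_quality = 1,
                              n_screens = 4) {
  if (n_essential <= 0 || n_essential >= n_genes) {
    rlang::abort("need 0 < n_essential < n_genes")
  }
  if (offtarget_rate < 0 || offtarget_rate >= 1) {
    rlang::abort("offtarget_rate must be in [0, 1)")
  }
  if (noise_sd <= 0) rlang::abort("noise_sd must be positive")
  if (length(screen_quality) == 1) {
    screen_quality <- rep(screen_quality, n_screens)
  }
  stopifnot(length(screen_quality) == n_screens)
  structure(list(n_genes = n_genes, n_essential = n_essential,
                 reagents_per_gene = reagents_per_gene,
                 replicates = replicates, timepoints = timepoints,
                 essential_shift = essential_shift,
                 reagent_efficacy_fraction = reagent_efficacy_fraction,
                 noise_sd = noise_sd, offtarget_rate = offtarget_rate,
                 screen_quality = screen_quality, n_screens = n_screens),
            class = "compendium_config")
}

#' Generate a synthetic screen compendium with ground truth
#'
#' Draws every reagent observation from the generative model described in
#' [compendium_config()]: a reagent flagged "behaves essential" (an effective
#' reagent of an essential gene, or an off-target reagent of a nonessential
#' gene) at screen *s*, timepoint *j* of *T* draws from
#' Normal(essential_shift × quality_s × j/T, noise_sd); every other reagent
#' draws from Normal(0, noise_sd). Fully seeded and reproducible.
#'
#' @param config A [compendium_config()].
#' @param seed Integer seed.
#' @return A list: `fold_changes` (a `"bf_fc"` tibble), `map` (reagent-to-gene
#'   tibble), `truth` (list of class `"screen_truth"`: `essentials`,
#'   `reagents` tibble with per-reagent `behaves_essential` flags, `screens`
#'   tibble with per-screen `quality`, and the `config`).
#' @export
simulate_compendium <- function(config, seed = 1L) {
  stopifnot(inherits(config, "compendium_config"))
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  essentials <- genes[seq_len(config$n_essential)]
  gene_col <- rep(genes, each = config$reagents_per_gene)
  map <- tibble::tibble(
    reagent = sprintf("%s_r%d", gene_col,
                      rep(seq_len(config$reagents_per_gene), config$n_genes)),
    gene = gene_col
  )
  n_eff <- round(config$reagent_efficacy_fraction * config$reagents_per_gene)

  screens <- sprintf("S%02d", seq_len(config$n_screens))
  ann <- tidyr::expand_grid(screen = screens,
                            timepoint = sprintf("T%d", seq_len(config$timepoints)),
                            replicate = seq_len(config$replicates))
  ann$sample <- sprintf("%s_%s_R%d", ann$screen, ann$timepoint, ann$replicate)
  ann <- ann[, c("sample", "screen", "timepoint", "replicate")]

  sim <- withr::with_seed(seed, {
    behaves <- vapply(seq_len(nrow(map)), function(i) {
      if (map$gene[i] %in% essentials) {
        # pick which of the gene's reagents are effective, at random per gene
        NA  # placeholder, filled below per gene
      } else {
        stats::runif(1) < config$offtarget_rate
      }
    }, logical(1))
    for (g in essentials) {
      idx <- which(map$gene == g)
      eff <- rep(FALSE, length(idx))
      if (n_eff > 0) eff[sample(length(idx), min(n_eff, length(idx)))] <- TRUE
      behaves[idx] <- eff
    }
    tp_frac <- as.integer(sub("T", "", ann$timepoint)) / config$timepoints
    quality <- config$screen_quality[match(ann$screen, screens)]
    mu <- outer(behaves, config$essential_shift * quality * tp_frac)
    values <- mu + stats::rnorm(length(mu), sd = config$noise_sd)
    list(behaves = behaves, values = values)
  })

  wide <- tibble::as_tibble(as.data.frame(sim$values))
  names(wide) <- ann$sample
  wide <- dplyr::bind_cols(tibble::tibble(reagent = map$reagent), wide)
  truth <- structure(list(
    essentials = essentials,
    reagents = tibble::tibble(reagent = map$reagent, gene = map$gene,
                              behaves_essential = sim$behaves),
    screens = tibble::tibble(screen = screens,
                             quality = config$screen_quality),
    config = config
  ), class = "screen_truth")
  list(fold_changes = fold_changes(wide, ann), map = map, truth = truth)
}

#' Generate an expression table consistent with planted essentiality
#'
#' Emulates the empirical relationship between expression level and
#' essentiality: per-gene mean log2 FPKM values are drawn from
#' Normal(`mu0`, `sigma`), and allocated to genes so that the probability a
#' value belongs to an essential gene follows odds proportional to
#' 2^(slope × expression) — making the binned log2(fraction essential)
#' versus mean-expression relation linear with the configured slope. A
#' configurable fraction of nonessential genes instead receives trace
#' expression (FPKM 0, so log2 FPKM far below −2); base means are drawn from
#' a normal left-truncated at −1, so only the injected trace genes fall below
#' the −2 trace threshold and trace-expression genes are nonessential by
#' construction.
#'
#' @param truth A `"screen_truth"` from [simulate_compendium()].
#' @param slope Target slope of log2(fraction essential) per log2 FPKM;
#'   default 0.5. Slope 0 gives a flat relation (random allocation).
#' @param mu0,sigma Mean and SD of the base expression distribution; defaults
#'   2 and 2 (log2 FPKM).
#' @param trace_fraction Fraction of nonessential genes given trace
#'   expression; default 0.1.
#' @param n_samples Samples (columns) in the table; default 4.
#' @param sample_sd Per-sample noise SD around the gene mean; default 0.25.
#' @param pseudocount Pseudocount of the resulting table; default 0.01.
#' @param seed Integer seed.
#' @return A `"bf_expr"` expression table.
#' @export
generate_expression <- function(truth, slope = 0.5, mu0 = 2, sigma = 2,
                                trace_fraction = 0.1, n_samples = 4,
                                sample_sd = 0.25, pseudocount = 0.01,
                                seed = 1L) {
  stopifnot(inherits(truth, "screen_truth"))
  genes <- unique(truth$reagents$gene)
  n <- length(genes)
  is_ess <- genes %in% truth$essentials
  n_ess <- sum(is_ess)

  withr::with_seed(seed, {
    # base expression from a normal left-truncated at -1 (inverse CDF), so
    # only the injected trace genes can fall below the -2 trace threshold
    x <- stats::qnorm(stats::runif(n, stats::pnorm(-1, mu0, sigma), 1),
                      mu0, sigma)
    if (slope == 0) {
      ess_idx <- sample(n, n_ess)
    } else {
      # calibrate c so that sum of p_i = min(1, c * 2^(slope*x_i)) equals the
      # essential count, making the binned fraction-essential relation
      # log2-linear with the configured slope; then draw labels Bernoulli(p_i)
      # and repair the count by random flips
      w <- 2^(slope * x)
      f <- function(lc) sum(pmin(1, exp(lc) * w)) - n_ess
      lc <- stats::uniroot(f, c(-80, 80))$root
      p <- pmin(1, exp(lc) * w)
      lab <- stats::runif(n) < p
      excess <- sum(lab) - n_ess
      if (excess > 0) lab[sample(which(lab), excess)] <- FALSE
      if (excess < 0) lab[sample(which(!lab), -excess)] <- TRUE
      ess_idx <- which(lab)
    }
    mean_expr <- numeric(n)
    mean_expr[is_ess] <- x[ess_idx]
    mean_expr[!is_ess] <- x[-ess_idx]
    non_idx <- which(!is_ess)
    n_trace <- floor(trace_fraction * length(non_idx))
    trace_idx <- if (n_trace > 0) sample(non_idx, n_trace) else integer()
    mean_expr[trace_idx] <- log2(pseudocount)  # FPKM 0
    vals <- matrix(mean_expr, n, n_samples) +
      stats::rnorm(n * n_samples, sd = sample_sd)
    fpkm <- pmax(2^vals - pseudocount, 0)
    df <- dplyr::bind_cols(tibble::tibble(gene = genes),
                           tibble::as_tibble(as.data.frame(fpkm)))
    names(df)[-1] <- sprintf("sample%d", seq_len(n_samples))
    expression_table(df, pseudocount = pseudocount)
  })
}

#' Reference sets from synthetic ground truth
#'
#' Convenience constructor for testing the classifier: the truth's essential
#' genes versus a seeded random draw of nonessential genes.
#'
#' @param truth A `"screen_truth"`.
#' @param n_nonessential Nonessential reference size; default equal to the
#'   essential set.
#' @param seed Integer seed for the nonessential draw.
#' @return A [reference_sets()] object.
#' @export
truth_reference_sets <- function(truth, n_nonessential = NULL, seed = 1L) {
  stopifnot(inherits(truth, "screen_truth"))
  genes <- unique(truth$reagents$gene)
  non <- setdiff(genes, truth$essentials)
  if (is.null(n_nonessential)) n_nonessential <- length(truth$essentials)
  n_nonessential <- min(n_nonessential, length(non))
  withr::with_seed(seed, {
    reference_sets(truth$essentials, sample(non, n_nonessential))
  })
}
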