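# Shared fixtures and independent oracles used across test files.

# tiny fold-change table: values[i, j] for reagents x samples
make_fc <- function(values, reagents, screens, timepoints, replicates) {
  wide <- tibble::as_tibble(as.data.frame(values))
  samples <- sprintf("smp%02d", seq_len(ncol(values)))
  names(wide) <- samples
  wide <- dplyr::bind_cols(tibble::tibble(reagent = reagents), wide)
  ann <- tibble::tibble(sample = samples, screen = screens,
                        timepoint = timepoints, replicate = replicates)
  fold_changes(wide, ann)
}

# density pair with exact closed-form normal likelihoods (no KDE involved)
make_normal_pair <- function(mu_e = -2, mu_n = 0, sd = 1,
                             bounds = truncation_bounds()) {
  grid <- seq(bounds$lower - 0.5, bounds$upper + 0.5, by = 0.01)
  structure(list(screen = "toy", timepoint = "T1", grid = grid,
                 f_ess = stats::dnorm(grid, mu_e, sd),
                 f_non = stats::dnorm(grid, mu_n, sd),
                 bounds = bounds, n_ess = 0L, n_non = 0L),
            class = "density_pair")
}

# expression table where each gene has one sample at exactly the given
# log2(FPKM + pc) value
make_expr <- function(genes, log2_values, pseudocount = 0.01, n_samples = 1) {
  fpkm <- 2^log2_values - pseudocount
  df <- tibble::tibble(gene = genes)
  for (j in seq_len(n_samples)) df[[paste0("s", j)]] <- fpkm
  expression_table(df, pseudocount = pseudocount)
}

# oracle: upper-tail hypergeometric P(X >= k) by exhaustive enumeration of
# all C(N, n) draws of n reagents from N with m marked
hyper_tail_enum <- function(k, m, N, n) {
  draws <- utils::combn(N, n)
  marked <- seq_len(m)  # which reagents are "successes" is arbitrary
  mean(apply(draws, 2, function(d) sum(d %in% marked) >= k))
}

# oracle: naive Benjamini-Hochberg (sort, scale by N/rank, enforce monotone)
bh_naive <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# oracle: PR curve by brute-force threshold sweep over the test sets
pr_bruteforce <- function(scores, test) {
  x <- scores[scores$gene %in% c(test$essentials, test$nonessentials), ]
  x <- x[order(-x$score, x$gene), ]
  n_ess <- sum(x$gene %in% test$essentials)
  do.call(rbind, lapply(seq_len(nrow(x)), function(i) {
    top <- x$gene[seq_len(i)]
    tp <- sum(top %in% test$essentials)
    fp <- sum(top %in% test$nonessentials)
    data.frame(gene = x$gene[i], tp = tp, fp = fp,
               recall = tp / n_ess, precision = tp / (tp + fp))
  }))
}
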