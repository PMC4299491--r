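test_that("fitted densities honour mode, accuracy, and floor contracts", {
  # 600 essential-reagent obs all at -2, 600 nonessential at 0
  n <- 600
  vals <- matrix(c(rep(-2, n), rep(0, n)), ncol = 1)
  fc <- make_fc(vals, sprintf("r%04d", seq_len(2 * n)), screens = "A",
                timepoints = "T1", replicates = 1L)
  map <- reagent_map(data.frame(reagent = sprintf("r%04d", seq_len(2 * n)),
                                gene = rep(c("E", "N"), each = n)))
  train <- reference_sets("E", "N")
  d <- fit_densities(fc, map, train, "A", "T1")
  # point mass smoothed: density maximum at the training value
  expect_equal(d$grid[which.max(d$f_ess)], -2, tolerance = 0.011)
  expect_equal(d$grid[which.max(d$f_non)], 0, tolerance = 0.011)
  # floor contract: density at the lower bound is positive even with no
  # training observation near -4
  expect_gt(d$f_non[which.min(abs(d$grid - (-4)))], 0)
  # each density integrates to ~1 over the grid before flooring dominates
  expect_equal(sum(d$f_ess) * 0.01, 1, tolerance = 0.01)
  expect_equal(sum(d$f_non) * 0.01, 1, tolerance = 0.01)

  expect_error(fit_densities(fc, map, train, "A", "T1", min_obs = 1000),
               "training")
})

test_that("KDE approximates a known sampling density", {
  set.seed(31)
  n <- 10000
  x <- rnorm(n)
  fc <- make_fc(matrix(c(x, x), ncol = 1),
                sprintf("r%05d", seq_len(2 * n)), screens = "A",
                timepoints = "T1", replicates = 1L)
  map <- reagent_map(data.frame(reagent = sprintf("r%05d", seq_len(2 * n)),
                                gene = rep(c("E", "N"), each = n)))
  wide <- truncation_bounds(-5, 5)  # bounds that clip (almost) nothing
  d <- fit_densities(fc, map, reference_sets("E", "N"), "A", "T1",
                     bounds = wide)
  expect_lt(max(abs(d$f_ess - dnorm(d$grid))), 0.05)
})

test_that("log-likelihood ratios follow closed-form normal densities", {
  d <- make_normal_pair(mu_e = -2, mu_n = 0, sd = 1)
  # equidistant point: ratio 0
  expect_equal(loglik_ratio(-1, d), 0, tolerance = 1e-9)
  # x = -2: 2 nats = 2/log(2) log2 units
  expect_equal(loglik_ratio(-2, d), 2 / log(2), tolerance = 1e-6)
  # truncation: x beyond the lower bound scores exactly as the bound
  expect_identical(loglik_ratio(-6, d), loglik_ratio(-4, d))
  expect_identical(loglik_ratio(9, d), loglik_ratio(0.5, d))
  # non-finite observations yield no term
  expect_true(is.na(loglik_ratio(NA_real_, d)))
  expect_true(is.na(loglik_ratio(Inf, d)))
})

test_that("gene Bayes Factors sum the expected number of terms", {
  # 5 reagents x 3 replicates x 2 timepoints -> 15 terms per timepoint
  set.seed(41)
  n_samples <- 6
  vals <- matrix(rnorm(5 * n_samples, -1), 5, n_samples)
  fc <- make_fc(vals, sprintf("r%d", 1:5),
                screens = rep("A", 6),
                timepoints = rep(c("T1", "T2"), each = 3),
                replicates = rep(1:3, 2))
  map <- reagent_map(data.frame(reagent = sprintf("r%d", 1:5), gene = "G"))
  dens <- list(T1 = make_normal_pair(), T2 = make_normal_pair(-3, 0, 1))
  res <- gene_bayes_factor("G", fc, map, dens)
  expect_equal(res$n_obs, 30)
  per_tp <- tibble::as_tibble(fc) |> dplyr::count(timepoint)
  expect_equal(per_tp$n, c(15, 15))

  # brute-force oracle: sum of individually computed log-ratios
  brute <- sum(vapply(seq_len(nrow(fc)), function(i) {
    loglik_ratio(fc$fold_change[i], dens[[fc$timepoint[i]]])
  }, numeric(1)))
  expect_equal(res$bf, brute, tolerance = 1e-12)

  # all observations at the symmetric point -> BF exactly 0
  fc0 <- make_fc(matrix(-1, 5, 6), sprintf("r%d", 1:5),
                 screens = rep("A", 6),
                 timepoints = rep(c("T1", "T2"), each = 3),
                 replicates = rep(1:3, 2))
  res0 <- gene_bayes_factor("G", fc0, map,
                            list(T1 = make_normal_pair(),
                                 T2 = make_normal_pair()))
  expect_equal(res0$bf, 0, tolerance = 1e-9)
})

test_that("BF is additive over disjoint observation subsets and clip-invariant", {
  set.seed(43)
  vals <- matrix(rnorm(12, -2, 2), 3, 4)
  fc <- make_fc(vals, sprintf("r%d", 1:3), screens = rep("A", 4),
                timepoints = rep(c("T1", "T2"), 2), replicates = c(1, 1, 2, 2))
  map <- reagent_map(data.frame(reagent = sprintf("r%d", 1:3), gene = "G"))
  dens <- list(T1 = make_normal_pair(), T2 = make_normal_pair())

  whole <- gene_bayes_factor("G", fc, map, dens)
  part1 <- gene_bayes_factor("G", dplyr::filter(fc, replicate == 1), map, dens)
  part2 <- gene_bayes_factor("G", dplyr::filter(fc, replicate == 2), map, dens)
  expect_equal(whole$bf, part1$bf + part2$bf, tolerance = 1e-12)

  # clipping: replacing out-of-bounds observations with the bound is a no-op
  vals2 <- vals; vals2[1, 1] <- -9; vals2[2, 2] <- 2
  vals3 <- vals; vals3[1, 1] <- -4; vals3[2, 2] <- 0.5
  fc2 <- make_fc(vals2, sprintf("r%d", 1:3), screens = rep("A", 4),
                 timepoints = rep(c("T1", "T2"), 2), replicates = c(1, 1, 2, 2))
  fc3 <- make_fc(vals3, sprintf("r%d", 1:3), screens = rep("A", 4),
                 timepoints = rep(c("T1", "T2"), 2), replicates = c(1, 1, 2, 2))
  expect_equal(gene_bayes_factor("G", fc2, map, dens)$bf,
               gene_bayes_factor("G", fc3, map, dens)$bf, tolerance = 1e-12)
})

test_that("lowering an observation never decreases BF under monotone densities", {
  d <- make_normal_pair(mu_e = -2, mu_n = 0, sd = 1)  # ratio decreasing in x
  xs <- seq(-5, 1, by = 0.25)
  llr <- loglik_ratio(xs, d)
  expect_true(all(diff(llr) <= 1e-9))
})

test_that("priors convert BF to LOD as stated", {
  expect_equal(apply_prior(5, uniform_prior(1)), 5)
  expect_equal(apply_prior(5, uniform_prior(0.1)), 5 + log2(0.1),
               tolerance = 1e-12)
  expect_equal(apply_prior(5, uniform_prior(0.1)), 1.678, tolerance = 5e-4)
  expect_equal(round(log2(0.1), 2), -3.32)
  expect_error(uniform_prior(0), "positive")
  expect_error(uniform_prior(-1), "positive")
})

test_that("expression prior fit matches constructed bin relations", {
  # constant fraction f in every qualifying bin -> slope 0, intercept log2(f + pc)
  bs <- 10
  means <- c(6, 5, 4, 3, 2)
  genes <- sprintf("g%03d", seq_len(bs * length(means)))
  expr_vals <- rep(means, each = bs)
  e <- make_expr(genes, expr_vals)
  ess <- genes[rep(seq(0, length(means) - 1) * bs, each = 2) + c(1, 2)]
  m <- fit_expression_prior(e, ess, bin_size = bs)
  expect_equal(m$slope, 0, tolerance = 1e-9)
  expect_equal(m$intercept, log2(0.2 + 0.001), tolerance = 1e-9)

  # bins constructed with log2(fraction + pc) = 0.5 * mean - 6 exactly
  ks <- c(1, 2, 4, 8)
  bin_means <- (log2(ks / bs + 0.001) + 6) / 0.5
  genes2 <- sprintf("h%03d", seq_len(bs * length(ks)))
  e2 <- make_expr(genes2, rep(bin_means, each = bs))
  ess2 <- unlist(lapply(seq_along(ks), function(i) {
    genes2[(i - 1) * bs + seq_len(ks[i])]
  }))
  m2 <- fit_expression_prior(e2, ess2, bin_size = bs)
  expect_equal(m2$slope, 0.5, tolerance = 1e-9)
  expect_equal(m2$intercept, -6, tolerance = 1e-9)

  # a bin with mean expression 0.5 is excluded and does not move the fit
  genes3 <- sprintf("x%03d", seq_len(bs))
  e3 <- make_expr(c(genes2, genes3), c(rep(bin_means, each = bs), rep(0.5, bs)))
  m3 <- fit_expression_prior(e3, ess2, bin_size = bs)
  expect_equal(m3$slope, m2$slope, tolerance = 1e-9)
  expect_equal(m3$intercept, m2$intercept, tolerance = 1e-9)
  expect_false(m3$bins$in_fit[m3$bins$mean_expression < 1])

  expect_error(fit_expression_prior(e, c("nope"), bin_size = bs), "essential")
})

test_that("emitted expression priors are clamped into [floor, 0]", {
  m <- structure(list(slope = 0.5, intercept = -6, floor = log2(0.001),
                      cap = 0, pseudocount = 0.001,
                      bins = tibble::tibble(in_fit = TRUE)),
                 class = "expr_prior")
  expect_equal(expression_prior_for_gene(m, 4), -4)
  expect_equal(expression_prior_for_gene(m, 100), 0)           # cap
  expect_equal(expression_prior_for_gene(m, -100), log2(0.001)) # floor
  expect_equal(round(log2(0.001), 2), -9.97)
})

test_that("run_screen separates planted essentials and is deterministic", {
  cfg <- compendium_config(n_genes = 300, n_essential = 30, n_screens = 1)
  sim <- simulate_compendium(cfg, seed = 8)
  refs <- truth_reference_sets(sim$truth, n_nonessential = 30, seed = 2)
  split <- split_reference_sets(refs, seed = 3)
  bf <- run_screen(sim$fold_changes, sim$map, split, "S01", min_obs = 20)
  scored_ess <- bf$bf[bf$gene %in% sim$truth$essentials]
  scored_non <- bf$bf[!bf$gene %in% sim$truth$essentials]
  expect_gt(median(scored_ess), median(scored_non))
  # train genes never scored in their own run
  expect_length(intersect(bf$gene, c(split$train$essentials,
                                     split$train$nonessentials)), 0)
  # determinism
  bf2 <- run_screen(sim$fold_changes, sim$map, split, "S01", min_obs = 20)
  expect_identical(bf, bf2)
  expect_error(run_screen(sim$fold_changes, sim$map, split, "S99"),
               "screen")
})

test_that("identical training distributions give near-zero BFs", {
  set.seed(55)
  n_reag <- 400
  vals <- matrix(rnorm(n_reag * 6, 0, 0.5), n_reag, 6)
  fc <- make_fc(vals, sprintf("r%03d", seq_len(n_reag)),
                screens = rep("A", 6), timepoints = rep(c("T1", "T2"), each = 3),
                replicates = rep(1:3, 2))
  genes <- sprintf("g%03d", seq_len(n_reag / 4))
  map <- reagent_map(data.frame(reagent = sprintf("r%03d", seq_len(n_reag)),
                                gene = rep(genes, each = 4)))
  refs <- reference_sets(genes[1:30], genes[31:60])
  split <- split_reference_sets(refs, seed = 1)
  bf <- run_screen(fc, map, split, "A", min_obs = 20)
  expect_lt(median(abs(bf$bf)), 2)
  expect_lt(max(abs(bf$bf)), 15)
})

test_that("run_compendium with a prior adds LOD = BF + log2 prior", {
  cfg <- compendium_config(n_genes = 200, n_essential = 20, n_screens = 2)
  sim <- simulate_compendium(cfg, seed = 12)
  refs <- truth_reference_sets(sim$truth, seed = 2)
  split <- split_reference_sets(refs, seed = 3)
  bf <- run_compendium(sim$fold_changes, sim$map, split,
                       prior = uniform_prior(0.1), min_obs = 10)
  expect_true(all(c("bf", "lod") %in% names(bf)))
  expect_equal(bf$lod, bf$bf + log2(0.1), tolerance = 1e-12)
  expect_setequal(unique(bf$screen), c("S01", "S02"))
})
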