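#' Singular value decomposition of a fold-change matrix
#'
#' Dropout screens share a dominant mode of variation: reagents targeting
#' genes that are essential in most lines drop out consistently, so the first
#' left singular vector (U1) of the reagent-by-sample fold-change matrix
#' separates consistently depleted reagents from the rest. Missing cells are
#' imputed as 0 (the neutral fold-change) for the decomposition only.
#'
#' The sign of a singular vector pair is arbitrary; here U1 is oriented so
#' that the sum of the first right-singular-vector entries is negative
#' (dropout samples project negatively), which makes consistently depleted
#' reagents project positively. If that sum is exactly zero the first nonzero
#' U1 entry is made positive.
#'
#' @param fc A `"bf_fc"` fold-change tibble with at least 2 reagents and 2
#'   samples.
#' @return A list of class `"fc_svd"`: `u` (reagent-by-component matrix), `d`
#'   (singular values, non-increasing), `v` (sample-by-component),
#'   `variance_fraction` (sigma_i^2 / sum sigma_j^2), `reagents`, `samples`.
#' @export
run_svd <- function(fc) {
  m <- fc_matrix(fc, impute = 0)
  if (nrow(m) < 2 || ncol(m) < 2) {
    rlang::abort("need at least 2 reagents and 2 samples for SVD")
  }
  if (stats::sd(as.vector(m)) == 0) {
    rlang::abort("fold-change matrix is constant: no variance to decompose")
  }
  s <- svd(m)
  # orient component 1: sum of right singular vector entries negative
  sv1 <- sum(s$v[, 1])
  flip <- if (sv1 > 0) {
    TRUE
  } else if (sv1 < 0) {
    FALSE
  } else {
    u1 <- s$u[, 1]
    nz <- u1[u1 != 0]
    length(nz) > 0 && nz[1] < 0
  }
  if (flip) {
    s$u[, 1] <- -s$u[, 1]
    s$v[, 1] <- -s$v[, 1]
  }
  structure(list(u = s$u, d = s$d, v = s$v,
                 variance_fraction = s$d^2 / sum(s$d^2),
                 reagents = rownames(m), samples = colnames(m)),
            class = "fc_svd")
}

#' @export
print.fc_svd <- function(x, ...) {
  cat("SVD of", length(x$reagents), "reagents x", length(x$samples),
      "samples; component 1 explains",
      sprintf("%.1f%%", 100 * x$variance_fraction[1]), "of variance\n")
  invisible(x)
}

#' Tidy the variance decomposition of an `fc_svd`
#'
#' @param x An `"fc_svd"` object.
#' @param ... Unused.
#' @return Tibble: `component`, `singular_value`, `variance_fraction`.
#' @export
tidy.fc_svd <- function(x, ...) {
  tibble::tibble(component = seq_along(x$d), singular_value = x$d,
                 variance_fraction = x$variance_fraction)
}

#' Project reagents onto the oriented first left singular vector
#'
#' The projection of reagent *r* is its oriented U1 component scaled by the
#' first singular value (sigma1 * U1\[r\]); scaling preserves the rank order
#' that the enrichment step uses. Consistently depleted reagents receive
#' large positive projections.
#'
#' @param svd_result An `"fc_svd"` from [run_svd()].
#' @return Tibble: `reagent`, `projection`.
#' @export
project_reagents <- function(svd_result) {
  stopifnot(inherits(svd_result, "fc_svd"))
  tibble::tibble(reagent = svd_result$reagents,
                 projection = svd_result$d[1] * svd_result$u[, 1])
}

#' Seed essential genes by hypergeometric enrichment of U1 projections
#'
#' For each gene, take the median projection *p* of its cognate reagents
#' (lower median for even counts, so the median reagent itself is counted).
#' With `N` total reagents, `m` of which have projection >= *p*, and `k` of
#' the gene's `n` reagents at or above *p* (k >= ceiling(n/2) by
#' construction), the enrichment p-value is the upper hypergeometric tail
#' P(X >= k) when drawing `n` reagents from `N` with `m` marked. P-values are
#' Benjamini-Hochberg adjusted across genes, and genes below the FDR
#' threshold are flagged as seed essentials. Single-reagent genes are scored
#' (n = 1, k = 1) but flagged low-confidence.
#'
#' @param projections Tibble with columns `reagent`, `projection` (from
#'   [project_reagents()]); every mapped reagent must be present.
#' @param map Reagent-to-gene tibble ([reagent_map()]).
#' @param fdr_threshold Adjusted p-value cutoff in (0, 1); default 0.25.
#' @return Tibble, one row per gene: `gene`, `n`, `p` (median projection),
#'   `m`, `k`, `p_value`, `adj_p`, `seed_essential`, `low_confidence`.
#' @export
seed_enrichment <- function(projections, map, fdr_threshold = 0.25) {
  stopifnot(is.data.frame(projections),
            all(c("reagent", "projection") %in% names(projections)))
  if (!is.numeric(fdr_threshold) || fdr_threshold <= 0 || fdr_threshold >= 1) {
    rlang::abort("fdr_threshold must be in (0, 1)")
  }
  unmatched <- setdiff(map$reagent, projections$reagent)
  if (length(unmatched) > 0) {
    rlang::abort(paste0("reagent(s) in map without projection: ",
                        paste(utils::head(unmatched, 5), collapse = ", ")))
  }
  proj <- projections$projection[match(map$reagent, projections$reagent)]
  all_proj <- proj
  n_total <- length(all_proj)

  res <- tibble::tibble(gene = map$gene, projection = proj) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n = dplyr::n(),
      p = lower_median(.data$projection),
      k = sum(.data$projection >= lower_median(.data$projection)),
      .groups = "drop"
    )
  res$m <- vapply(res$p, function(p) sum(all_proj >= p), integer(1))
  # upper tail P(X >= k) drawing n from N with m successes
  res$p_value <- stats::phyper(res$k - 1, res$m, n_total - res$m, res$n,
                               lower.tail = FALSE)
  res$adj_p <- stats::p.adjust(res$p_value, method = "BH")
  res$seed_essential <- res$adj_p < fdr_threshold
  res$low_confidence <- res$n == 1
  res[, c("gene", "n", "p", "m", "k", "p_value", "adj_p",
          "seed_essential", "low_confidence")]
}

# lower median: element at position ceiling(n/2) of the sorted vector,
# so at least ceiling(n/2) values are >= it
lower_median <- function(x) {
  sort(x)[ceiling(length(x) / 2)]
}
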