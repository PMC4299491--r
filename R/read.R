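#' Build a fold-change table from a matrix and sample annotations
#'
#' The central experimental input is a matrix of log2 fold-changes of
#' perturbation reagents (shRNA hairpins or gRNAs) across screen samples,
#' where each sample belongs to a screen (cell line), a timepoint, and a
#' replicate. `fold_changes()` validates the pieces and returns them in tidy
#' long form: one row per (reagent, sample) cell.
#'
#' Missing observations (empty cells or `NA` in the source file) are kept as
#' `NA` rows and are excluded from all downstream likelihood sums; they are
#' never imputed (the SVD step imputes 0 internally, see [run_svd()]).
#'
#' @param values Data frame whose first column holds reagent identifiers and
#'   whose remaining columns hold log2 fold-changes, one column per sample.
#' @param annotations Data frame with columns `sample`, `screen`, `timepoint`,
#'   `replicate` covering every sample column of `values`.
#' @return A tibble of class `"bf_fc"` with columns `reagent`, `sample`,
#'   `screen`, `timepoint`, `replicate`, `fold_change` (`NA` = missing).
#' @examples
#' vals <- data.frame(reagent = c("r1", "r2"), s1 = c(-2, 0), s2 = c(-1.5, 0.2))
#' ann <- data.frame(sample = c("s1", "s2"), screen = "A",
#'                   timepoint = c("T1", "T2"), replicate = 1L)
#' fold_changes(vals, ann)
#' @export
fold_changes <- function(values, annotations) {
  stopifnot(is.data.frame(values), ncol(values) >= 2, is.data.frame(annotations))
  values <- tibble::as_tibble(values)
  names(values)[1] <- "reagent"
  values$reagent <- as.character(values$reagent)

  dup <- unique(values$reagent[duplicated(values$reagent)])
  if (length(dup) > 0) {
    rlang::abort(paste0("duplicated reagent id(s): ", paste(dup, collapse = ", ")))
  }

  required <- c("sample", "screen", "timepoint", "replicate")
  missing_cols <- setdiff(required, names(annotations))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("annotation table lacks column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  annotations <- tibble::as_tibble(annotations)[required]
  annotations$sample <- as.character(annotations$sample)
  annotations$screen <- as.character(annotations$screen)
  annotations$timepoint <- as.character(annotations$timepoint)
  annotations$replicate <- as.integer(annotations$replicate)
  if (anyNA(annotations)) rlang::abort("annotations contain missing values")
  if (anyDuplicated(annotations$sample)) rlang::abort("duplicated sample annotation")

  data_samples <- names(values)[-1]
  absent <- setdiff(annotations$sample, data_samples)
  if (length(absent) > 0) {
    rlang::abort(paste0("annotated sample(s) absent from matrix: ",
                        paste(absent, collapse = ", ")))
  }
  unannotated <- setdiff(data_samples, annotations$sample)
  if (length(unannotated) > 0) {
    rlang::abort(paste0("sample(s) without annotation: ",
                        paste(unannotated, collapse = ", ")))
  }

  long <- tidyr::pivot_longer(values, -"reagent",
                              names_to = "sample", values_to = "fold_change")
  long$fold_change <- as.numeric(long$fold_change)
  bad <- !is.na(long$fold_change) & !is.finite(long$fold_change)
  if (any(bad)) rlang::abort("non-finite fold-change values present")

  out <- dplyr::inner_join(long, annotations, by = "sample")
  out <- out[, c("reagent", "sample", "screen", "timepoint", "replicate",
                 "fold_change")]
  class(out) <- c("bf_fc", class(tibble::tibble()))
  out
}

#' Read a fold-change matrix and its sample annotations
#'
#' Both files are tab-separated with one header row; lines starting with `#`
#' are comments. The matrix's first column holds reagent identifiers; the
#' annotation file has columns `sample`, `screen`, `timepoint`, `replicate`.
#' Empty cells or `NA` mark missing observations.
#'
#' @param path Path to the fold-change matrix (TSV).
#' @param annotation_path Path to the sample annotation table (TSV).
#' @return A `"bf_fc"` tibble; see [fold_changes()].
#' @export
read_fold_changes <- function(path, annotation_path) {
  values <- read_screen_tsv(path)
  ann <- read_screen_tsv(annotation_path)
  fold_changes(values, ann)
}

#' Write a fold-change table back to matrix + annotation TSV files
#'
#' Inverse of [read_fold_changes()]; values round-trip at full precision.
#'
#' @param fc A `"bf_fc"` tibble.
#' @param path,annotation_path Output file paths.
#' @return `fc`, invisibly.
#' @export
write_fold_changes <- function(fc, path, annotation_path) {
  stopifnot(inherits(fc, "bf_fc"))
  wide <- tidyr::pivot_wider(fc[, c("reagent", "sample", "fold_change")],
                             names_from = "sample", values_from = "fold_change")
  readr::write_tsv(wide, path, na = "NA")
  ann <- dplyr::distinct(fc[, c("sample", "screen", "timepoint", "replicate")])
  readr::write_tsv(ann, annotation_path)
  invisible(fc)
}

#' Spread a fold-change table into a reagent-by-sample matrix
#'
#' @param fc A `"bf_fc"` tibble.
#' @param impute Value substituted for missing cells (`NA` keeps them missing).
#' @return A numeric matrix, rows named by reagent, columns by sample.
#' @export
fc_matrix <- function(fc, impute = NA_real_) {
  stopifnot(inherits(fc, "bf_fc"))
  wide <- tidyr::pivot_wider(fc[, c("reagent", "sample", "fold_change")],
                             names_from = "sample", values_from = "fold_change")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$reagent
  if (!is.na(impute)) m[is.na(m)] <- impute
  m
}

#' Sample annotations of a fold-change table
#'
#' @param fc A `"bf_fc"` tibble.
#' @return Tibble with one row per sample: `sample`, `screen`, `timepoint`,
#'   `replicate`.
#' @export
fc_samples <- function(fc) {
  stopifnot(inherits(fc, "bf_fc"))
  dplyr::distinct(tibble::as_tibble(fc)[, c("sample", "screen", "timepoint",
                                            "replicate")])
}

#' Read a reagent-to-gene map
#'
#' Two-column TSV (`reagent`, `gene`); every reagent maps to exactly one gene,
#' many reagents per gene.
#'
#' @param path Path to the map (TSV).
#' @return A tibble with columns `reagent`, `gene`.
#' @export
read_reagent_map <- function(path) {
  reagent_map(read_screen_tsv(path))
}

#' Validate a reagent-to-gene map given as a data frame
#'
#' @param df Data frame whose first two columns are reagent and gene ids.
#' @return A validated tibble with columns `reagent`, `gene`.
#' @export
reagent_map <- function(df) {
  stopifnot(is.data.frame(df), ncol(df) >= 2)
  if (nrow(df) == 0) rlang::abort("no mappings: reagent map is empty")
  map <- tibble::tibble(reagent = as.character(df[[1]]),
                        gene = as.character(df[[2]]))
  conflict <- map |>
    dplyr::distinct() |>
    dplyr::count(.data$reagent) |>
    dplyr::filter(.data$n > 1)
  if (nrow(conflict) > 0) {
    rlang::abort(paste0("reagent(s) mapped to multiple genes: ",
                        paste(conflict$reagent, collapse = ", ")))
  }
  dplyr::distinct(map)
}

#' Summarise a reagent map
#'
#' @param map Tibble from [reagent_map()].
#' @return Tibble with one row per reagents-per-gene count: `n_reagents`,
#'   `n_genes`.
#' @export
map_summary <- function(map) {
  map |>
    dplyr::count(.data$gene, name = "n_reagents") |>
    dplyr::count(.data$n_reagents, name = "n_genes")
}

#' Read a plain-text gene list (one gene per line)
#'
#' @param path Path to the list; `#` lines are comments.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  x <- readr::read_lines(path)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read a gene expression table in FPKM
#'
#' The source table is gene-by-sample FPKM (TSV, first column = gene id).
#' Values are log-transformed on read as `log2(FPKM + pseudocount)`.
#'
#' @param path Path to the FPKM table (TSV).
#' @param pseudocount Positive pseudocount added before the log; default 0.01.
#' @return An `"bf_expr"` tibble; see [expression_table()].
#' @export
read_expression <- function(path, pseudocount = 0.01) {
  expression_table(read_screen_tsv(path), pseudocount = pseudocount)
}

#' Build an expression table from a gene-by-sample FPKM data frame
#'
#' @param df Data frame: first column gene ids, remaining columns FPKM values
#'   per sample.
#' @param pseudocount Positive pseudocount for the log transform.
#' @return A tibble of class `"bf_expr"` with columns `gene`, `sample`,
#'   `fpkm`, `log2_fpkm` and a `pseudocount` attribute.
#' @export
expression_table <- function(df, pseudocount = 0.01) {
  stopifnot(is.data.frame(df), ncol(df) >= 2)
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount <= 0) {
    rlang::abort("pseudocount must be a positive scalar")
  }
  df <- tibble::as_tibble(df)
  names(df)[1] <- "gene"
  df$gene <- as.character(df$gene)
  if (anyDuplicated(df$gene)) rlang::abort("duplicated gene id in expression table")
  long <- tidyr::pivot_longer(df, -"gene", names_to = "sample",
                              values_to = "fpkm")
  long$fpkm <- as.numeric(long$fpkm)
  long$log2_fpkm <- log2(long$fpkm + pseudocount)
  attr(long, "pseudocount") <- pseudocount
  class(long) <- c("bf_expr", class(tibble::tibble()))
  long
}

#' Per-gene expression summaries
#'
#' Mean and standard deviation of `log2(FPKM + pseudocount)` per gene over a
#' sample subset.
#'
#' @param expr A `"bf_expr"` tibble.
#' @param samples Optional character vector of samples to restrict to.
#' @return Tibble: `gene`, `mean_log2`, `sd_log2`, `n_samples`.
#' @export
expression_summary <- function(expr, samples = NULL) {
  stopifnot(inherits(expr, "bf_expr"))
  x <- tibble::as_tibble(expr)
  if (!is.null(samples)) x <- dplyr::filter(x, .data$sample %in% samples)
  x |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(mean_log2 = mean(.data$log2_fpkm),
                     sd_log2 = stats::sd(.data$log2_fpkm),
                     n_samples = dplyr::n(), .groups = "drop")
}

#' Quantile-normalize an expression table
#'
#' Forces every sample (column) to the same empirical distribution: the
#' reference distribution is the row-wise mean of the per-sample sorted
#' log2-expression vectors, and each sample's values are replaced by the
#' reference value at their within-sample rank. Tied values receive the mean
#' of the reference values across their tied ranks, so the map is well defined
#' and idempotent. FPKM values are back-transformed from the normalized log2
#' scale.
#'
#' @param expr A complete (no missing values) `"bf_expr"` tibble with at least
#'   two samples.
#' @return A quantile-normalized `"bf_expr"` tibble.
#' @export
quantile_normalize <- function(expr) {
  stopifnot(inherits(expr, "bf_expr"))
  pc <- attr(expr, "pseudocount")
  wide <- tidyr::pivot_wider(tibble::as_tibble(expr)[, c("gene", "sample", "log2_fpkm")],
                             names_from = "sample", values_from = "log2_fpkm")
  m <- as.matrix(wide[, -1, drop = FALSE])
  if (ncol(m) < 2) rlang::abort("quantile normalization needs at least 2 samples")
  if (anyNA(m)) rlang::abort("expression table has missing values; cannot normalize")
  ref <- rowMeans(apply(m, 2, sort))
  norm <- apply(m, 2, function(x) {
    out <- ref[rank(x, ties.method = "first")]
    stats::ave(out, match(x, x), FUN = mean)  # mean of reference values over tied ranks
  })
  long <- tibble::tibble(
    gene = rep(wide$gene, each = ncol(m)),
    sample = rep(colnames(m), times = nrow(m)),
    log2_fpkm = as.vector(t(norm))
  )
  long$fpkm <- pmax(2^long$log2_fpkm - pc, 0)
  long <- long[, c("gene", "sample", "fpkm", "log2_fpkm")]
  attr(long, "pseudocount") <- pc
  class(long) <- c("bf_expr", class(tibble::tibble()))
  long
}

# Shared TSV dialect: tab-separated, one header row, '#' comments,
# "" or "NA" for missing.
read_screen_tsv <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  readr::read_tsv(path, comment = "#", na = c("", "NA"),
                  show_col_types = FALSE, progress = FALSE)
}
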