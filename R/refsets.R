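#' Gold-standard reference gene sets
#'
#' A pair of disjoint gene sets — known essentials and known nonessentials —
#' used to train the fold-change likelihoods and to evaluate screens.
#'
#' @param essentials Character vector of essential gene ids.
#' @param nonessentials Character vector of nonessential gene ids.
#' @return A list of class `"reference_sets"` with elements `essentials` and
#'   `nonessentials` (both unique character vectors).
#' @examples
#' reference_sets(c("RPL3", "PSMA1"), c("OR1A1", "TAS2R1"))
#' @export
reference_sets <- function(essentials, nonessentials) {
  essentials <- unique(as.character(essentials))
  nonessentials <- unique(as.character(nonessentials))
  overlap <- intersect(essentials, nonessentials)
  if (length(overlap) > 0) {
    rlang::abort(paste0("reference sets overlap: ",
                        paste(utils::head(overlap, 5), collapse = ", ")))
  }
  structure(list(essentials = essentials, nonessentials = nonessentials),
            class = "reference_sets")
}

#' @export
print.reference_sets <- function(x, ...) {
  cat("Reference sets:", length(x$essentials), "essentials,",
      length(x$nonessentials), "nonessentials\n")
  invisible(x)
}

#' Split reference sets into equal-sized training and testing halves
#'
#' Each set is shuffled with a seeded uniform permutation and assigned
#' alternately to train and test; when the count is odd the training half gets
#' the extra gene. The same seed always yields the same split, and train/test
#' partition the input exactly.
#'
#' @param refs A [reference_sets()] object; both sets must have at least two
#'   genes.
#' @param seed Integer seed making the split reproducible.
#' @return A list of class `"reference_split"` with elements `train`, `test`
#'   (both `"reference_sets"`) and `seed`.
#' @export
split_reference_sets <- function(refs, seed = 1L) {
  stopifnot(inherits(refs, "reference_sets"))
  halve <- function(x, label) {
    if (length(x) < 2) {
      rlang::abort(paste0("cannot split ", label, ": fewer than 2 genes"))
    }
    perm <- sample(x)
    idx <- seq_along(perm)
    list(train = perm[idx %% 2 == 1], test = perm[idx %% 2 == 0])
  }
  withr::with_seed(seed, {
    e <- halve(refs$essentials, "essentials")
    n <- halve(refs$nonessentials, "nonessentials")
  })
  structure(list(train = reference_sets(e$train, n$train),
                 test = reference_sets(e$test, n$test),
                 seed = as.integer(seed)),
            class = "reference_split")
}

#' @export
print.reference_split <- function(x, ...) {
  cat("Reference split (seed ", x$seed, "):\n  train: ",
      length(x$train$essentials), " essentials / ",
      length(x$train$nonessentials), " nonessentials\n  test:  ",
      length(x$test$essentials), " essentials / ",
      length(x$test$nonessentials), " nonessentials\n", sep = "")
  invisible(x)
}

#' Swap the halves of a reference split
#'
#' Twofold cross-validation scores each half of the compendium with densities
#' trained on the other half's references; `swap_split()` gives the mirrored
#' split for the second fold.
#'
#' @param split A `"reference_split"`.
#' @return The split with `train` and `test` exchanged.
#' @export
swap_split <- function(split) {
  stopifnot(inherits(split, "reference_split"))
  structure(list(train = split$test, test = split$train, seed = split$seed),
            class = "reference_split")
}
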