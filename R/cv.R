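# Cross-validation layout: 5 subsets, subset 5 a fixed test set, subsets
# 1-4 rotating as validation across 4 folds; training images are the
# remaining 3 subsets (augmented), validation always uses originals.

#' Cross-validation layout
#'
#' @param n_subsets Number of subsets (5).
#' @param folds Number of folds (4): fold k validates on subset k and
#'   trains on the other non-test subsets.
#' @param test_count Images in the fixed test subset; default
#'   `round(n * 13/93)`, the study proportion.
#' @return An object of class `cv_layout`.
#' @export
cv_layout <- function(n_subsets = 5L, folds = 4L, test_count = NULL) {
  if (folds != n_subsets - 1L)
    stop_skullmark("invalid_config",
                   "layout expects folds == n_subsets - 1 (rotating validation)")
  structure(list(n_subsets = as.integer(n_subsets),
                 folds = as.integer(folds), test_count = test_count),
            class = "cv_layout")
}

#' Assign images to cross-validation folds
#'
#' Shuffles the images deterministically, sets aside the fixed test
#' subset, splits the remainder as evenly as possible into the
#' `n_subsets - 1` rotating subsets, and emits a manifest giving every
#' image's role in every fold.  Test images never appear in any train or
#' validation set.
#'
#' @param annotations Annotation data frame (one row per image).
#' @param layout A [cv_layout()].
#' @param seed Shuffling seed.
#' @return A list with `manifest` (data frame: `image_index`, `subset`,
#'   and one `fold_k` role column per fold) and `folds` (per fold, the
#'   integer indices of `train`, `val`, `test` images).
#' @export
make_cv_folds <- function(annotations, layout = cv_layout(), seed = 1L) {
  n <- nrow(annotations)
  if (is.null(n) || n < layout$n_subsets)
    stop_skullmark("split", sprintf("need at least %d images, got %d",
                                    layout$n_subsets, n))
  test_count <- layout$test_count
  if (is.null(test_count)) test_count <- round(n * 13 / 93)
  test_count <- max(1L, as.integer(test_count))
  rot <- layout$n_subsets - 1L
  if (n - test_count < rot)
    stop_skullmark("split", "too few images for the rotating subsets")

  perm <- with_seed(seed, sample.int(n))
  subset <- integer(n)
  subset[perm[seq_len(test_count)]] <- layout$n_subsets
  rest <- perm[(test_count + 1L):n]
  subset[rest] <- rep_len(seq_len(rot), length(rest))

  manifest <- data.frame(image_index = seq_len(n), subset = subset)
  folds <- vector("list", layout$folds)
  for (k in seq_len(layout$folds)) {
    role <- ifelse(subset == layout$n_subsets, "test",
                   ifelse(subset == k, "val", "train"))
    manifest[[paste0("fold_", k)]] <- role
    folds[[k]] <- list(train = which(role == "train"),
                       val = which(role == "val"),
                       test = which(role == "test"))
  }
  list(manifest = manifest, folds = folds, layout = layout)
}

#' Write a fold manifest to YAML
#'
#' @param cv Result of [make_cv_folds()].
#' @param path Output YAML path.
#' @export
write_cv_manifest <- function(cv, path) {
  out <- list(
    n_subsets = cv$layout$n_subsets,
    folds = lapply(seq_along(cv$folds), function(k) {
      f <- cv$folds[[k]]
      list(fold = k, train = f$train, val = f$val, test = f$test)
    }))
  yaml::write_yaml(out, path)
  invisible(path)
}
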