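# Ensemble consensus correction: patient-grouped fold assignment and the
# pixel-wise m-of-n agreement rule that proposes a refined label map from
# the predictions of models that saw the image during training.

#' Assign patients to cross-validation folds
#'
#' Shuffles the patient ids with a seeded stream and deals them round-robin
#' into `n_folds` folds, so folds partition the patients, fold sizes differ
#' by at most one, and no patient appears in two folds.
#'
#' @param patients Character vector of unique patient ids.
#' @param n_folds Number of folds (>= 2, <= number of patients).
#' @param seed Integer seed; the assignment is deterministic given the seed.
#' @return A `fold_assignment` object: list with `patient_to_fold` (named
#'   integer vector, folds indexed from 0) and `n_folds`.
#' @export
split_folds <- function(patients, n_folds, seed = 1L) {
  patients <- as.character(patients)
  if (length(patients) == 0L) stop("patients must be non-empty")
  if (anyDuplicated(patients)) {
    stop(sprintf("duplicate patient id: '%s'",
                 patients[duplicated(patients)][1]))
  }
  if (n_folds < 2L) stop("n_folds must be at least 2")
  if (n_folds > length(patients)) {
    stop(sprintf("cannot split %d patients into %d non-empty folds",
                 length(patients), n_folds))
  }
  perm <- with_seed(seed, sample(patients))
  assignment <- stats::setNames(
    rep_len(seq_len(n_folds) - 1L, length(perm)), perm
  )
  structure(list(patient_to_fold = assignment[patients],
                 n_folds = as.integer(n_folds)),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  sizes <- tabulate(x$patient_to_fold + 1L, nbins = x$n_folds)
  cat(sprintf("fold assignment: %d patients over %d folds (sizes %s)\n",
              length(x$patient_to_fold), x$n_folds,
              paste(sizes, collapse = "/")))
  invisible(x)
}

#' Bundle an original mask with ensemble predictions
#'
#' @param original The current (to-be-refined) label matrix.
#' @param predictions List of predicted label matrices, same shape as
#'   `original`.
#' @param m Agreement threshold: a class must be predicted by at least `m`
#'   members to overrule the original label. Requiring `m > n/2` guarantees
#'   the winning class is unique.
#' @return An `ensemble_set` object.
#' @export
ensemble_set <- function(original, predictions, m = 3L) {
  original <- validate_mask(original)
  if (!is.list(predictions) || length(predictions) < 1L) {
    stop("predictions must be a non-empty list of label matrices")
  }
  predictions <- lapply(predictions, validate_mask)
  same <- vapply(predictions, function(p) identical(dim(p), dim(original)),
                 logical(1))
  if (!all(same)) stop("all predictions must share the original's shape")
  n <- length(predictions)
  if (m < 1L || m > n) stop("m must be between 1 and the number of predictions")
  if (m <= n / 2) {
    stop(sprintf("m = %d with n = %d is ambiguous: require m > n/2 so at most one class can reach the threshold",
                 m, n))
  }
  structure(list(original = original, predictions = predictions,
                 m = as.integer(m)),
            class = "ensemble_set")
}

#' Pixel-wise consensus refinement
#'
#' For every pixel independently: if at least `m` of the `n` ensemble
#' predictions assign the same class, that class becomes the refined label;
#' otherwise the original label is kept. With the default 3-of-4 rule this
#' reproduces the cross-validation correction applied during dataset
#' refinement. Since `m > n/2`, at most one class can reach the threshold,
#' so the rule is unambiguous.
#'
#' @param ens An [ensemble_set()].
#' @return The refined label matrix, same shape as the original.
#' @export
consensus_refine <- function(ens) {
  stopifnot(inherits(ens, "ensemble_set"))
  preds <- ens$predictions
  best_count <- matrix(0L, nrow(ens$original), ncol(ens$original))
  best_class <- matrix(0L, nrow(ens$original), ncol(ens$original))
  for (cls in seg_classes) {
    votes <- Reduce(`+`, lapply(preds, function(p) p == cls))
    upd <- votes > best_count
    best_count[upd] <- votes[upd]
    best_class[upd] <- cls
  }
  out <- ens$original
  win <- best_count >= ens$m
  out[win] <- best_class[win]
  out
}

#' Tabulate label transitions between an original and a refined mask
#'
#' @param original,refined Label matrices of the same shape.
#' @return A 4 x 4 integer matrix of pixel counts, rows = original class,
#'   columns = refined class; the diagonal counts unchanged pixels and the
#'   total equals the pixel count.
#' @export
refinement_report <- function(original, refined) {
  original <- validate_mask(original)
  refined <- validate_mask(refined)
  if (!identical(dim(original), dim(refined))) {
    stop("original and refined masks must share one shape")
  }
  tab <- table(factor(original, levels = seg_classes),
               factor(refined, levels = seg_classes))
  m <- matrix(as.integer(tab), 4L, 4L,
              dimnames = list(from = names(seg_classes),
                              to = names(seg_classes)))
  m
}
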