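# Dice-coefficient evaluation per class and mean +/- sd aggregation over
# groups of images (e.g. per-hospital populations).

#' Dice coefficient for one class
#'
#' Computes `2|A n B| / (|A| + |B|)` over the pixel sets of class `cls` in
#' the two masks. When the class is absent from both masks the result is
#' governed by `empty_policy`: `"exclude"` (default) returns `NA` so the
#' slice contributes nothing for that class — crediting 1.0 would inflate
#' averages on apical/basal slices lacking trabeculae — while `"one"`
#' returns 1.
#'
#' @param a,b Label matrices of the same shape.
#' @param cls Class code in 0..3.
#' @param empty_policy `"exclude"` (default) or `"one"`.
#' @return Dice value in `[0, 1]`, or `NA` under the exclude policy when the
#'   class is absent from both masks.
#' @export
dice <- function(a, b, cls, empty_policy = c("exclude", "one")) {
  a <- validate_mask(a); b <- validate_mask(b)
  empty_policy <- match.arg(empty_policy)
  if (!identical(dim(a), dim(b))) stop("masks must share one shape")
  if (!(cls %in% seg_classes)) stop(sprintf("invalid class code %s", cls))
  in_a <- a == cls
  in_b <- b == cls
  na <- sum(in_a); nb <- sum(in_b)
  if (na + nb == 0L) {
    return(if (empty_policy == "one") 1 else NA_real_)
  }
  2 * sum(in_a & in_b) / (na + nb)
}

#' Per-class Dice report
#'
#' Dice for the three tissue classes EL, IC and TZ (background is excluded
#' from evaluation) plus their mean over the defined values.
#'
#' @inheritParams dice
#' @return A `dice_result`: list with `per_class` (named numeric, possibly
#'   `NA` under the exclude policy) and `average`.
#' @export
dice_report <- function(a, b, empty_policy = c("exclude", "one")) {
  empty_policy <- match.arg(empty_policy)
  per_class <- vapply(c("EL", "IC", "TZ"), function(nm) {
    dice(a, b, seg_classes[[nm]], empty_policy)
  }, numeric(1))
  structure(
    list(per_class = per_class,
         average = if (all(is.na(per_class))) NA_real_
                   else mean(per_class, na.rm = TRUE)),
    class = "dice_result"
  )
}

#' @export
print.dice_result <- function(x, digits = 3, ...) {
  vals <- format(round(c(x$per_class, average = x$average), digits))
  cat("Dice:", paste(names(vals), vals, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Aggregate Dice results by group
#'
#' Per group (e.g. population), the mean and standard deviation of every
#' Dice column over the images whose value is defined, in the mean +/- sd
#' layout used for reporting segmentation benchmarks. The standard deviation
#' uses the population form (divide by n); set `sample_sd = TRUE` for the
#' n - 1 form.
#'
#' @param results List of `dice_result` objects (from [dice_report()]).
#' @param groups Character vector of group labels, one per result.
#' @param sample_sd Use the sample (n - 1) standard deviation instead of the
#'   population form.
#' @return A data frame with one row per group: `group`, `n`, and
#'   `<col>_mean` / `<col>_sd` for EL, IC, TZ and average.
#' @export
aggregate_dice <- function(results, groups, sample_sd = FALSE) {
  if (length(results) == 0L) stop("results must be non-empty")
  if (length(groups) != length(results)) {
    stop("groups must have one label per result")
  }
  cols <- c("EL", "IC", "TZ", "average")
  mat <- t(vapply(results, function(r) {
    c(r$per_class[c("EL", "IC", "TZ")], average = r$average)
  }, numeric(4)))
  colnames(mat) <- cols
  out <- lapply(unique(groups), function(g) {
    sub <- mat[groups == g, , drop = FALSE]
    stats_g <- lapply(cols, function(cn) {
      v <- sub[, cn]
      v <- v[!is.na(v)]
      if (length(v) == 0L) return(c(NA_real_, NA_real_))
      mu <- mean(v)
      sd2 <- mean((v - mu)^2)
      if (sample_sd && length(v) > 1L) sd2 <- sd2 * length(v) / (length(v) - 1L)
      c(mu, sqrt(sd2))
    })
    row <- c(list(group = g, n = nrow(sub)),
             stats::setNames(unlist(stats_g),
                             as.vector(t(outer(cols, c("mean", "sd"),
                                               paste, sep = "_")))))
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
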