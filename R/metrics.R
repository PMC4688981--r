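#' Overlap similarity indices
#'
#' Voxel-count overlap between a gold-standard mask `A` and an automatic
#' segmentation `B` on a common grid:
#'
#' * Dice similarity coefficient `DSC = 2|A n B| / (|A| + |B|)` — linear in
#'   the overlapping volume, penalises false positives;
#' * Jaccard index `JI = |A n B| / |A u B|` — non-linear, penalises false
#'   positives more strongly;
#' * inclusion index `INI = |A n B| / |A|` — asymmetric (the first argument
#'   is the gold standard) and blind to false positives: any `B` covering
#'   `A` scores 1.
#'
#' All three lie in `[0, 1]` with 1 meaning perfect agreement (total
#' inclusion for INI), and satisfy `DSC = 2 JI / (1 + JI)`. Overlaps are
#' voxel counts: on a shared grid, physical-volume weighting would multiply
#' numerator and denominator by the same voxel volume and cancel.
#'
#' Masks that make a metric undefined raise an error rather than returning
#' 0, so that silent zeros cannot corrupt group means: both masks empty for
#' `dice`/`jaccard`, empty gold for `inclusion`.
#'
#' @param gold,auto [label_volume()] masks on identical grids; `gold` is the
#'   gold standard.
#' @return A number in `[0, 1]`; `score_pair()` returns an object of class
#'   `similarity_scores` with fields `dsc`, `ji`, `ini`.
#' @name overlap-metrics
#' @examples
#' a <- label_volume(array(c(1, 1, 1, 0), dim = c(4, 1, 1)))
#' b <- label_volume(array(c(0, 1, 1, 1), dim = c(4, 1, 1)))
#' dice(a, b)
#' jaccard(a, b)
#' inclusion(a, b)
NULL

overlap_counts <- function(gold, auto) {
  stopifnot(is_label_volume(gold), is_label_volume(auto))
  check_same_grid(list(gold, auto), "masks")
  list(a = sum(gold$voxels), b = sum(auto$voxels),
       ab = sum(gold$voxels & auto$voxels))
}

#' @rdname overlap-metrics
#' @export
dice <- function(gold, auto) {
  ov <- overlap_counts(gold, auto)
  if (ov$a + ov$b == 0L) {
    stop("Dice undefined: both masks are empty", call. = FALSE)
  }
  2 * ov$ab / (ov$a + ov$b)
}

#' @rdname overlap-metrics
#' @export
jaccard <- function(gold, auto) {
  ov <- overlap_counts(gold, auto)
  uni <- ov$a + ov$b - ov$ab
  if (uni == 0L) {
    stop("Jaccard undefined: both masks are empty", call. = FALSE)
  }
  ov$ab / uni
}

#' @rdname overlap-metrics
#' @export
inclusion <- function(gold, auto) {
  ov <- overlap_counts(gold, auto)
  if (ov$a == 0L) {
    stop("inclusion index undefined: gold-standard mask is empty",
         call. = FALSE)
  }
  ov$ab / ov$a
}

#' @rdname overlap-metrics
#' @export
score_pair <- function(gold, auto) {
  structure(
    list(dsc = dice(gold, auto), ji = jaccard(gold, auto),
         ini = inclusion(gold, auto)),
    class = "similarity_scores"
  )
}

#' @export
print.similarity_scores <- function(x, ...) {
  cat(sprintf("<similarity_scores> DSC %.4f  JI %.4f  INI %.4f\n",
              x$dsc, x$ji, x$ini))
  invisible(x)
}
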