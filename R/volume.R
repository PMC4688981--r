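#' Binary label volume on a regular 3D grid
#'
#' The basic container all overlap arithmetic runs on: a 3D binary voxel
#' array together with its grid geometry. The axis convention is fixed
#' throughout the package: axis 1 = right-left, axis 2 = anterior-posterior,
#' axis 3 = superior-inferior (an LPS-like frame). The mm coordinate of the
#' centre of voxel `(i, j, k)` is `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param voxels 3D array; values are coerced to 0/1 (logical or 0/1 numeric
#'   accepted).
#' @param spacing Per-axis voxel size in mm (length 1 or 3, all > 0).
#' @param origin mm coordinate of the centre of voxel (1, 1, 1). Length 3.
#' @param frame Axis-convention tag, default `"LPS"`.
#'
#' @return An object of class `label_volume` with fields `voxels`
#'   (integer 0/1 array), `spacing_mm`, `origin_mm` and `frame`.
#' @export
#' @examples
#' v <- label_volume(array(c(1, 0, 0, 1), dim = c(2, 2, 1)), spacing = 2)
#' mask_volume_voxels(v)
label_volume <- function(voxels, spacing = 1, origin = c(0, 0, 0),
                         frame = "LPS") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("`voxels` must be a 3D array", call. = FALSE)
  }
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 finite positive values (mm)", call. = FALSE)
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be 3 finite mm coordinates", call. = FALSE)
  }
  vox <- as.integer(voxels != 0)
  dim(vox) <- dim(voxels)
  structure(
    list(voxels = vox, spacing_mm = as.numeric(spacing),
         origin_mm = as.numeric(origin), frame = frame),
    class = "label_volume"
  )
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<label_volume> %d x %d x %d voxels, spacing %s mm, %d foreground (%s)\n",
    d[1], d[2], d[3], paste(format(x$spacing_mm), collapse = " x "),
    sum(x$voxels), x$frame
  ))
  invisible(x)
}

is_label_volume <- function(x) inherits(x, "label_volume")

#' Number of foreground voxels in a mask
#'
#' @param volume A [label_volume()].
#' @return Integer count of voxels equal to 1.
#' @export
mask_volume_voxels <- function(volume) {
  stopifnot(is_label_volume(volume))
  sum(volume$voxels)
}

# Error unless all volumes share dim, spacing, origin and frame.
check_same_grid <- function(volumes, what = "volumes") {
  ref <- volumes[[1L]]
  for (v in volumes[-1L]) {
    if (!identical(dim(v$voxels), dim(ref$voxels)) ||
        !isTRUE(all.equal(v$spacing_mm, ref$spacing_mm)) ||
        !isTRUE(all.equal(v$origin_mm, ref$origin_mm)) ||
        !identical(v$frame, ref$frame)) {
      stop("grid mismatch: all ", what,
           " must share dimensions, spacing, origin and frame",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

# Test whether the foreground of a mask forms one 26-connected component.
# Breadth-first flood fill over the 26-neighbourhood.
mask_is_connected <- function(volume) {
  stopifnot(is_label_volume(volume))
  d <- dim(volume$voxels)
  fg <- which(volume$voxels == 1L)
  if (length(fg) == 0L) return(FALSE)
  idx <- arrayInd(fg, d)
  key <- (idx[, 3] - 1L) * d[1] * d[2] + (idx[, 2] - 1L) * d[1] + idx[, 1]
  inmask <- logical(prod(d))
  inmask[key] <- TRUE
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  visited <- logical(prod(d))
  queue <- key[1L]
  visited[queue] <- TRUE
  n_seen <- 1L
  while (length(queue) > 0L) {
    cur <- arrayInd(queue, d)
    nxt <- integer(0)
    for (r in seq_len(nrow(offs))) {
      nb <- cur + matrix(offs[r, ], nrow(cur), 3, byrow = TRUE)
      ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] &
        nb[, 2] >= 1L & nb[, 2] <= d[2] &
        nb[, 3] >= 1L & nb[, 3] <= d[3]
      if (!any(ok)) next
      nbk <- (nb[ok, 3] - 1L) * d[1] * d[2] + (nb[ok, 2] - 1L) * d[1] + nb[ok, 1]
      nbk <- nbk[inmask[nbk] & !visited[nbk]]
      if (length(nbk)) {
        nbk <- unique(nbk)
        visited[nbk] <- TRUE
        n_seen <- n_seen + length(nbk)
        nxt <- c(nxt, nbk)
      }
    }
    queue <- nxt
  }
  n_seen == length(fg)
}

# Evaluate an expression under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
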