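#' STAPLE label fusion (binary EM)
#'
#' Simultaneous Truth and Performance Level Estimation: given J candidate
#' binary segmentations ("raters") of the same scene, estimate per-voxel
#' posterior probabilities `W_i` that the true label is foreground together
#' with each rater's sensitivity `p_j` and specificity `q_j`, by
#' expectation-maximisation.
#'
#' With decisions `D_ij` and foreground prior `f1`, one EM iteration is
#'
#' \deqn{a_i = f_1 \prod_j p_j^{D_{ij}} (1-p_j)^{1-D_{ij}}, \quad
#'       b_i = (1-f_1) \prod_j q_j^{1-D_{ij}} (1-q_j)^{D_{ij}}, \quad
#'       W_i = a_i / (a_i + b_i)}
#' \deqn{p_j = \sum_i W_i D_{ij} / \sum_i W_i, \quad
#'       q_j = \sum_i (1-W_i)(1-D_{ij}) / \sum_i (1-W_i)}
#'
#' Iterations stop when the largest absolute change in any `p_j` or `q_j`
#' drops below `tol`, or after `max_iter` iterations. The returned posterior
#' is the E-step map of the last iteration performed; the consensus mask
#' thresholds it at `threshold`. All probabilities are clamped to
#' `[1e-10, 1 - 1e-10]` to avoid division-by-zero degeneracies. For speed
#' the E/M sums are evaluated on the bounding box of the union of rater
#' foregrounds; voxels outside it, where every rater votes background, share
#' one posterior value that enters the M-step analytically, so the result is
#' identical to the full-grid computation.
#'
#' Degenerate inputs are well defined, not errors: all-empty raters give an
#' empty consensus, all-full raters a full one.
#'
#' @param raters List of [label_volume()] masks on identical grids (>= 1).
#' @param prior Foreground prior `f1`: a number in (0, 1), or `"auto"`
#'   (default) for the mean foreground fraction across raters.
#' @param tol Convergence tolerance on the rater parameters. Default 1e-6.
#' @param max_iter Maximum EM iterations. Default 100.
#' @param init_performance Initial value of every `p_j` and `q_j`
#'   (capped at 0.99999). Default 0.9.
#' @param threshold Posterior threshold defining the consensus. Default 0.5.
#' @param restrict Use the bounding-box computation (default `TRUE`);
#'   `FALSE` forces the equivalent full-grid evaluation.
#'
#' @return An object of class `fusion_result`: `consensus` (a
#'   [label_volume()]), `posterior` (3D array in `[0,1]`), `sensitivities`,
#'   `specificities`, `n_iterations`, `converged`.
#' @export
#' @examples
#' m <- label_volume(array(c(1, 1, 0, 0), dim = c(4, 1, 1)))
#' fr <- staple(list(m, m, m))
#' fr$sensitivities
staple <- function(raters, prior = "auto", tol = 1e-6, max_iter = 100L,
                   init_performance = 0.9, threshold = 0.5, restrict = TRUE) {
  if (length(raters) < 1L) stop("need at least one rater", call. = FALSE)
  stopifnot(all(vapply(raters, is_label_volume, logical(1))))
  check_same_grid(raters, "rater masks")
  if (max_iter < 1L) stop("`max_iter` must be >= 1", call. = FALSE)

  eps <- 1e-10
  clamp <- function(x) pmin(pmax(x, eps), 1 - eps)
  ref <- raters[[1L]]
  dims <- dim(ref$voxels)
  n_total <- prod(dims)
  J <- length(raters)

  # decisions as an n_total x J matrix
  D_full <- vapply(raters, function(r) as.numeric(r$voxels), numeric(n_total))
  dim(D_full) <- c(n_total, J)

  f1 <- if (identical(prior, "auto")) mean(D_full) else prior
  if (!is.numeric(f1) || length(f1) != 1L || f1 <= 0 || f1 >= 1) {
    if (!identical(prior, "auto")) {
      stop("numeric `prior` must lie strictly in (0, 1)", call. = FALSE)
    }
    f1 <- clamp(f1)
  }

  # bounding box of the union of foregrounds ("inside"); everything outside
  # is an all-background voxel handled analytically
  union_idx <- which(rowSums(D_full) > 0)
  if (restrict && length(union_idx) > 0L && length(union_idx) < n_total) {
    sub <- arrayInd(union_idx, dims)
    lo <- apply(sub, 2, min)
    hi <- apply(sub, 2, max)
    in_box <- array(FALSE, dims)
    in_box[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
    inside <- which(in_box)
  } else {
    inside <- seq_len(n_total)
  }
  D <- D_full[inside, , drop = FALSE]
  n_out <- n_total - length(inside)

  p <- rep(min(init_performance, 0.99999), J)
  q <- rep(min(init_performance, 0.99999), J)

  W <- NULL
  w_out <- 0
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    pc <- clamp(p); qc <- clamp(q)
    # E-step in log space: logit(W_i) = loga_i - logb_i
    loga <- log(f1) + drop(D %*% log(pc)) + drop((1 - D) %*% log(1 - pc))
    logb <- log(1 - f1) + drop((1 - D) %*% log(qc)) + drop(D %*% log(1 - qc))
    W <- 1 / (1 + exp(logb - loga))
    # shared posterior of an all-background voxel (outside the box)
    loga0 <- log(f1) + sum(log(1 - pc))
    logb0 <- log(1 - f1) + sum(log(qc))
    w_out <- 1 / (1 + exp(logb0 - loga0))
    # M-step over the full grid, outside voxels contributing analytically
    sw <- sum(W) + n_out * w_out
    sn <- sum(1 - W) + n_out * (1 - w_out)
    p_new <- drop(crossprod(D, W)) / max(sw, eps)
    q_new <- (drop(crossprod(1 - D, 1 - W)) + n_out * (1 - w_out)) /
      max(sn, eps)
    delta <- max(abs(p_new - p), abs(q_new - q))
    p <- p_new; q <- q_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }

  posterior <- array(w_out, dim = dims)
  posterior[inside] <- W
  consensus <- label_volume(array(as.integer(posterior >= threshold), dims),
                            spacing = ref$spacing_mm, origin = ref$origin_mm,
                            frame = ref$frame)
  structure(
    list(consensus = consensus, posterior = posterior,
         sensitivities = p, specificities = q,
         n_iterations = iter, converged = converged),
    class = "fusion_result"
  )
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf(
    "<fusion_result> %d raters, %d EM iterations (%s), %d consensus voxels\n",
    length(x$sensitivities), x$n_iterations,
    if (x$converged) "converged" else "not converged",
    sum(x$consensus$voxels)
  ))
  cat("  sensitivity:", format(round(x$sensitivities, 4)), "\n")
  cat("  specificity:", format(round(x$specificities, 4)), "\n")
  invisible(x)
}

#' Majority-vote label fusion
#'
#' A voxel is foreground iff strictly more than half the raters vote
#' foreground; exact ties (possible with an even rater count) are background.
#'
#' @param raters List of [label_volume()] masks on identical grids (>= 1).
#' @return A [label_volume()] consensus.
#' @export
majority_vote <- function(raters) {
  if (length(raters) < 1L) stop("need at least one rater", call. = FALSE)
  stopifnot(all(vapply(raters, is_label_volume, logical(1))))
  check_same_grid(raters, "rater masks")
  ref <- raters[[1L]]
  votes <- Reduce(`+`, lapply(raters, function(r) r$voxels))
  label_volume(array(as.integer(votes > length(raters) / 2), dim(ref$voxels)),
               spacing = ref$spacing_mm, origin = ref$origin_mm,
               frame = ref$frame)
}
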