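test_that("unanimous raters are a STAPLE fixed point", {
  m <- ball_mask()
  for (prior in list("auto", 0.3, 0.5)) {
    fr <- staple(list(m, m, m), prior = prior)
    expect_identical(fr$consensus$voxels, m$voxels)
    expect_true(all(fr$sensitivities > 1 - 1e-4))
    expect_true(fr$converged)
  }
})

test_that("degenerate rater sets give defined consensus, not errors", {
  zero <- lv(rep(0L, 27), c(3, 3, 3))
  fr <- staple(list(zero, zero, zero))
  expect_equal(sum(fr$consensus$voxels), 0)
  one <- lv(rep(1L, 27), c(3, 3, 3))
  fr <- staple(list(one, one))
  expect_equal(sum(fr$consensus$voxels), 27)
})

test_that("STAPLE is invariant under rater permutation", {
  set.seed(42)
  truth <- ball_mask()
  raters <- lapply(1:5, function(i) flip_noise_rater(truth, 0.08, seed = i))
  f1 <- staple(raters)
  f2 <- staple(rev(raters))
  expect_identical(f1$consensus$voxels, f2$consensus$voxels)
  expect_equal(f1$posterior, f2$posterior, tolerance = 1e-12)
  expect_equal(sort(round(f1$sensitivities, 10)),
               sort(round(f2$sensitivities, 10)))
  expect_equal(sort(round(f1$specificities, 10)),
               sort(round(f2$specificities, 10)))
})

test_that("posterior matches the brute-force EM oracle on a 5-rater grid", {
  # 3 x 3 x 1 grid, mixed votes, fixed prior 0.5, exactly 2 EM iterations
  set.seed(9)
  vecs <- lapply(1:5, function(i) as.integer(runif(9) < 0.5))
  raters <- lapply(vecs, function(v) lv(v, c(3, 3, 1)))
  fr <- staple(raters, prior = 0.5, tol = 0, max_iter = 2)
  oracle <- staple_oracle(vecs, prior = 0.5, n_iter = 2)
  expect_equal(as.vector(fr$posterior), oracle$posterior, tolerance = 1e-12)
  expect_equal(fr$sensitivities, oracle$p, tolerance = 1e-12)
  expect_equal(fr$specificities, oracle$q, tolerance = 1e-12)
})

test_that("bounding-box restriction does not change the result", {
  set.seed(5)
  truth <- ball_mask(dims = c(12, 12, 12), radius = 3)
  raters <- lapply(1:4, function(i) flip_noise_rater(truth, 0.05, seed = i))
  fa <- staple(raters, restrict = TRUE)
  fb <- staple(raters, restrict = FALSE)
  expect_equal(fa$posterior, fb$posterior, tolerance = 1e-10)
  expect_equal(fa$sensitivities, fb$sensitivities, tolerance = 1e-10)
  expect_identical(fa$consensus$voxels, fb$consensus$voxels)
})

test_that("STAPLE fuses flip-noise raters at least as well as majority vote", {
  truth <- ball_mask()
  margins <- replicate(20, NA_real_)
  for (r in 1:20) {
    raters <- lapply(1:7, function(i) flip_noise_rater(truth, 0.1, seed = 100 * r + i))
    st <- staple(raters)
    mv <- majority_vote(raters)
    margins[r] <- dice(truth, st$consensus) - dice(truth, mv)
  }
  expect_gte(mean(margins), -0.01)
})

test_that("majority vote follows the strict-majority tie rule", {
  v1 <- lv(c(1L, 1L, 0L))
  v0 <- lv(c(1L, 0L, 0L))
  expect_equal(as.vector(majority_vote(list(v1, v1, v0))$voxels), c(1, 1, 0))
  # even rater count: (1, 0) ties resolve to background
  expect_equal(as.vector(majority_vote(list(v1, v0))$voxels), c(1, 0, 0))
  expect_identical(majority_vote(list(v1, v1, v1))$voxels, v1$voxels)
})

test_that("fusion rejects mismatched grids and bad priors", {
  a <- lv(rep(1L, 8), c(2, 2, 2))
  b <- label_volume(array(1L, c(2, 2, 2)), spacing = 3)
  expect_error(staple(list(a, b)), "grid mismatch")
  expect_error(majority_vote(list(a, b)), "grid mismatch")
  expect_error(staple(list(a), prior = 1.5), "prior")
  expect_error(staple(list()), "at least one")
})
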