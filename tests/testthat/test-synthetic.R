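test_that("phantom landmarks encode the requested protraction distance", {
  cfg <- synthetic_config()
  ph <- generate_phantom(40, cfg, seed = 1)
  d <- protraction_distance(ph$atlas$landmarks)
  expect_lte(abs(d - 40), cfg$spacing_mm[2] / 2)
  expect_gt(mask_volume_voxels(ph$atlas$gold_mask), 0)
})

test_that("phantom generation is seed-deterministic and protraction-sensitive", {
  cfg <- synthetic_config()
  a <- generate_phantom(40, cfg, seed = 7)
  b <- generate_phantom(40, cfg, seed = 7)
  expect_identical(a$atlas$gold_mask$voxels, b$atlas$gold_mask$voxels)
  lo <- generate_phantom(20, cfg, seed = 7)
  hi <- generate_phantom(70, cfg, seed = 7)
  expect_gt(sum(lo$atlas$gold_mask$voxels != hi$atlas$gold_mask$voxels), 0)
  off <- abs(protraction_distance(hi$atlas$landmarks) -
               protraction_distance(lo$atlas$landmarks))
  expect_lte(abs(off - 50), cfg$spacing_mm[2])
})

test_that("protraction is recovered within half a voxel on random phantoms", {
  cfg <- small_config()
  set.seed(13)
  req <- runif(50, cfg$protraction_range_mm[1], cfg$protraction_range_mm[2])
  for (i in seq_along(req)) {
    ph <- generate_phantom(req[i], cfg, seed = i)
    expect_lte(abs(protraction_distance(ph$atlas$landmarks) - req[i]),
               cfg$spacing_mm[2] / 2)
  }
})

test_that("generated masks are nonempty and 26-connected", {
  cfg <- small_config()
  for (i in 1:8) {
    ph <- generate_phantom(15 + 3 * i, cfg, seed = 20 + i)
    expect_gt(mask_volume_voxels(ph$atlas$gold_mask), 0)
    expect_true(connected_26(ph$atlas$gold_mask))
  }
})

test_that("out-of-range protraction and oversized structures error clearly", {
  cfg <- small_config()
  expect_error(generate_phantom(90, cfg, seed = 1), "outside configured range")
  # a grid too small to hold the structure names the offending axis
  tiny <- synthetic_config(grid_shape = c(24L, 10L, 24L), spacing_mm = 2,
                           protraction_range_mm = c(5, 60))
  expect_error(generate_phantom(50, tiny, seed = 1),
               "anterior-posterior|axis")
})

test_that("generate_database draws a reproducible, uniquely-labelled set", {
  cfg <- small_config(n_atlases = 12L, seed = 1L)
  db <- generate_database(cfg)
  expect_length(db, 12)
  ids <- vapply(db, function(ph) ph$atlas$id, character(1))
  expect_length(unique(ids), 12)
  prot <- vapply(db, `[[`, numeric(1), "true_protraction_mm")
  expect_true(all(prot >= 15 & prot <= 40))
  db2 <- generate_database(cfg)
  expect_identical(prot, vapply(db2, `[[`, numeric(1), "true_protraction_mm"))
  expect_length(generate_database(small_config(n_atlases = 3L)), 3)
  expect_error(synthetic_config(n_atlases = 2), ">= 3")
  expect_error(synthetic_config(protraction_range_mm = c(50, 20)), "lower")
})

test_that("zero displacement reproduces the patient gold mask exactly", {
  cfg <- small_config(error_base_mm = 0, error_slope = 0.2)
  pat <- generate_phantom(30, cfg, seed = 2, id = "pat")
  out <- simulate_registration(pat, pat, cfg, seed = 5) # delta = 0, a = 0
  expect_identical(out$voxels, pat$atlas$gold_mask$voxels)
})

test_that("simulated registration is seed-deterministic and checks grids", {
  cfg <- small_config()
  atl <- generate_phantom(20, cfg, seed = 1, id = "a")
  pat <- generate_phantom(35, cfg, seed = 2, id = "p")
  r1 <- simulate_registration(atl, pat, cfg, seed = 11)
  r2 <- simulate_registration(atl, pat, cfg, seed = 11)
  expect_identical(r1$voxels, r2$voxels)
  r3 <- simulate_registration(atl, pat, cfg, seed = 12)
  expect_gt(sum(r1$voxels != r3$voxels), 0)
  other <- generate_phantom(30, synthetic_config(), seed = 3, id = "o")
  expect_error(simulate_registration(other, pat, cfg), "grid mismatch")
})

test_that("label-transfer error grows with the protraction difference", {
  # Monte Carlo over the stated error model: a = 1, b = 0.2, 20 seeds,
  # delta = 0 vs delta = 30 mm
  cfg <- synthetic_config(error_base_mm = 1, error_slope = 0.2)
  pat <- generate_phantom(30, cfg, seed = 2, id = "pat")
  near <- generate_phantom(30, cfg, seed = 3, id = "near")
  far <- generate_phantom(60, cfg, seed = 4, id = "far")
  gold <- pat$atlas$gold_mask
  d0 <- vapply(1:20, function(s)
    dice(gold, simulate_registration(near, pat, cfg, seed = s)), numeric(1))
  d30 <- vapply(1:20, function(s)
    dice(gold, simulate_registration(far, pat, cfg, seed = s)), numeric(1))
  expect_gt(mean(d0), mean(d30))
})

test_that("mean DSC decreases across protraction-difference bins", {
  cfg <- small_config()
  pat <- generate_phantom(16, cfg, seed = 2, id = "pat")
  gold <- pat$atlas$gold_mask
  deltas <- c(4, 12, 22) # three |delta protraction| bins
  mean_dsc <- vapply(deltas, function(dl) {
    atl <- generate_phantom(16 + dl, cfg, seed = 3, id = "atl")
    mean(vapply(1:30, function(s)
      dice(gold, simulate_registration(atl, pat, cfg, seed = 500 + s)),
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_dsc) < 0))
})
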