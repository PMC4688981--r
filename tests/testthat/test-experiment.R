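test_that("combination enumeration matches direct counting", {
  ids <- sprintf("a%02d", 1:11)
  all2 <- enumerate_random_combinations(ids, 2)
  expect_length(all2, choose(11, 2)) # 55
  expect_true(all(vapply(all2, length, integer(1)) == 2))
  expect_length(unique(vapply(all2, paste, character(1), collapse = "+")), 55)
  expect_length(enumerate_random_combinations(ids, 11), 1)
  expect_error(enumerate_random_combinations(ids, 12), "\\[1, 11\\]")
  expect_error(enumerate_random_combinations(ids, 0), "\\[1, 11\\]")
})

test_that("combination subsampling is seeded and distinct", {
  ids <- sprintf("a%02d", 1:11)
  s1 <- enumerate_random_combinations(ids, 3, limit = 10, seed = 4)
  s2 <- enumerate_random_combinations(ids, 3, limit = 10, seed = 4)
  expect_identical(s1, s2)
  expect_length(s1, 10)
  expect_length(unique(vapply(s1, paste, character(1), collapse = "+")), 10)
  s3 <- enumerate_random_combinations(ids, 3, limit = 10, seed = 5)
  expect_false(identical(s1, s3))
})

test_that("group summaries match hand-computed mean and SD", {
  dsc <- c(0.5, 0.6, 0.7, 0.8)
  rec <- data.frame(patient_id = sprintf("p%d", 1:4), k = 2L,
                    strategy = "selected", combination = "a+b",
                    dsc = dsc, ji = dsc / 2, ini = dsc)
  s <- summarize_runs(rec)
  expect_equal(s$dsc_mean, 0.65)
  expect_equal(s$dsc_sd, sqrt(sum((dsc - 0.65)^2) / 3))
  expect_equal(s$n_runs, 4L)
  # degenerate cells
  s1 <- summarize_runs(rec[1, ])
  expect_equal(s1$dsc_sd, 0)
  expect_false(s1$sd_defined)
  s2 <- summarize_runs(rec[c(1, 1), ])
  expect_equal(s2$dsc_sd, 0)
  expect_true(s2$sd_defined)
})

test_that("Welch t-test behaves at the textbook cases", {
  a <- c(0.9, 0.8, 0.85)
  b <- c(0.5, 0.55, 0.45)
  tt <- independent_t_test(a, b)
  expect_lt(tt$p, 0.05)
  expect_equal(tt$mean_difference, mean(a) - mean(b))
  # swapping groups flips t and the difference, not p
  rev <- independent_t_test(b, a)
  expect_equal(rev$t, -tt$t)
  expect_equal(rev$mean_difference, -tt$mean_difference)
  expect_equal(rev$p, tt$p)
  # identical constant groups are NaN-guarded
  same <- independent_t_test(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(same$mean_difference, 0)
  expect_equal(same$p, 1)
  expect_error(independent_t_test(0.5, c(0.4, 0.6)), "n >= 2")
})

test_that("equivalence trial verdicts follow the CI-in-margin rule", {
  ref <- c(0.58, 0.60, 0.62, 0.59, 0.61)
  # same values: d = 0, CI symmetric, equivalent for a wide-enough margin
  eq <- equivalence_test(ref, ref, margin_mode = "absolute", margin_value = 0.05)
  expect_equal(eq$mean_difference, 0)
  expect_equal(eq$ci_low, -eq$ci_high)
  expect_true(eq$equivalent)
  expect_true(eq$ci_low <= eq$mean_difference & eq$mean_difference <= eq$ci_high)
  # relative margin is 10% of the reference mean
  eq_rel <- equivalence_test(ref, ref - 0.01, margin_mode = "relative",
                             margin_value = 0.10)
  expect_equal(eq_rel$margin, 0.10 * mean(ref))
  # shift of twice the margin with near-zero variance: not equivalent
  shifted <- ref - 2 * eq$margin
  eq2 <- equivalence_test(ref, shifted, margin_mode = "absolute",
                          margin_value = 0.05)
  expect_false(eq2$equivalent)
  expect_error(equivalence_test(0.5, ref), "n >= 2")
})

test_that("reference k maximises selected-arm mean DSC, ties to smaller k", {
  s <- data.frame(strategy = "selected", k = c(2, 5, 6, 7),
                  dsc_mean = c(0.44, 0.598, 0.598, 0.593))
  expect_equal(pick_reference_k(s), 5L)
  s2 <- data.frame(strategy = "selected", k = 6, dsc_mean = 0.5)
  expect_equal(pick_reference_k(s2), 6L)
  s$dsc_mean <- c(0.44, 0.58, 0.598, 0.593)
  expect_equal(pick_reference_k(s), 6L)
})

test_that("sample size formula matches the closed form and scales", {
  expect_equal(sample_size_two_means(sd = 1, delta = 1), 13L)
  n1 <- sample_size_two_means(sd = 0.12, delta = 0.05)
  n2 <- sample_size_two_means(sd = 0.12, delta = 0.10)
  expect_lt(n2, n1)
  expect_lte(n2, ceiling(n1 / 4) + 1) # inverse-square law up to rounding
  expect_error(sample_size_two_means(sd = 1, delta = 0), "delta")
})

test_that("small leave-one-out arms produce the expected design counts", {
  cfg <- small_config(n_atlases = 4L, seed = 3L, error_base_mm = 2)
  db <- generate_database(cfg)
  prop <- propagate_atlases(db, cfg, seed = 1)
  sel <- run_selected_arm(db, k_values = 2L, cfg, seed = 1, propagations = prop)
  expect_equal(nrow(sel), 4) # one record per patient
  expect_true(all(sel$strategy == "selected"))
  expect_true(all(sel$k == 2))
  # patient never sits in its own combination
  for (i in seq_len(nrow(sel))) {
    expect_false(grepl(sel$patient_id[i], sel$combination[i], fixed = TRUE))
  }
  # exhaustive random arm: n * choose(n - 1, k) records
  ran <- run_random_arm(db, k_values = 2L, limit = "all", config = cfg,
                        seed = 1, propagations = prop)
  expect_equal(nrow(ran), 4 * choose(3, 2))
  # seeded repeatability of the scores
  ran2 <- run_random_arm(db, k_values = 2L, limit = "all", config = cfg,
                         seed = 1, propagations = prop)
  expect_identical(ran, ran2)
})

test_that("zero-error registration gives perfect scores everywhere", {
  cfg <- small_config(n_atlases = 4L, seed = 5L,
                      error_base_mm = 0, error_slope = 0)
  db <- generate_database(cfg)
  sel <- run_selected_arm(db, k_values = 2:3, cfg, seed = 1)
  expect_equal(nrow(sel), 8)
  expect_true(all(sel$dsc == 1))
  expect_true(all(sel$ji == 1))
  expect_true(all(sel$ini == 1))
})

test_that("at k = n - 1 the selected and random arms coincide", {
  cfg <- small_config(n_atlases = 4L, seed = 7L)
  db <- generate_database(cfg)
  prop <- propagate_atlases(db, cfg, seed = 2)
  k <- length(db) - 1L
  sel <- run_selected_arm(db, k_values = k, cfg, seed = 2, propagations = prop)
  ran <- run_random_arm(db, k_values = k, limit = "all", config = cfg,
                        seed = 2, propagations = prop)
  sel <- sel[order(sel$patient_id), ]
  ran <- ran[order(ran$patient_id), ]
  expect_equal(sel$combination, ran$combination)
  expect_equal(sel$dsc, ran$dsc)
  expect_equal(sel$ji, ran$ji)
  expect_equal(sel$ini, ran$ini)
})
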