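#' Enumerate or sample random atlas combinations
#'
#' All `choose(n, k)` size-`k` subsets of the available atlas ids, or a
#' seeded uniform sample of `limit` distinct subsets.
#'
#' @param available Character vector of atlas ids.
#' @param k Subset size, `1 <= k <= length(available)`.
#' @param limit `"all"` (default) for exhaustive enumeration, or the number
#'   of distinct subsets to sample without replacement.
#' @param seed RNG seed for the sampling case.
#' @return List of character vectors (each sorted), deterministic given
#'   `seed`.
#' @export
enumerate_random_combinations <- function(available, k, limit = "all",
                                          seed = 1L) {
  n <- length(available)
  if (!is.numeric(k) || length(k) != 1L || k != as.integer(k) ||
      k < 1L || k > n) {
    stop(sprintf("`k` (%s) must be an integer in [1, %d]", format(k), n),
         call. = FALSE)
  }
  combos <- utils::combn(sort(available), k, simplify = FALSE)
  if (identical(limit, "all") || limit >= length(combos)) return(combos)
  if (!is.numeric(limit) || limit < 1L) {
    stop("`limit` must be \"all\" or a positive count", call. = FALSE)
  }
  keep <- with_seed(seed, sample.int(length(combos), limit))
  combos[sort(keep)]
}

# Deterministic per-(patient, atlas) registration seed.
pair_seed <- function(seed, patient_idx, atlas_idx) {
  (abs(as.integer(seed)) %% 100000L) * 10000L + patient_idx * 100L + atlas_idx
}

#' Propagate every atlas onto every patient
#'
#' Runs the simulated registration once per ordered (patient, atlas) pair of
#' a phantom database, so the leave-one-out arms can reuse label
#' propagations instead of recomputing them per combination (one
#' registration per pair is also what a real pipeline would compute).
#'
#' @param db List of phantoms from [generate_database()].
#' @param config A [synthetic_config()] (error model).
#' @param seed Base seed; each pair gets a deterministic derived seed.
#' @param registration Function `(atlas, patient, config, seed)` returning a
#'   [label_volume()]; defaults to [simulate_registration()].
#' @return Nested list: `result[[patient_id]][[atlas_id]]` is the atlas
#'   contour propagated onto that patient.
#' @export
propagate_atlases <- function(db, config = synthetic_config(), seed = 1L,
                              registration = simulate_registration) {
  ids <- vapply(db, function(ph) ph$atlas$id, character(1))
  out <- vector("list", length(db))
  names(out) <- ids
  for (pi in seq_along(db)) {
    per <- vector("list", length(db) - 1L)
    names(per) <- ids[-pi]
    for (ai in seq_along(db)) {
      if (ai == pi) next
      per[[ids[ai]]] <- registration(db[[ai]], db[[pi]], config,
                                     seed = pair_seed(seed, pi, ai))
    }
    out[[ids[pi]]] <- per
  }
  out
}

fuse_and_score <- function(patient, combo_ids, propagated, fusion_args) {
  raters <- propagated[combo_ids]
  fr <- do.call(staple, c(list(raters = unname(raters)), fusion_args))
  score_pair(patient$atlas$gold_mask, fr$consensus)
}

run_record <- function(patient_id, k, strategy, combo_ids, scores) {
  data.frame(patient_id = patient_id, k = as.integer(k), strategy = strategy,
             combination = paste(sort(combo_ids), collapse = "+"),
             dsc = scores$dsc, ji = scores$ji, ini = scores$ini,
             stringsAsFactors = FALSE)
}

#' Leave-one-out experiment: morphometrically selected arm
#'
#' Each atlas of the database in turn plays the patient; the remaining
#' atlases are ranked by protraction similarity, the top `k` are propagated
#' onto the patient, STAPLE-fused, and the consensus is scored against the
#' patient's gold mask — for every `k` in `k_values`. A 12-atlas database
#' with `k = 2:8` yields 7 x 12 = 84 run records.
#'
#' @param db List of phantoms from [generate_database()].
#' @param k_values Atlas counts to evaluate. Default `2:8`.
#' @param config A [synthetic_config()].
#' @param seed Base seed for the simulated registrations.
#' @param fusion_args Named list of extra arguments to [staple()].
#' @param propagations Optional precomputed [propagate_atlases()] result.
#' @return Data frame with one row per (patient, k): `patient_id`, `k`,
#'   `strategy` (`"selected"`), `combination`, `dsc`, `ji`, `ini`.
#' @export
run_selected_arm <- function(db, k_values = 2:8, config = synthetic_config(),
                             seed = 1L, fusion_args = list(),
                             propagations = NULL) {
  if (length(db) < max(k_values) + 1L) {
    stop("database must contain at least max(k_values) + 1 atlases",
         call. = FALSE)
  }
  if (is.null(propagations)) {
    propagations <- propagate_atlases(db, config, seed)
  }
  ids <- vapply(db, function(ph) ph$atlas$id, character(1))
  rows <- list()
  for (pi in seq_along(db)) {
    patient <- db[[pi]]
    pool <- db[-pi]
    ranked <- rank_atlases(patient$atlas$protraction_mm,
                           lapply(pool, function(ph) ph$atlas))
    ranked_ids <- vapply(ranked, function(a) a$id, character(1))
    for (k in k_values) {
      combo <- ranked_ids[seq_len(k)]
      sc <- tryCatch(
        fuse_and_score(patient, combo, propagations[[ids[pi]]], fusion_args),
        error = function(e) {
          stop(sprintf("selected arm failed at patient %s, k = %d: %s",
                       ids[pi], k, conditionMessage(e)), call. = FALSE)
        })
      rows[[length(rows) + 1L]] <- run_record(ids[pi], k, "selected", combo, sc)
    }
  }
  do.call(rbind, rows)
}

#' Leave-one-out experiment: random-combination arm
#'
#' As [run_selected_arm()], but for each (patient, k) the atlas combinations
#' are size-`k` subsets of the remaining atlases drawn by
#' [enumerate_random_combinations()]. The default `limit = 7` per
#' (patient, k) gives 7 x 12 = 84 runs per `k` on a 12-atlas database,
#' clearing the 75-runs-per-k sample size that a power analysis
#' (power 0.80, 90% confidence) asks of the group comparison.
#'
#' @inheritParams run_selected_arm
#' @param limit Combinations per (patient, k): a count or `"all"`.
#' @return Data frame of run records with `strategy = "random"`.
#' @export
run_random_arm <- function(db, k_values = 2:8, limit = 7L,
                           config = synthetic_config(), seed = 1L,
                           fusion_args = list(), propagations = NULL) {
  if (length(db) < max(k_values) + 1L) {
    stop("database must contain at least max(k_values) + 1 atlases",
         call. = FALSE)
  }
  if (is.null(propagations)) {
    propagations <- propagate_atlases(db, config, seed)
  }
  ids <- vapply(db, function(ph) ph$atlas$id, character(1))
  rows <- list()
  for (pi in seq_along(db)) {
    patient <- db[[pi]]
    pool_ids <- ids[-pi]
    for (k in k_values) {
      # seed stream disjoint from the per-pair registration seeds
      combos <- enumerate_random_combinations(
        pool_ids, k, limit = limit,
        seed = pair_seed(seed, pi, 0L) + 5000L + k
      )
      for (combo in combos) {
        sc <- tryCatch(
          fuse_and_score(patient, combo, propagations[[ids[pi]]], fusion_args),
          error = function(e) {
            stop(sprintf("random arm failed at patient %s, k = %d: %s",
                         ids[pi], k, conditionMessage(e)), call. = FALSE)
          })
        rows[[length(rows) + 1L]] <- run_record(ids[pi], k, "random", combo, sc)
      }
    }
  }
  do.call(rbind, rows)
}

#' Per-(strategy, k) group means and standard deviations
#'
#' @param records Run records from the experiment arms (rows are pooled
#'   across patients within each (strategy, k) cell).
#' @return Data frame with one row per (strategy, k): `n_runs`, mean and
#'   sample SD (n - 1 denominator) of each index. A single-run cell reports
#'   `sd = 0` with `sd_defined = FALSE`.
#' @export
summarize_runs <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  cells <- split(records, list(records$strategy, records$k), drop = TRUE)
  rows <- lapply(cells, function(cell) {
    n <- nrow(cell)
    sdv <- function(x) if (n > 1L) stats::sd(x) else 0
    data.frame(strategy = cell$strategy[1], k = cell$k[1], n_runs = n,
               dsc_mean = mean(cell$dsc), dsc_sd = sdv(cell$dsc),
               ji_mean = mean(cell$ji), ji_sd = sdv(cell$ji),
               ini_mean = mean(cell$ini), ini_sd = sdv(cell$ini),
               sd_defined = n > 1L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$strategy, out$k), ]
  rownames(out) <- NULL
  out
}

#' Independent two-sample t-test on similarity scores
#'
#' Two-sided Welch (unequal-variance) test by default; set
#' `var_equal = TRUE` for the classical Student test. Two groups that are
#' both constant are NaN-guarded: equal means give `t = 0, p = 1`, unequal
#' means `t = +/-Inf, p = 0`.
#'
#' @param group_a,group_b Numeric score vectors, each of length >= 2.
#' @param var_equal Pool variances? Default `FALSE` (Welch).
#' @return List with `t`, `p` and `mean_difference` (= mean(a) - mean(b)).
#' @export
independent_t_test <- function(group_a, group_b, var_equal = FALSE) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("both groups need n >= 2", call. = FALSE)
  }
  md <- mean(group_a) - mean(group_b)
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    if (md == 0) return(list(t = 0, p = 1, mean_difference = 0))
    return(list(t = sign(md) * Inf, p = 0, mean_difference = md))
  }
  tt <- stats::t.test(group_a, group_b, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value, mean_difference = md)
}

#' Equivalence trial on the difference of group means
#'
#' Declares two groups equivalent when the two-sided `confidence`-level
#' confidence interval of their mean difference (Welch standard error and
#' degrees of freedom) lies entirely within `[-margin, +margin]` —
#' equivalent to two one-sided tests at level `(1 - confidence) / 2` each.
#' The margin is either `margin_value` itself (`"absolute"`) or
#' `margin_value * mean(reference)` (`"relative"`, the default, so 0.10
#' reads "within 10% of the reference group's mean score").
#'
#' @param reference,comparison Numeric score vectors, each n >= 2;
#'   `reference` is the group the margin is anchored on.
#' @param margin_mode `"relative"` (default) or `"absolute"`.
#' @param margin_value Margin size. Default 0.10.
#' @param confidence Two-sided confidence level of the CI. Default 0.90.
#' @param reference_k,comparison_k Optional atlas counts recorded in the
#'   result for reporting.
#' @return An object of class `equivalence_result`: `reference_k`,
#'   `comparison_k`, `mean_difference` (reference - comparison), `ci_low`,
#'   `ci_high`, `margin`, `equivalent`.
#' @export
equivalence_test <- function(reference, comparison, margin_mode = "relative",
                             margin_value = 0.10, confidence = 0.90,
                             reference_k = NA_integer_,
                             comparison_k = NA_integer_) {
  if (length(reference) < 2L || length(comparison) < 2L) {
    stop("both groups need n >= 2", call. = FALSE)
  }
  margin_mode <- match.arg(margin_mode, c("relative", "absolute"))
  stopifnot(margin_value > 0, confidence > 0, confidence < 1)
  d <- mean(reference) - mean(comparison)
  va <- stats::var(reference) / length(reference)
  vb <- stats::var(comparison) / length(comparison)
  se <- sqrt(va + vb)
  if (se == 0) {
    ci <- c(d, d)
  } else {
    df <- (va + vb)^2 /
      (va^2 / (length(reference) - 1) + vb^2 / (length(comparison) - 1))
    tq <- stats::qt(1 - (1 - confidence) / 2, df)
    ci <- d + c(-1, 1) * tq * se
  }
  margin <- if (margin_mode == "relative") margin_value * mean(reference)
            else margin_value
  structure(
    list(reference_k = reference_k, comparison_k = comparison_k,
         mean_difference = d, ci_low = ci[1], ci_high = ci[2],
         margin = margin, equivalent = ci[1] >= -margin && ci[2] <= margin),
    class = "equivalence_result"
  )
}

#' @export
print.equivalence_result <- function(x, ...) {
  cat(sprintf(
    "<equivalence_result> d = %.4f, 90%%-type CI [%.4f, %.4f], margin %.4f -> %s\n",
    x$mean_difference, x$ci_low, x$ci_high, x$margin,
    if (x$equivalent) "equivalent" else "not equivalent"))
  invisible(x)
}

#' Reference atlas count for the equivalence trial
#'
#' The `k` with the highest mean DSC in the selected arm; ties go to the
#' smaller `k` (fewer atlases means less registration work).
#'
#' @param summaries Output of [summarize_runs()].
#' @return Integer `k`.
#' @export
pick_reference_k <- function(summaries) {
  sel <- summaries[summaries$strategy == "selected", ]
  if (nrow(sel) == 0L) stop("no selected-arm summaries", call. = FALSE)
  sel <- sel[order(-sel$dsc_mean, sel$k), ]
  as.integer(sel$k[1])
}

#' Sample size for comparing two means
#'
#' Normal-approximation formula
#' `n = 2 (z_{1-alpha/2} + z_{power})^2 sd^2 / delta^2` per group, rounded
#' up.
#'
#' @param sd Common standard deviation of the score.
#' @param delta Smallest difference worth detecting (> 0).
#' @param power Desired power. Default 0.80.
#' @param alpha Two-sided significance level. Default 0.10 (matching a 90%
#'   confidence interval).
#' @return Integer n per group.
#' @export
#' @examples
#' sample_size_two_means(sd = 1, delta = 1) # 13
sample_size_two_means <- function(sd, delta, power = 0.80, alpha = 0.10) {
  if (!is.numeric(delta) || delta <= 0) {
    stop("`delta` must be > 0", call. = FALSE)
  }
  stopifnot(sd >= 0, power > 0, power < 1, alpha > 0, alpha < 1)
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  as.integer(ceiling(2 * z^2 * sd^2 / delta^2))
}

#' Run the full selected-versus-random leave-one-out experiment
#'
#' Generates (or accepts) a phantom database, propagates every atlas onto
#' every patient once, runs both experiment arms, summarises the per-k
#' groups, Welch-tests selected versus random per k and index, and runs the
#' equivalence trial of every other selected-arm `k` against the
#' reference `k` (the selected `k` with highest mean DSC).
#'
#' @param config A [synthetic_config()].
#' @param k_values Atlas counts. Default `2:8`.
#' @param random_limit Random combinations per (patient, k). Default 7.
#' @param seed Seed for registrations and random-arm sampling.
#' @param db Optional pre-generated database (defaults to
#'   `generate_database(config)`).
#' @param fusion_args Extra arguments to [staple()].
#' @param margin_mode,margin_value,confidence Equivalence-trial settings,
#'   see [equivalence_test()].
#' @param verbose Emit progress messages. Default `FALSE`.
#' @return List: `records` (both arms pooled), `summaries`, `t_tests` (data
#'   frame per k and index), `reference_k`, `equivalence` (list of
#'   [equivalence_test()] results keyed by comparison k).
#' @export
run_loo_experiment <- function(config = synthetic_config(), k_values = 2:8,
                               random_limit = 7L, seed = 1L, db = NULL,
                               fusion_args = list(),
                               margin_mode = "relative", margin_value = 0.10,
                               confidence = 0.90, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.null(db)) {
    say("generating %d-atlas phantom database", config$n_atlases)
    db <- generate_database(config)
  }
  say("propagating %d x %d atlas-patient pairs", length(db), length(db) - 1L)
  prop <- propagate_atlases(db, config, seed)
  say("running selected arm")
  sel <- run_selected_arm(db, k_values, config, seed, fusion_args, prop)
  say("running random arm (limit %s per patient and k)", format(random_limit))
  ran <- run_random_arm(db, k_values, random_limit, config, seed,
                        fusion_args, prop)
  records <- rbind(sel, ran)
  summaries <- summarize_runs(records)

  tt_rows <- list()
  for (k in k_values) {
    sk <- sel[sel$k == k, ]
    rk <- ran[ran$k == k, ]
    for (index in c("dsc", "ji", "ini")) {
      tt <- independent_t_test(sk[[index]], rk[[index]])
      tt_rows[[length(tt_rows) + 1L]] <- data.frame(
        k = k, index = index, mean_selected = mean(sk[[index]]),
        mean_random = mean(rk[[index]]), mean_difference = tt$mean_difference,
        t = tt$t, p = tt$p, stringsAsFactors = FALSE)
    }
  }
  t_tests <- do.call(rbind, tt_rows)

  ref_k <- pick_reference_k(summaries)
  ref_scores <- sel$dsc[sel$k == ref_k]
  equivalence <- list()
  for (k in setdiff(k_values, ref_k)) {
    equivalence[[as.character(k)]] <- equivalence_test(
      ref_scores, sel$dsc[sel$k == k],
      margin_mode = margin_mode, margin_value = margin_value,
      confidence = confidence, reference_k = ref_k, comparison_k = k)
  }
  say("done: %d run records, reference k = %d", nrow(records), ref_k)
  list(records = records, summaries = summaries, t_tests = t_tests,
       reference_k = ref_k, equivalence = equivalence)
}
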