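make_subs <- function(n = 30, seed = 2) {
  spec <- motif_spec("PSALD", n_substrates = n, seed = seed)
  generate_substrates(spec)
}

test_that("train/test split is a random 2:1 substrate-level partition", {
  subs <- make_subs(300)
  sp <- split_train_test(subs, fraction = 2 / 3, seed = 1)
  expect_equal(nrow(sp$train), 200L)
  expect_equal(nrow(sp$test), 100L)
  expect_equal(sort(c(rownames(sp$train), rownames(sp$test))),
               sort(rownames(subs)))
  # reproducible
  sp2 <- split_train_test(subs, fraction = 2 / 3, seed = 1)
  expect_identical(sp$train, sp2$train)
  expect_error(split_train_test(subs, fraction = 0), "between 0 and 1")
  expect_error(split_train_test(subs, fraction = 1), "between 0 and 1")
  expect_error(split_train_test(subs[1:2, ], 0.5), "at least 3")
})

test_that("k-fold partition is balanced, exhaustive and disjoint", {
  f <- kfold_partition(10, 10, seed = 1)
  expect_equal(sort(f), 1:10)                        # leave-one-out
  f <- kfold_partition(23, 10, seed = 1)
  expect_equal(length(f), 23L)
  expect_equal(sort(as.integer(table(f)), decreasing = TRUE),
               c(3L, 3L, 3L, rep(2L, 7)))
  expect_identical(f, kfold_partition(23, 10, seed = 1))
  expect_error(kfold_partition(5, 10), "fewer substrates")
})

test_that("confusion metrics match hand-computed values", {
  m <- compute_metrics(tp = 9, fn = 1, tn = 89, fp = 1)
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$fpr, 1 / 90)
  expect_equal(m$specificity, 89 / 90)
  expect_equal(m$precision, 0.9)
  expect_equal(m$accuracy, 0.98)
  expect_equal(m$mcc, 800 / 900)
  expect_equal(m$f1, 0.9)
  expect_length(m$undefined, 0)
  expect_equal(m$fpr, 1 - m$specificity)

  perfect <- compute_metrics(10, 0, 90, 0)
  for (mn in c("sensitivity", "specificity", "accuracy", "precision",
               "mcc", "f1"))
    expect_equal(perfect[[mn]], 1)
  expect_equal(perfect$fpr, 0)

  deg <- compute_metrics(0, 0, 10, 5)
  expect_true(all(c("precision", "mcc", "f1") %in% deg$undefined))
  expect_equal(deg$precision, 0)
  expect_error(compute_metrics(-1, 0, 0, 0), "negative")
})

test_that("AUC matches brute-force pair counting and known examples", {
  # perfectly separated
  expect_equal(roc_auc(c(1, 2, 10, 11), c(0, 0, 1, 1))$auc, 1)
  # pos {2,3}, neg {1,2}: 3 wins + 1 tie/2 over 4 pairs
  expect_equal(roc_auc(c(2, 3, 1, 2), c(1, 1, 0, 0))$auc, 0.875)
  expect_error(roc_auc(c(1, 2), c(1, 1)), "both")

  set.seed(31)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    label <- c(1, 0, rbinom(n - 2, 1, 0.5))
    score <- sample(1:6, n, replace = TRUE)   # discrete -> ties occur
    r <- roc_auc(score, label)
    expect_equal(r$auc, auc_bruteforce(score, label), tolerance = 1e-12)
    expect_equal(r$points$fpr[[1]], 0)
    expect_equal(r$points$tpr[[nrow(r$points)]], 1)
    expect_true(all(diff(r$points$fpr) >= 0) && all(diff(r$points$tpr) >= 0))
  }
})

test_that("KS D equals the brute-force maximal ECDF gap", {
  expect_equal(ks_separation(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ks_separation(c(1, 2), c(3, 4)), 1)
  expect_equal(ks_separation(c(1, 3), c(2, 4)), 0.5)
  expect_error(ks_separation(numeric(0), 1), "non-empty")

  set.seed(7)
  for (i in 1:10) {
    a <- rnorm(sample(5:40, 1))
    b <- rnorm(sample(5:40, 1), mean = runif(1, 0, 2))
    expect_equal(ks_separation(a, b),
                 unname(suppressWarnings(stats::ks.test(a, b))$statistic),
                 tolerance = 1e-12)
  }
})

test_that("grid search is deterministic and returns the single cell of a 1x1 grid", {
  subs <- make_subs(60, seed = 4)
  bg <- generate_background(motif_spec(n_background = 200, seed = 4))
  cfg <- cv_config(k_folds = 5, grid_offsets = -4, grid_thresholds = 0.5,
                   seed = 9)
  res <- grid_search_cv(subs, bg, cfg)
  expect_equal(res$best_offset, -4)
  expect_equal(res$best_threshold, 0.5)
  expect_equal(dim(res$f1_grid), c(1L, 1L))

  cfg2 <- cv_config(k_folds = 5, grid_offsets = c(-6, -4, -2),
                    grid_thresholds = c(-1, 0, 1, 2), seed = 9)
  r1 <- grid_search_cv(subs, bg, cfg2)
  r2 <- grid_search_cv(subs, bg, cfg2)
  expect_identical(r1$f1_grid, r2$f1_grid)
  expect_identical(r1$best_threshold, r2$best_threshold)
  # optimum attains the grid maximum
  expect_equal(r1$f1_grid[sprintf("%g", r1$best_offset),
                          sprintf("%g", r1$best_threshold)],
               max(r1$f1_grid))
  # summary carries mean and sample sd across folds
  f1s <- vapply(r1$fold_metrics, `[[`, numeric(1), "f1")
  expect_equal(unname(r1$summary["f1", "mean"]), mean(f1s))
  expect_equal(unname(r1$summary["f1", "sd"]), stats::sd(f1s))
})

test_that("protein-level negatives are sampled at the requested ratio", {
  x <- toy_pwm(threshold = 0)
  set.seed(12)
  seqs <- c(prot1 = paste(sample(cleavescan:::AA_ALPHABET, 600, TRUE),
                          collapse = ""))
  positives <- data.frame(sequence_id = "prot1",
                          p1_position = c(10L, 50L, 120L, 333L, 590L))
  lab <- sample_protein_negatives(x, seqs, positives, ratio = 100, seed = 3)
  expect_equal(sum(lab$label == 1L), 5L)
  expect_equal(sum(lab$label == 0L), 500L)
  expect_false(any(duplicated(paste(lab$sequence_id, lab$p1_position))))
  lab2 <- sample_protein_negatives(x, seqs, positives, ratio = 100, seed = 3)
  expect_identical(lab, lab2)

  # insufficient negatives: take all, warn
  short <- c(p = paste(sample(cleavescan:::AA_ALPHABET, 30, TRUE),
                       collapse = ""))
  expect_warning(
    lab3 <- sample_protein_negatives(x, short,
                                     data.frame(sequence_id = "p",
                                                p1_position = 10L),
                                     ratio = 100, seed = 1),
    "negatives available")
  expect_equal(sum(lab3$label == 0L), 25L)   # 26 full-window bonds minus 1 positive
})

test_that("cleavage-position refinement moves only below-threshold sites, within range", {
  x <- toy_pwm(seed = 4)
  # plant the argmax window so one bond scores score_max
  best <- paste(apply(x$M, 2, function(v) names(which.max(v))), collapse = "")
  set.seed(5)
  seq <- paste0(paste(sample(cleavescan:::AA_ALPHABET, 20, TRUE), collapse = ""),
                best,
                paste(sample(cleavescan:::AA_ALPHABET, 20, TRUE), collapse = ""))
  sites <- scan_sequence(x, seq, "p")
  top <- sites$p1_position[which.max(sites$score)]   # = 23
  x2 <- pwm(x$M, x$offset, threshold = x$score_max - 1e-6, enzyme = "toy")

  # reported 2 bonds away from the only above-threshold bond -> reassigned
  rep_df <- data.frame(sequence_id = "p", p1_position = top - 2L)
  out <- refine_cleavage_positions(x2, c(p = seq), rep_df, max_shift = 4)
  expect_true(out$reassigned[[1]])
  expect_equal(out$corrected_position[[1]], top)
  expect_gte(out$corrected_score[[1]], out$reported_score[[1]])
  expect_lte(abs(out$corrected_position[[1]] - out$reported_position[[1]]), 4L)
  expect_equal(attr(out, "n_reassigned"), 1L)

  # reported bond already above threshold -> unchanged
  rep_top <- data.frame(sequence_id = "p", p1_position = top)
  out2 <- refine_cleavage_positions(x2, c(p = seq), rep_top)
  expect_false(out2$reassigned[[1]])
  expect_equal(out2$corrected_position[[1]], top)

  # nothing above threshold within +/-4 -> unchanged
  far <- data.frame(sequence_id = "p", p1_position = top - 10L)
  out3 <- refine_cleavage_positions(x2, c(p = seq), far, max_shift = 4)
  expect_false(out3$reassigned[[1]])
  expect_equal(out3$corrected_position[[1]], top - 10L)
})
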