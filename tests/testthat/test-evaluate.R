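test_that("ROC/AUC matches brute-force pair counting with tie half-credit", {
  r <- roc_auc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))
  expect_equal(r$auc, 0.75)
  expect_equal(r$roc[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(unlist(r$roc[nrow(r$roc), ]), c(fpr = 1, tpr = 1))

  # perfect separation and all-tied scores
  expect_equal(roc_auc(c(5, 4, 1, 0), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(2, 6), c(1, 0, 1, 0, 0, 1))$auc, 0.5)

  set.seed(61)
  for (rep in 1:25) {
    n <- sample(6:30, 1)
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    l <- rbinom(n, 1, 0.5)
    if (sum(l) == 0 || sum(l) == n) next
    r <- roc_auc(s, l)
    expect_equal(r$auc, oracle_auc(s, l), tolerance = 1e-12)
    # ROC monotone, trapezoid equals reported AUC
    expect_true(all(diff(r$roc$fpr) >= 0), info = "fpr non-decreasing")
    expect_true(all(diff(r$roc$tpr) >= 0), info = "tpr non-decreasing")
    trap <- sum(diff(r$roc$fpr) * (head(r$roc$tpr, -1) +
                                     tail(r$roc$tpr, -1)) / 2)
    expect_equal(r$auc, trap, tolerance = 1e-9)
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "positive and a negative")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(65)
  for (rep in 1:5) {
    s <- round(runif(60), 2)                  # rounded: ties occur
    l <- c(1, 0, rbinom(58, 1, 0.4))
    expect_equal(roc_auc(s, l)$auc,
                 as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant to monotone transforms of the scores", {
  set.seed(62)
  s <- runif(40)
  l <- rbinom(40, 1, 0.4)
  a0 <- roc_auc(s, l)$auc
  expect_equal(roc_auc(exp(3 * s), l)$auc, a0)
  expect_equal(roc_auc(rank(s), l)$auc, a0)
})

test_that("scoring with the training matrix itself gives AUC 0.5", {
  # every held-out pair is zeroed in training, so its score ties all
  # candidate (unknown) pairs: normalized rank 0.5 everywhere
  set.seed(63)
  A <- random_binary(8, 6)
  pairs <- which(A == 1, arr.ind = TRUE)
  unknown <- A == 0
  u <- apply(pairs, 1, function(ij) {
    A_train <- A
    A_train[ij[1], ij[2]] <- 0
    mdhgi:::normalized_rank(A_train[ij[1], ij[2]], A_train[unknown])
  })
  rr <- mdhgi:::rank_roc(u)
  expect_equal(rr$auc, 0.5)
})

test_that("normalized-rank ROC is exact and well-formed", {
  set.seed(64)
  u <- c(0.1, 0.1, 0.25, 0.5, 0.9)
  rr <- mdhgi:::rank_roc(u)
  expect_equal(rr$auc, 1 - mean(u), tolerance = 1e-12)
  expect_true(all(diff(rr$roc$fpr) >= 0))
  expect_true(all(diff(rr$roc$tpr) >= 0))
  expect_equal(rr$roc$fpr[1], 0); expect_equal(rr$roc$tpr[1], 0)
  expect_equal(tail(rr$roc$fpr, 1), 1); expect_equal(tail(rr$roc$tpr, 1), 1)
})

small_dataset <- function(seed = 5) {
  generate_synthetic(synth_config(n_mirnas = 20, n_diseases = 15,
                                  rank = 2, density = 0.15,
                                  hidden_frac = 0, flip_frac = 0,
                                  seed = seed))
}

test_that("global LOOCV recovers signal on structured data", {
  ds <- small_dataset()
  rep <- global_loocv(ds$observed, ds$ontology, ds$ms, max_folds = 12,
                      fold_seed = 2)
  expect_s3_class(rep, "mdhgi_cv")
  expect_gt(rep$auc, 0.5)
  # permutation check on the normalized ranks: under the null they are
  # uniform; observed mean must be extreme
  u <- rep$per_test_rank$norm_rank
  p <- stats::pbinom(sum(u < 0.5), length(u), 0.5,
                     lower.tail = FALSE)
  expect_lt(mean(u), 0.5)
  expect_equal(rep$auc, 1 - mean(u), tolerance = 1e-12)
})

test_that("local LOOCV ranks within the disease and skips empty pools", {
  ds <- small_dataset(seed = 8)
  rep <- local_loocv(ds$observed, ds$ontology, ds$ms, max_folds = 10,
                     fold_seed = 3)
  expect_gt(rep$auc, 0.5)
  # candidate counts are per-disease: at most the number of miRNAs
  expect_true(all(rep$per_test_rank$n_candidates < nrow(ds$observed)))
  A <- ds$observed
  for (k in seq_len(nrow(rep$per_test_rank))) {
    d <- rep$per_test_rank$disease[k]
    expect_equal(rep$per_test_rank$n_candidates[k], sum(A[, d] == 0))
  }
})

test_that("held-out pairs change the recomputed kernels (no leakage)", {
  ds <- small_dataset(seed = 9)
  A <- ds$observed
  ij <- which(A == 1, arr.ind = TRUE)[1, ]
  A_train <- A
  A_train[ij[1], ij[2]] <- 0
  gd_full <- gip_kernel(A, "diseases")
  gd_fold <- gip_kernel(A_train, "diseases")
  expect_gt(max(abs(unclass(gd_full) - unclass(gd_fold))), 0)
  gr_full <- gip_kernel(A, "mirnas")
  gr_fold <- gip_kernel(A_train, "mirnas")
  expect_gt(max(abs(unclass(gr_full) - unclass(gr_fold))), 0)
})

test_that("k-fold reports are seed-deterministic with mean +/- sd", {
  ds <- small_dataset(seed = 12)
  r1 <- kfold_cv(ds$observed, ds$ontology, ds$ms, k = 5, repeats = 2,
                 seed = 17)
  r2 <- kfold_cv(ds$observed, ds$ontology, ds$ms, k = 5, repeats = 2,
                 seed = 17)
  expect_identical(r1$auc_per_repeat, r2$auc_per_repeat)
  expect_identical(r1$per_test_rank, r2$per_test_rank)
  expect_equal(r1$auc, mean(r1$auc_per_repeat))
  expect_equal(r1$auc_sd, stats::sd(r1$auc_per_repeat))
  # a different seed gives a different partition
  r3 <- kfold_cv(ds$observed, ds$ontology, ds$ms, k = 5, repeats = 2,
                 seed = 18)
  expect_false(identical(r1$per_test_rank$mirna, r3$per_test_rank$mirna))
  expect_error(kfold_cv(ds$observed, k = 1000), "fewer associations")
})

test_that("frozen similarities reproduce the cheaper variant differently", {
  ds <- small_dataset(seed = 14)
  r_refit <- global_loocv(ds$observed, ds$ontology, ds$ms, max_folds = 6,
                          fold_seed = 4)
  r_frozen <- global_loocv(ds$observed, ds$ontology, ds$ms, max_folds = 6,
                           fold_seed = 4, refit_similarity = FALSE)
  # same folds, but the kernel matrices differ, so ranks generally differ
  expect_equal(r_refit$per_test_rank$mirna, r_frozen$per_test_rank$mirna)
  expect_false(isTRUE(all.equal(r_refit$per_test_rank$norm_rank,
                                r_frozen$per_test_rank$norm_rank,
                                tolerance = 1e-12)))
})
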