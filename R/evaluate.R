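#' ROC curve and AUC with half-credit tie handling
#'
#' Threshold-sweep ROC over the unique score values; tied blocks of mixed
#' labels produce diagonal segments, so the trapezoidal area equals the
#' rank-statistic (Mann-Whitney) AUC with ties counted half.
#'
#' @param scores numeric vector.
#' @param labels binary vector (1 = positive), same length.
#' @return list with `auc` and `roc` (data.frame of `fpr`, `tpr` from (0,0)
#'   to (1,1)).
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  if (np == 0 || nn == 0)
    stop("both a positive and a negative label are required", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  grp <- cumsum(!duplicated(s))             # tie groups, descending score
  tp <- cumsum(l)[!duplicated(grp, fromLast = TRUE)]
  fp <- cumsum(1 - l)[!duplicated(grp, fromLast = TRUE)]
  roc <- data.frame(fpr = c(0, fp / nn), tpr = c(0, tp / np))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                utils::tail(roc$tpr, -1)) / 2)
  list(auc = auc, roc = roc)
}

# ROC/AUC from per-test normalized ranks: u_i in (0, 1) is the fraction of a
# fold's candidates scoring above the held-out pair (ties half).  TPR at
# FPR = x is the fraction of held-out pairs whose normalized rank is <= x;
# emitting both corners of every jump makes the trapezoidal area exact.
rank_roc <- function(u) {
  ux <- sort(unique(u))
  n <- length(u)
  tpr_after <- vapply(ux, function(x) mean(u <= x), 0)
  fpr <- c(0, rep(ux, each = 2L), 1)
  tpr <- c(0, as.vector(rbind(c(0, utils::head(tpr_after, -1)), tpr_after)),
           1)
  roc <- data.frame(fpr = fpr, tpr = tpr)
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                utils::tail(roc$tpr, -1)) / 2)
  list(auc = auc, roc = roc)
}

# Normalized rank of `score` within candidate scores: (# above + half ties,
# scaled); the complement of the per-fold AUC contribution.
normalized_rank <- function(score, candidates) {
  (sum(candidates > score) + 0.5 * sum(candidates == score)) /
    length(candidates)
}

# Shared fold runner.  `folds` is a list of integer vectors indexing rows of
# `pairs` (the known-association positions in A_full).  For each fold the
# fold's pairs are zeroed, the A-dependent pipeline is refit, and every test
# pair is scored against its candidate pool.
run_cv_folds <- function(A_full, pairs, folds, ss, ms, pool = "global",
                         refit_similarity = TRUE, ...) {
  dots <- list(...)
  frozen <- NULL
  if (!refit_similarity) {
    kc <- if (is.null(dots$kernel)) kernel_control() else dots$kernel
    wc <- if (is.null(dots$weights)) edge_weights() else dots$weights
    frozen <- build_similarities(A_full, ss, ms, kc, wc)
  }
  unknown <- A_full == 0
  out <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    test <- pairs[folds[[f]], , drop = FALSE]
    A_train <- A_full
    A_train[test] <- 0
    fit <- tryCatch(
      do.call(mdhgi_engine, c(list(A_train, ss = ss, ms = ms,
                                   similarities = frozen), dots)),
      error = function(e) stop("pipeline failed in fold ", f, ": ",
                               conditionMessage(e), call. = FALSE))
    P <- fit$scores
    u <- numeric(nrow(test))
    ncand <- integer(nrow(test))
    for (t in seq_len(nrow(test))) {
      i <- test[t, 1L]
      j <- test[t, 2L]
      cand <- if (pool == "global") P[unknown] else P[unknown[, j], j]
      u[t] <- normalized_rank(P[i, j], cand)
      ncand[t] <- length(cand)
    }
    out[[f]] <- data.frame(fold = f, mirna = rownames(A_full)[test[, 1L]],
                           disease = colnames(A_full)[test[, 2L]],
                           norm_rank = u, n_candidates = ncand)
  }
  do.call(rbind, out)
}

cv_report <- function(per_test, scheme, seed = NA_integer_,
                      auc_per_repeat = NULL) {
  rr <- rank_roc(per_test$norm_rank)
  structure(list(auc = rr$auc,
                 auc_sd = if (!is.null(auc_per_repeat))
                   stats::sd(auc_per_repeat) else NA_real_,
                 auc_per_repeat = auc_per_repeat,
                 roc = rr$roc,
                 per_test_rank = per_test,
                 scheme = scheme,
                 seed = seed),
            class = "mdhgi_cv")
}

#' @export
print.mdhgi_cv <- function(x, ...) {
  cat("Cross-validation (", x$scheme, "): ", nrow(x$per_test_rank),
      " test samples\n", sep = "")
  if (is.na(x$auc_sd))
    cat("  AUC =", format(round(x$auc, 4), nsmall = 4), "\n")
  else
    cat("  AUC =", format(round(x$auc, 4), nsmall = 4), "+/-",
        format(round(x$auc_sd, 4), nsmall = 4), "over",
        length(x$auc_per_repeat), "repeats\n")
  invisible(x)
}

#' Global leave-one-out cross-validation
#'
#' Each known association is held out in turn: it is zeroed in the training
#' matrix, all association-dependent quantities (interaction-profile
#' kernels, decomposition, propagation) are recomputed, and the held-out
#' pair's score is ranked against all unknown miRNA-disease pairs.  The
#' semantic and functional similarities do not depend on the association
#' matrix and are computed once.
#'
#' @param catalog an [association_catalog()] or binary association matrix.
#' @param ontology optional [disease_ontology()].
#' @param ms optional miRNA functional similarity matrix.
#' @param ... pipeline parameters forwarded to the fitting engine
#'   (`kernel`, `ialm`, `propagation`, `weights`, `orientation`,
#'   `decompose`, `semantic`).
#' @param max_folds optionally subsample this many held-out pairs (an
#'   approximation for quick runs); `NULL` runs every fold.
#' @param fold_seed seed for the subsampling draw.
#' @param refit_similarity recompute the interaction-profile kernels from
#'   each fold's training matrix (the default; freezing them leaks the
#'   held-out label through the kernel).
#' @return an object of class `mdhgi_cv`: `auc`, `roc` (data.frame), and
#'   `per_test_rank` (normalized rank and candidate count per fold).
#' @export
global_loocv <- function(catalog, ontology = NULL, ms = NULL, ...,
                         max_folds = NULL, fold_seed = 1L,
                         refit_similarity = TRUE) {
  cv_loocv(catalog, ontology, ms, pool = "global", max_folds = max_folds,
           fold_seed = fold_seed, refit_similarity = refit_similarity, ...)
}

#' Local leave-one-out cross-validation
#'
#' As [global_loocv()], but the held-out pair is ranked only against the
#' unknown miRNAs of its own disease.
#'
#' @inheritParams global_loocv
#' @return an object of class `mdhgi_cv`.
#' @export
local_loocv <- function(catalog, ontology = NULL, ms = NULL, ...,
                        max_folds = NULL, fold_seed = 1L,
                        refit_similarity = TRUE) {
  cv_loocv(catalog, ontology, ms, pool = "local", max_folds = max_folds,
           fold_seed = fold_seed, refit_similarity = refit_similarity, ...)
}

cv_loocv <- function(catalog, ontology, ms, pool, max_folds, fold_seed,
                     refit_similarity, semantic = semantic_control(), ...) {
  A <- if (inherits(catalog, "association_catalog"))
    build_adjacency(catalog) else catalog
  pairs <- which(A == 1, arr.ind = TRUE)
  if (nrow(pairs) < 2L) stop("need at least 2 associations", call. = FALSE)
  ss <- if (!is.null(ontology))
    semantic_similarity(ontology, semantic, diseases = colnames(A))
  idx <- seq_len(nrow(pairs))
  if (!is.null(max_folds) && max_folds < length(idx)) {
    old <- local_seed(fold_seed)
    idx <- sort(sample(idx, max_folds))
    restore_seed(old)
  }
  if (pool == "local") {
    # skip (with a warning) diseases whose candidate pool is empty
    ncand <- colSums(A == 0)
    empty <- ncand[pairs[idx, 2L]] == 0
    if (any(empty)) {
      warning(sum(empty), " fold(s) skipped: disease has no candidate miRNAs",
              call. = FALSE)
      idx <- idx[!empty]
    }
  }
  per_test <- run_cv_folds(A, pairs, as.list(idx), ss, ms, pool = pool,
                           refit_similarity = refit_similarity, ...)
  cv_report(per_test, scheme = paste0(pool, "_loocv"))
}

#' Repeated k-fold cross-validation
#'
#' Per repeat, the known associations are split at random into `k`
#' equal-size folds; each fold is zeroed in turn, the pipeline is refit, and
#' the fold's pairs are ranked against all unknown pairs.  The per-repeat
#' AUCs give the reported mean and standard deviation.
#'
#' @inheritParams global_loocv
#' @param k number of folds (default 5).
#' @param repeats number of random re-partitions.
#' @param seed master seed; each repeat draws its partition from a
#'   sub-stream of this seed, so reports are reproducible bit-for-bit.
#' @return an object of class `mdhgi_cv` with `auc` (mean over repeats),
#'   `auc_sd`, `auc_per_repeat` and pooled `roc`.
#' @export
kfold_cv <- function(catalog, ontology = NULL, ms = NULL, k = 5L,
                     repeats = 100L, seed = 1L, ...,
                     refit_similarity = TRUE,
                     semantic = semantic_control()) {
  A <- if (inherits(catalog, "association_catalog"))
    build_adjacency(catalog) else catalog
  pairs <- which(A == 1, arr.ind = TRUE)
  if (nrow(pairs) < k) stop("fewer associations than folds", call. = FALSE)
  ss <- if (!is.null(ontology))
    semantic_similarity(ontology, semantic, diseases = colnames(A))
  reports <- vector("list", repeats)
  aucs <- numeric(repeats)
  for (r in seq_len(repeats)) {
    old <- local_seed(seed + r - 1L)
    perm <- sample(nrow(pairs))
    restore_seed(old)
    folds <- split(perm, rep_len(seq_len(k), length(perm)))
    per_test <- run_cv_folds(A, pairs, folds, ss, ms, pool = "global",
                             refit_similarity = refit_similarity, ...)
    per_test$repeat_id <- r
    reports[[r]] <- per_test
    aucs[r] <- rank_roc(per_test$norm_rank)$auc
  }
  per_test <- do.call(rbind, reports)
  rep <- cv_report(per_test, scheme = sprintf("%d-fold x %d", k, repeats),
                   seed = seed, auc_per_repeat = aucs)
  rep$auc <- mean(aucs)
  rep
}

# Seed a private RNG scope and return what is needed to restore the caller's
# RNG state afterwards, so package functions do not clobber user streams.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
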