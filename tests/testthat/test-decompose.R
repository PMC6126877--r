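test_that("singular value thresholding shrinks the spectrum", {
  set.seed(41)
  M <- matrix(rnorm(20), 5, 4)
  expect_equal(svt(M, 0), M, tolerance = 1e-10)
  expect_equal(svt(diag(c(3, 1)), 2), diag(c(1, 0)))
  expect_equal(svt(M, max(svd(M)$d) + 1), matrix(0, 5, 4))
  # singular values of the result are the shrunk originals
  d <- svd(M)$d
  expect_equal(svd(svt(M, 0.5))$d, pmax(d - 0.5, 0), tolerance = 1e-10)
})

test_that("column-wise shrinkage matches the closed form", {
  Q <- cbind(c(3, 4), c(0.3, 0.4))
  S <- l21_shrink(Q, 1)
  expect_equal(S[, 1], c(2.4, 3.2))   # norm 5, scale 1 - 1/5
  expect_equal(S[, 2], c(0, 0))       # norm 0.5 <= 1, zeroed
  expect_equal(l21_shrink(Q, 0), Q)
  # it is the proximal operator: objective no larger than nearby points
  set.seed(42)
  Q2 <- matrix(rnorm(12), 3)
  P <- l21_shrink(Q2, 0.7)
  obj <- function(E) 0.7 * l21_norm(E) + 0.5 * sum((E - Q2)^2)
  for (i in 1:20)
    expect_lte(obj(P), obj(P + matrix(rnorm(12, sd = .05), 3)) + 1e-12)
})

test_that("IALM reaches feasibility and matches the convex oracle", {
  set.seed(43)
  for (rep in 1:6) {
    A <- random_binary(sample(4:8, 1), sample(4:8, 1))
    fit <- ialm_lrr(A)
    expect_true(fit$converged)
    r <- fit$residuals[fit$iterations, ]
    expect_lte(r$constraint, 1e-8)
    expect_lte(r$split, 1e-8)
    # objective within 1% of the independent primal-dual optimum
    o <- pdhg_lrr(A, iter = 20000)
    expect_lt(abs(fit$objective - o$objective) / o$objective, 0.01)
  }
})

test_that("low-rank structure is recovered and corruption lands in E", {
  # duplicated columns, no noise: coefficient rank cannot exceed rank(A).
  # The balance weight is set so the self-expression term is active on a
  # matrix this small (the weight trades off against the total column mass,
  # so tiny instances need a larger value than the full-scale default).
  ctl <- ialm_control(alpha = 0.5)
  base <- cbind(c(1, 1, 1, 0, 0, 0), c(0, 0, 1, 1, 1, 1))
  A <- base[, c(1, 1, 2, 2)] * 1
  dimnames(A) <- list(paste0("m", 1:6), paste0("d", 1:4))
  fit <- ialm_lrr(A, ctl)
  expect_lte(sum(svd(fit$X)$d > 1e-6), qr(A)$rank)
  expect_lt(sqrt(sum(fit$E^2)) / sqrt(sum(A^2)), 0.05)
  # and the solution is the convex optimum
  ref <- pdhg_lrr(A, alpha = 0.5, iter = 20000)
  expect_lt(abs(fit$objective - ref$objective) / ref$objective, 0.01)

  # corrupt one entry of one member of a triplicated column: the majority
  # pins down the clean pattern, so the corrupted column carries the
  # largest share of the residual's column norms
  At <- base[, c(1, 1, 1, 2, 2)] * 1
  dimnames(At) <- list(paste0("m", 1:6), paste0("d", 1:5))
  At[5, 1] <- 1
  fitc <- ialm_lrr(At, ctl)
  cn <- sqrt(colSums(fitc$E^2))
  expect_equal(unname(which.max(cn)), 1L)
  refc <- pdhg_lrr(At, alpha = 0.5, iter = 20000)
  expect_lt(abs(fitc$objective - refc$objective) / refc$objective, 0.01)
})

test_that("identity dictionary degenerates to robust PCA", {
  set.seed(7)
  L <- tcrossprod(matrix(rnorm(16), 8, 2), matrix(rnorm(16), 8, 2))
  A <- L
  A[, 7] <- rnorm(8, sd = 3)    # whole-column outliers: the l2,1 regime
  A[, 8] <- rnorm(8, sd = 3)
  fit <- ialm_lrr(A, ialm_control(alpha = 0.8), dictionary = diag(8))
  ref <- pdhg_lrr(A, alpha = 0.8, dictionary = diag(8), iter = 30000)
  expect_lt(norm(fit$X - ref$X, "F") / norm(ref$X, "F"), 0.05)
  expect_lt(abs(fit$objective - ref$objective) / ref$objective, 0.01)
  # the residual concentrates on the corrupted columns
  cn <- sqrt(colSums(fit$E^2))
  expect_gt(sum(cn[7:8]) / sum(cn), 0.9)
})

test_that("reconstruction orientations combine as defined", {
  set.seed(45)
  A <- random_binary(7, 5)
  rd <- reconstruct(A, "disease_side")
  rm_ <- reconstruct(A, "mirna_side")
  ra <- reconstruct(A, "average")
  expect_equal(ra$A_star, (rd$A_star + rm_$A_star) / 2)
  expect_equal(dim(rd$A_star), dim(A))
  expect_equal(dimnames(ra$A_star), dimnames(A))
  # disease-side coefficients are n x n, miRNA-side m x m
  expect_equal(dim(rd$disease_fit$X), c(5L, 5L))
  expect_equal(dim(rm_$mirna_fit$X), c(7L, 7L))
})

test_that("reconstruction denoises flipped low-rank association data", {
  wins <- 0L
  for (s in 1:5) {
    ds <- generate_synthetic(synth_config(seed = s, hidden_frac = 0,
                                          flip_frac = 0.15))
    r <- reconstruct(ds$observed)
    wins <- wins + (stats::cor(c(r$A_star), c(ds$A_true)) >
                      stats::cor(c(ds$observed), c(ds$A_true)))
  }
  expect_gte(wins, 4L)
})

test_that("solver rejects degenerate input and validates controls", {
  expect_error(ialm_lrr(matrix(0, 3, 3)), "all-zero")
  expect_error(ialm_control(alpha = -1), "alpha")
  expect_error(ialm_control(rho = 0.5), "rho")
  expect_error(ialm_control(tol = 2), "tol")
})
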