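#' Singular value thresholding
#'
#' Soft-thresholds the singular values of a matrix: the proximal operator of
#' the nuclear norm.
#'
#' @param M numeric matrix.
#' @param tau non-negative threshold subtracted from each singular value
#'   (floored at zero).
#' @return the thresholded matrix.
#' @export
svt <- function(M, tau) {
  stopifnot(tau >= 0)
  sv <- svd(M)
  d <- pmax(sv$d - tau, 0)
  keep <- d > 0
  if (!any(keep)) return(matrix(0, nrow(M), ncol(M)))
  sv$u[, keep, drop = FALSE] %*% (d[keep] * t(sv$v[, keep, drop = FALSE]))
}

#' Column-wise l2 shrinkage
#'
#' Proximal operator of `tau` times the l2,1 norm (sum of column Euclidean
#' norms): each column is scaled by `max(1 - tau/||q||, 0)`, zeroing columns
#' whose norm does not exceed the threshold.
#'
#' @param Q numeric matrix.
#' @param tau non-negative threshold.
#' @return the shrunk matrix.
#' @export
l21_shrink <- function(Q, tau) {
  stopifnot(tau >= 0)
  nrm <- sqrt(colSums(Q^2))
  scale <- ifelse(nrm > tau, 1 - tau / pmax(nrm, .Machine$double.eps), 0)
  sweep(Q, 2L, scale, `*`)
}

#' Sum of column Euclidean norms (l2,1 norm)
#'
#' @param E numeric matrix.
#' @return the l2,1 norm of `E`.
#' @export
l21_norm <- function(E) sum(sqrt(colSums(E^2)))

#' Nuclear norm (sum of singular values)
#'
#' @param X numeric matrix.
#' @return the nuclear norm of `X`.
#' @export
nuclear_norm <- function(X) sum(svd(X, nu = 0, nv = 0)$d)

#' Low-rank self-expressive decomposition by inexact ALM
#'
#' Solves `min ||X||_* + alpha ||E||_{2,1}  s.t.  D = D X + E` (with
#' `D = A` by default: the matrix is expressed in terms of its own columns).
#' The equivalent split problem with auxiliary `J = X` is solved by
#' alternating closed-form updates of `J` (singular value thresholding),
#' `X` (a linear system) and `E` (column-wise shrinkage), followed by
#' gradient ascent on the two Lagrange multipliers and growth of the penalty
#' `mu`.  Setting `dictionary` to the identity matrix degenerates the model
#' to robust PCA (with a column-sparse noise term).
#'
#' @param A numeric matrix to decompose (constraint right-hand side).
#' @param control an [ialm_control()] list.
#' @param dictionary left factor `D` in the constraint `A = D X + E`;
#'   defaults to `A` itself.
#' @return an object of class `ialm_lrr`: list with `X` (coefficients), `E`
#'   (residual), `A_star` (`D %*% X`), `iterations`, `residuals`
#'   (per-iteration data.frame with both relative residuals), `converged`,
#'   `objective` (`||X||_* + alpha ||E||_{2,1}`).
#' @export
ialm_lrr <- function(A, control = ialm_control(), dictionary = A) {
  stopifnot(is.matrix(A), all(is.finite(A)))
  if (all(A == 0)) stop("cannot decompose an all-zero matrix", call. = FALSE)
  D <- dictionary
  stopifnot(is.matrix(D), nrow(D) == nrow(A))
  k <- ncol(D)
  n <- ncol(A)
  alpha <- control$alpha
  mu <- control$mu0
  X <- J <- matrix(0, k, n)
  E <- matrix(0, nrow(A), n)
  Y1 <- matrix(0, nrow(A), n)
  Y2 <- matrix(0, k, n)
  normA <- sqrt(sum(A^2))
  DtD <- crossprod(D)
  sys <- DtD + diag(k)            # coefficient of the X-update, fixed
  ch <- chol(sys)
  res1 <- res2 <- numeric(0)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(control$max_iter)) {
    J <- svt(X + Y2 / mu, 1 / mu)
    X <- backsolve(ch, backsolve(ch, crossprod(D, A - E + Y1 / mu) +
                                    J - Y2 / mu, transpose = TRUE))
    E <- l21_shrink(A - D %*% X + Y1 / mu, alpha / mu)
    R1 <- A - D %*% X - E
    R2 <- X - J
    Y1 <- Y1 + mu * R1
    Y2 <- Y2 + mu * R2
    mu <- min(control$rho * mu, control$mu_max)
    r1 <- sqrt(sum(R1^2)) / normA
    r2 <- sqrt(sum(R2^2)) / normA
    res1 <- c(res1, r1)
    res2 <- c(res2, r2)
    if (!is.finite(r1) || !is.finite(r2))
      stop("solver produced non-finite values at iteration ", it,
           call. = FALSE)
    if (r1 <= control$tol && r2 <= control$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("IALM did not converge within ", control$max_iter, " iterations",
            call. = FALSE)
  structure(list(X = X, E = E, A_star = D %*% X,
                 iterations = it,
                 residuals = data.frame(iteration = seq_along(res1),
                                        constraint = res1, split = res2),
                 converged = converged,
                 objective = nuclear_norm(X) + alpha * l21_norm(E),
                 alpha = alpha),
            class = "ialm_lrr")
}

#' @export
print.ialm_lrr <- function(x, ...) {
  cat("Self-expressive low-rank decomposition (IALM)\n",
      " coefficients: ", nrow(x$X), "x", ncol(x$X),
      "; iterations: ", x$iterations,
      "; converged: ", x$converged, "\n",
      " objective ||X||_* + alpha||E||_2,1 = ", format(x$objective), "\n",
      sep = "")
  invisible(x)
}

#' Reconstruct a denoised association matrix
#'
#' Runs the self-expressive decomposition on the binary association matrix
#' and projects it onto the learned coefficients: `A_star = A %*% X`.  The
#' decomposition can express diseases in terms of diseases (columns,
#' `"disease_side"`), miRNAs in terms of miRNAs (rows of `A`, i.e. columns
#' of `t(A)`, `"mirna_side"`), or average the two reconstructions
#' (`"average"`, the default, treating the two readings symmetrically).
#' Entries of the reconstruction are relative ranking scores and are not
#' clamped to \[0, 1\].
#'
#' @param A binary miRNA x disease association matrix.
#' @param orientation `"average"`, `"disease_side"` or `"mirna_side"`.
#' @param control an [ialm_control()] list.
#' @return list with `A_star` (the reconstruction, dimnames of `A`),
#'   `orientation`, and the underlying `ialm_lrr` fits (`disease_fit`,
#'   `mirna_fit`; `NULL` when not computed).
#' @export
reconstruct <- function(A, orientation = c("average", "disease_side",
                                           "mirna_side"),
                        control = ialm_control()) {
  orientation <- match.arg(orientation)
  fit_d <- fit_m <- NULL
  if (orientation %in% c("average", "disease_side"))
    fit_d <- ialm_lrr(A, control)
  if (orientation %in% c("average", "mirna_side"))
    fit_m <- ialm_lrr(t(A), control)
  A_star <- switch(orientation,
                   disease_side = fit_d$A_star,
                   mirna_side = t(fit_m$A_star),
                   average = (fit_d$A_star + t(fit_m$A_star)) / 2)
  dimnames(A_star) <- dimnames(A)
  list(A_star = A_star, orientation = orientation,
       disease_fit = fit_d, mirna_fit = fit_m)
}
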