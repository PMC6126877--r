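#' Primal-dual solver for the self-expressive decomposition
#'
#' Solves the same convex program as [ialm_lrr()] —
#' `min ||X||_* + alpha ||A - D X||_{2,1}` — with the Chambolle-Pock
#' primal-dual hybrid gradient method after eliminating the residual
#' (`E = A - D X`).  The algorithm shares no code path with the IALM solver
#' (fixed step sizes, no penalty schedule, no auxiliary split variable), so
#' it serves as an independent cross-check on small instances; its O(1/N)
#' rate makes it impractical at scale, which is why [ialm_lrr()] is the
#' production solver.
#'
#' @param A numeric matrix (constraint right-hand side).
#' @param alpha positive l2,1 weight.
#' @param dictionary left factor `D`; defaults to `A` (self-expressive), use
#'   the identity for the robust-PCA degeneration.
#' @param iter number of primal-dual iterations.
#' @return list with `X`, `E = A - D X`, and `objective`.
#' @export
pdhg_lrr <- function(A, alpha = 0.1, dictionary = A, iter = 20000L) {
  stopifnot(is.matrix(A), alpha > 0)
  D <- dictionary
  L <- max(svd(D, nu = 0, nv = 0)$d)
  if (L == 0) stop("zero dictionary", call. = FALSE)
  tau <- 0.95 / L
  sigma <- 0.95 / L
  k <- ncol(D)
  X <- Xbar <- matrix(0, k, ncol(A))
  Z <- matrix(0, nrow(A), ncol(A))            # dual of D %*% X
  prox_g <- function(V, t) {
    # prox of t * alpha*||A - .||_{2,1} at V: Y = A - shrink(A - V, t*alpha)
    A - l21_shrink(A - V, t * alpha)
  }
  for (i in seq_len(iter)) {
    V <- Z + sigma * (D %*% Xbar)
    Z <- V - sigma * prox_g(V / sigma, 1 / sigma)
    Xold <- X
    X <- svt(X - tau * crossprod(D, Z), tau)
    Xbar <- 2 * X - Xold
  }
  E <- A - D %*% X
  list(X = X, E = E, objective = nuclear_norm(X) + alpha * l21_norm(E))
}
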