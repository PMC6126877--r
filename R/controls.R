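#' Control parameters for the sparse low-rank decomposition solver
#'
#' Hyperparameters of the inexact augmented Lagrange multiplier (IALM) solver
#' for the self-expressive decomposition \eqn{A = AX + E} with objective
#' \eqn{\|X\|_* + \alpha \|E\|_{2,1}}.
#'
#' @param alpha positive weight balancing the nuclear-norm (low-rank) term
#'   against the l2,1 (column-sparse noise) term.  Default 0.1.
#' @param mu0 initial value of the augmented Lagrangian penalty \eqn{\mu}.
#' @param rho multiplicative growth factor for \eqn{\mu} per iteration
#'   (\eqn{\rho \ge 1}).
#' @param mu_max ceiling for \eqn{\mu}.
#' @param tol relative Frobenius tolerance on both constraint residuals
#'   (\eqn{A - AX - E} and \eqn{X - J}) at which the solver stops.
#' @param max_iter maximum number of outer iterations.
#' @return a named list of validated solver settings.
#' @export
ialm_control <- function(alpha = 0.1, mu0 = 1e-6, rho = 1.1,
                         mu_max = 1e10, tol = 1e-8, max_iter = 1000L) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  if (alpha <= 0) stop("'alpha' must be > 0", call. = FALSE)
  if (mu0 <= 0) stop("'mu0' must be > 0", call. = FALSE)
  if (rho < 1) stop("'rho' must be >= 1", call. = FALSE)
  if (mu_max <= 0) stop("'mu_max' must be > 0", call. = FALSE)
  if (tol <= 0 || tol >= 1) stop("'tol' must be in (0, 1)", call. = FALSE)
  if (max_iter < 1) stop("'max_iter' must be >= 1", call. = FALSE)
  list(alpha = alpha, mu0 = mu0, rho = rho, mu_max = mu_max,
       tol = tol, max_iter = as.integer(max_iter))
}

#' Control parameters for heterogeneous-graph propagation
#'
#' @param a decay factor in (0,1) weighting the network-propagation term
#'   against the reconstructed association anchor.  Default 0.4.
#' @param cutoff convergence cutoff on the entrywise L1 change between
#'   successive score matrices.  Default 1e-6.
#' @param max_iter iteration cap.
#' @return a named list of validated propagation settings.
#' @export
propagation_control <- function(a = 0.4, cutoff = 1e-6, max_iter = 1000L) {
  if (!is.numeric(a) || length(a) != 1L || a <= 0 || a >= 1)
    stop("'a' must be in (0, 1)", call. = FALSE)
  if (cutoff <= 0) stop("'cutoff' must be > 0", call. = FALSE)
  if (max_iter < 1) stop("'max_iter' must be >= 1", call. = FALSE)
  list(a = a, cutoff = cutoff, max_iter = as.integer(max_iter))
}

#' Control parameters for Gaussian interaction-profile kernels
#'
#' @param beta_d original bandwidth for the disease kernel (the data-driven
#'   bandwidth is `beta_d` divided by the mean squared profile norm).
#' @param beta_r original bandwidth for the miRNA kernel.
#' @return a named list of validated kernel settings.
#' @export
kernel_control <- function(beta_d = 1, beta_r = 1) {
  if (beta_d <= 0 || beta_r <= 0)
    stop("kernel bandwidth parameters must be > 0", call. = FALSE)
  list(beta_d = beta_d, beta_r = beta_r)
}

#' Control parameters for disease semantic similarity
#'
#' @param delta semantic contribution decay factor in (0, 1]; each step from a
#'   disease to an ancestor multiplies the contribution by `delta`.
#'   Default 0.5.
#' @param log_base base of the logarithm used by the DAG-frequency
#'   (information-content) contribution model.  Default `exp(1)`.
#' @return a named list of validated semantic-similarity settings.
#' @export
semantic_control <- function(delta = 0.5, log_base = exp(1)) {
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0 || delta > 1)
    stop("'delta' must be in (0, 1]", call. = FALSE)
  if (log_base <= 1) stop("'log_base' must be > 1", call. = FALSE)
  list(delta = delta, log_base = log_base)
}

#' Edge weights for the heterogeneous graph
#'
#' Scalar weights applied to the (already normalized) miRNA-miRNA and
#' disease-disease similarity blocks, used for sensitivity analyses of the
#' similarity data.  The miRNA-disease block weight multiplies the
#' reconstructed association matrix.
#'
#' @param w_mm weight for miRNA-miRNA edges in \[0, 1\].
#' @param w_dd weight for disease-disease edges in \[0, 1\].
#' @param w_md weight for miRNA-disease edges in \[0, 1\] (kept at 1 in the
#'   standard model).
#' @return a named list of validated edge weights.
#' @export
edge_weights <- function(w_mm = 1, w_dd = 1, w_md = 1) {
  w <- c(w_mm = w_mm, w_dd = w_dd, w_md = w_md)
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1))
    stop("edge weights must lie in [0, 1]", call. = FALSE)
  as.list(w)
}
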