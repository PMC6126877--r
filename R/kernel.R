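#' Gaussian interaction-profile kernel similarity
#'
#' The interaction profile of a disease (miRNA) is its column (row) of the
#' binary association matrix.  The kernel bandwidth is the control bandwidth
#' divided by the mean squared profile norm, so the similarity scale adapts
#' to the density of the association data.
#'
#' @param A binary miRNA x disease association matrix with dimnames.
#' @param axis `"diseases"` (profiles are columns) or `"mirnas"` (rows).
#' @param control a [kernel_control()] list.
#' @return a [similarity_matrix()] of kind `"GD"` (diseases) or `"GR"`
#'   (miRNAs), diagonal exactly 1.
#' @export
gip_kernel <- function(A, axis = c("diseases", "mirnas"),
                       control = kernel_control()) {
  axis <- match.arg(axis)
  stopifnot(is.matrix(A))
  P <- if (axis == "diseases") t(A) else A          # profiles as rows
  beta_prime <- if (axis == "diseases") control$beta_d else control$beta_r
  nrm2 <- rowSums(P^2)
  if (mean(nrm2) == 0)
    stop("all interaction profiles are zero; kernel bandwidth undefined",
         call. = FALSE)
  beta <- beta_prime / mean(nrm2)
  G <- tcrossprod(P)
  d2 <- outer(nrm2, nrm2, `+`) - 2 * G               # squared distances
  d2[d2 < 0] <- 0                                    # numerical floor
  K <- exp(-beta * d2)
  diag(K) <- 1
  dimnames(K) <- list(rownames(P), rownames(P))
  similarity_matrix(K, kind = if (axis == "diseases") "GD" else "GR")
}

#' Integrate semantic and kernel similarity for diseases
#'
#' Where both diseases have a DAG (semantic similarity defined) the
#' integrated similarity is the mean of semantic and kernel similarity;
#' otherwise it falls back to the kernel similarity alone.
#'
#' @param ss disease semantic similarity (may contain `NA` for DAG-less
#'   diseases).
#' @param gd disease interaction-profile kernel similarity, same index.
#' @param has_dag named logical over the shared index; defaults to the
#'   `has_dag` attribute of `ss`.
#' @return a [similarity_matrix()] of kind `"SD"`.
#' @export
integrate_disease <- function(ss, gd, has_dag = attr(ss, "has_dag")) {
  if (!identical(dimnames(ss), dimnames(gd)))
    stop("similarity matrices are indexed differently", call. = FALSE)
  if (is.null(has_dag)) stop("'has_dag' mask is required", call. = FALSE)
  has_dag <- has_dag[rownames(gd)]
  both <- outer(has_dag, has_dag, `&`)
  S <- unclass(gd)
  ssm <- unclass(ss)
  use <- both & !is.na(ssm)
  S[use] <- (ssm[use] + S[use]) / 2
  similarity_matrix(S, kind = "SD")
}

#' Integrate functional and kernel similarity for miRNAs
#'
#' Where both miRNAs are covered by the functional similarity matrix the
#' integrated similarity is the mean of functional and kernel similarity;
#' otherwise it falls back to the kernel similarity alone.
#'
#' @param ms miRNA functional similarity matrix; may cover only a subset of
#'   the kernel's miRNAs, and may contain `NA` for undefined pairs.
#' @param gr miRNA interaction-profile kernel similarity (defines the output
#'   index).
#' @return a [similarity_matrix()] of kind `"SR"`.
#' @export
integrate_mirna <- function(ms, gr) {
  mirnas <- rownames(gr)
  S <- unclass(gr)
  pos <- match(mirnas, rownames(ms))
  covered <- !is.na(pos)
  if (any(covered)) {
    sub <- unclass(ms)[pos[covered], pos[covered], drop = FALSE]
    both <- which(outer(covered, covered, `&`))
    msfull <- matrix(NA_real_, length(mirnas), length(mirnas))
    msfull[outer(covered, covered, `&`)] <- sub
    use <- !is.na(msfull)
    S[use] <- (msfull[use] + S[use]) / 2
  }
  similarity_matrix(S, kind = "SR")
}

#' Symmetric (degree) normalization of a similarity matrix
#'
#' Divides every entry by the square root of the product of its row and
#' column sums, the normalization under which the propagation iteration is
#' guaranteed to converge.  Rows/columns with zero sum are left as zeros.
#'
#' @param s raw, non-negative, symmetric similarity matrix.
#' @return the normalized matrix (attribute `normalized = TRUE`, same kind).
#' @export
symmetric_normalize <- function(s) {
  S <- unclass(s)
  if (anyNA(S)) stop("normalize after integration: NA entries present",
                     call. = FALSE)
  if (min(S) < -1e-12) stop("negative entries in similarity matrix",
                            call. = FALSE)
  d <- rowSums(S)
  scale <- ifelse(d > 0, 1 / sqrt(d), 0)
  N <- S * tcrossprod(scale)
  kind <- attr(s, "kind")
  similarity_matrix(N, kind = if (is.null(kind)) "SD" else kind,
                    normalized = TRUE)
}

#' Scale the normalized similarity blocks of the heterogeneous graph
#'
#' Multiplies the normalized miRNA-miRNA and disease-disease similarity
#' matrices by scalar weights (the miRNA-disease weight is applied to the
#' reconstructed association matrix by the caller).  Scaling must happen
#' after normalization: a uniform pre-normalization scaling cancels exactly
#' in the degree normalization, so only post-normalization weights have any
#' effect.
#'
#' @param sr_norm normalized miRNA similarity.
#' @param sd_norm normalized disease similarity.
#' @param weights an [edge_weights()] list.
#' @return list with scaled `sr` and `sd` (still flagged normalized).
#' @export
apply_edge_weights <- function(sr_norm, sd_norm, weights = edge_weights()) {
  if (!isTRUE(attr(sr_norm, "normalized")) ||
      !isTRUE(attr(sd_norm, "normalized")))
    stop("edge weights apply to normalized similarity matrices", call. = FALSE)
  sr <- unclass(sr_norm) * weights$w_mm
  sd <- unclass(sd_norm) * weights$w_dd
  attributes(sr) <- attributes(sr_norm)
  attributes(sd) <- attributes(sd_norm)
  list(sr = sr, sd = sd)
}
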