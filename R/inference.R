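#' Single-pass path score between one miRNA and one disease
#'
#' Sums the weights of all length-three paths miRNA'-miRNA-...-disease:
#' `sum_i sum_j SR(m_i, m) * A_star(m_i, d_j) * SD(d_j, d)`.  This is the
#' scalar form of one propagation product and serves as an oracle for a
#' single iteration of [propagate()].
#'
#' @param m miRNA name.
#' @param d disease name.
#' @param sr miRNA similarity matrix (rows/cols miRNAs).
#' @param sd disease similarity matrix (rows/cols diseases).
#' @param a_star reconstructed association matrix (miRNAs x diseases).
#' @return the path score (a single number).
#' @export
path_score <- function(m, d, sr, sd, a_star) {
  if (!m %in% rownames(sr)) stop("unknown miRNA '", m, "'", call. = FALSE)
  if (!d %in% rownames(sd)) stop("unknown disease '", d, "'", call. = FALSE)
  drop(crossprod(unclass(sr)[, m], a_star %*% unclass(sd)[, d]))
}

#' Heterogeneous-graph score propagation
#'
#' Iterates `P <- a * SR %*% P %*% SD + (1 - a) * A_star` from `P0 = A_star`
#' until the entrywise L1 change between successive iterates falls below the
#' cutoff.  Both similarity matrices must be symmetrically normalized
#' ([symmetric_normalize()]); with that normalization the iteration
#' converges for any decay factor in (0, 1), and the fixed point does not
#' depend on the starting matrix.
#'
#' @param sr_norm normalized miRNA similarity (m x m).
#' @param sd_norm normalized disease similarity (n x n).
#' @param a_star reconstructed association matrix (m x n).
#' @param control a [propagation_control()] list.
#' @param P0 optional starting matrix (defaults to `a_star`).
#' @return an object of class `mdhgi_scores`: list with `P` (score matrix),
#'   `iterations`, `final_change`, `converged`.
#' @export
propagate <- function(sr_norm, sd_norm, a_star,
                      control = propagation_control(), P0 = a_star) {
  if (!isTRUE(attr(sr_norm, "normalized")) ||
      !isTRUE(attr(sd_norm, "normalized")))
    stop("propagate() requires symmetrically normalized similarity matrices",
         call. = FALSE)
  stopifnot(nrow(sr_norm) == nrow(a_star), nrow(sd_norm) == ncol(a_star))
  a <- control$a
  SR <- unclass(sr_norm)
  SD <- unclass(sd_norm)
  anchor <- (1 - a) * a_star
  P <- P0
  converged <- FALSE
  change <- Inf
  it <- 0L
  for (it in seq_len(control$max_iter)) {
    Pn <- a * (SR %*% P %*% SD) + anchor
    change <- sum(abs(Pn - P))
    P <- Pn
    if (change < control$cutoff) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("propagation did not converge within ", control$max_iter,
            " iterations (last L1 change ", format(change), ")",
            call. = FALSE)
  dimnames(P) <- dimnames(a_star)
  structure(list(P = P, iterations = it, final_change = change,
                 converged = converged),
            class = "mdhgi_scores")
}

#' @export
print.mdhgi_scores <- function(x, ...) {
  cat("Propagated score matrix: ", nrow(x$P), " x ", ncol(x$P),
      "; iterations: ", x$iterations,
      "; final L1 change: ", format(x$final_change), "\n", sep = "")
  invisible(x)
}

#' Rank candidate miRNAs for one disease
#'
#' Candidates are the miRNAs with no known association with the disease in
#' the training matrix; known-associated miRNAs never appear in the list.
#' Ties are broken alphabetically by miRNA name for determinism.
#'
#' @param P score matrix (miRNAs x diseases) or an `mdhgi_scores` object.
#' @param A_train binary training association matrix, same dimnames.
#' @param disease disease name.
#' @return data.frame with columns `mirna`, `score`, `rank`, sorted by
#'   decreasing score.
#' @export
rank_for_disease <- function(P, A_train, disease) {
  if (inherits(P, "mdhgi_scores")) P <- P$P
  disease <- tolower(trimws(disease))
  if (!disease %in% colnames(P))
    stop("unknown disease '", disease, "'", call. = FALSE)
  cand <- rownames(P)[A_train[, disease] == 0]
  s <- P[cand, disease]
  ord <- order(-s, cand)
  data.frame(mirna = cand[ord], score = unname(s[ord]),
             rank = seq_along(ord), stringsAsFactors = FALSE,
             row.names = NULL)
}
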