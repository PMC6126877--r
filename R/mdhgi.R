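#' Fit the matrix-decomposition + heterogeneous-graph association model
#'
#' End-to-end predictor of miRNA-disease association scores.  The pipeline:
#' (1) build the binary association matrix from the catalog; (2) compute
#' disease semantic similarity from the ontology (two contribution models,
#' averaged) and take the miRNA functional similarity as given; (3) compute
#' Gaussian interaction-profile kernel similarities for both node types from
#' the association matrix and integrate them with the semantic/functional
#' similarities (kernel-only fallback where the latter are undefined);
#' (4) symmetrically normalize both integrated similarities; (5) denoise the
#' association matrix by the l2,1-regularized low-rank self-expressive
#' decomposition ([ialm_lrr()]); (6) propagate the reconstruction over the
#' heterogeneous graph ([propagate()]) to the fixed point.
#'
#' @param catalog an [association_catalog()], or a binary miRNA x disease
#'   matrix with dimnames.
#' @param ontology optional [disease_ontology()]; when `NULL` disease
#'   similarity is the interaction-profile kernel alone.
#' @param ms optional miRNA functional similarity matrix; when `NULL` miRNA
#'   similarity is the interaction-profile kernel alone.
#' @param semantic a [semantic_control()] list.
#' @param kernel a [kernel_control()] list.
#' @param ialm an [ialm_control()] list.
#' @param propagation a [propagation_control()] list.
#' @param weights an [edge_weights()] list.
#' @param orientation decomposition orientation passed to [reconstruct()].
#' @param decompose if `FALSE`, skip the decomposition and propagate the raw
#'   association matrix (ablation).
#' @return an object of class `mdhgi`: list with `scores` (miRNA x disease
#'   matrix), `A` (training matrix), `A_star` (reconstruction), `SR`/`SD`
#'   (normalized, weighted similarities), `decomposition` (from
#'   [reconstruct()], `NULL` when disabled), `propagation` (iterations,
#'   final change, convergence flag), `params`, `call`.
#' @seealso [predict.mdhgi()], [rank_for_disease()], [global_loocv()],
#'   [kfold_cv()], [generate_synthetic()]
#' @examples
#' set.seed(1)
#' ds <- generate_synthetic(synth_config(n_mirnas = 15, n_diseases = 10,
#'                                       seed = 1))
#' fit <- mdhgi(ds$observed, ds$ontology, ds$ms)
#' head(predict(fit, disease = colnames(fit$A)[1]), 3)
#' @export
mdhgi <- function(catalog, ontology = NULL, ms = NULL,
                  semantic = semantic_control(),
                  kernel = kernel_control(),
                  ialm = ialm_control(),
                  propagation = propagation_control(),
                  weights = edge_weights(),
                  orientation = c("average", "disease_side", "mirna_side"),
                  decompose = TRUE) {
  orientation <- match.arg(orientation)
  A <- if (inherits(catalog, "association_catalog"))
    build_adjacency(catalog) else catalog
  stopifnot(is.matrix(A), all(A %in% c(0, 1)))
  ss <- if (!is.null(ontology))
    semantic_similarity(ontology, semantic, diseases = colnames(A))
  fit <- mdhgi_engine(A, ss = ss, ms = ms, kernel = kernel, ialm = ialm,
                      propagation = propagation, weights = weights,
                      orientation = orientation, decompose = decompose)
  fit$call <- match.call()
  fit
}

# Integrated, normalized, weighted similarity pair from one adjacency
# matrix.  Kept separate so cross-validation can freeze it when asked.
build_similarities <- function(A, ss, ms, kernel, weights) {
  gd <- gip_kernel(A, "diseases", kernel)
  gr <- gip_kernel(A, "mirnas", kernel)
  sd_raw <- if (is.null(ss)) gd else integrate_disease(ss, gd)
  sr_raw <- if (is.null(ms)) gr else integrate_mirna(ms, gr)
  apply_edge_weights(symmetric_normalize(sr_raw),
                     symmetric_normalize(sd_raw), weights)
}

# Core pipeline on a prepared adjacency matrix; `ss` is the semantic
# similarity over colnames(A) (with its has_dag attribute) or NULL.  Split
# out so cross-validation can recompute the A-dependent stages per fold while
# reusing the A-independent semantic similarity.
mdhgi_engine <- function(A, ss = NULL, ms = NULL,
                         kernel = kernel_control(),
                         ialm = ialm_control(),
                         propagation = propagation_control(),
                         weights = edge_weights(),
                         orientation = "average",
                         decompose = TRUE,
                         similarities = NULL) {
  w <- if (is.null(similarities))
    build_similarities(A, ss, ms, kernel, weights) else similarities
  dec <- NULL
  A_star <- A
  if (decompose) {
    dec <- reconstruct(A, orientation, ialm)
    A_star <- dec$A_star
  }
  A_star <- weights$w_md * A_star
  prop <- propagate(w$sr, w$sd, A_star, propagation)
  structure(list(scores = prop$P, A = A, A_star = A_star,
                 SR = w$sr, SD = w$sd,
                 decomposition = dec,
                 propagation = prop[c("iterations", "final_change",
                                      "converged")],
                 params = list(kernel = kernel, ialm = ialm,
                               propagation = propagation, weights = weights,
                               orientation = orientation,
                               decompose = decompose)),
            class = "mdhgi")
}

#' @export
print.mdhgi <- function(x, ...) {
  cat("MDHGI association model\n")
  cat("  ", nrow(x$A), " miRNAs x ", ncol(x$A), " diseases, ",
      sum(x$A), " known associations\n", sep = "")
  cat("  decomposition: ",
      if (is.null(x$decomposition)) "disabled (raw adjacency)"
      else x$decomposition$orientation, "\n", sep = "")
  cat("  propagation: ", x$propagation$iterations, " iterations, final L1 ",
      "change ", format(x$propagation$final_change), "\n", sep = "")
  invisible(x)
}

#' @export
summary.mdhgi <- function(object, ...) {
  cand <- object$scores[object$A == 0]
  out <- list(dim = dim(object$A), n_assoc = sum(object$A),
              decompose = !is.null(object$decomposition),
              propagation = object$propagation,
              score_quantiles = stats::quantile(cand,
                                                c(0, .25, .5, .75, 1)))
  class(out) <- "summary.mdhgi"
  out
}

#' @export
print.summary.mdhgi <- function(x, ...) {
  cat("MDHGI association model: ", x$dim[1L], " miRNAs x ", x$dim[2L],
      " diseases, ", x$n_assoc, " known associations\n", sep = "")
  cat("  decomposition enabled:", x$decompose, "\n")
  cat("  propagation converged:", x$propagation$converged,
      "in", x$propagation$iterations, "iterations\n")
  cat("  candidate-pair score quantiles:\n")
  print(x$score_quantiles)
  invisible(x)
}

#' Predicted association scores or ranked candidates
#'
#' With `disease = NULL` returns the full miRNA x disease score matrix.
#' With a disease name, returns the ranked candidate list for that disease
#' (known-associated miRNAs excluded), optionally truncated to the top `n`.
#'
#' @param object a fitted [mdhgi()] model.
#' @param disease optional disease name.
#' @param n number of top candidates to return (default all).
#' @param ... unused.
#' @return score matrix, or a data.frame from [rank_for_disease()].
#' @export
predict.mdhgi <- function(object, disease = NULL, n = Inf, ...) {
  if (is.null(disease)) return(object$scores)
  ranked <- rank_for_disease(object$scores, object$A, disease)
  utils::head(ranked, n)
}

#' Plot solver and propagation convergence diagnostics
#'
#' Shows the per-iteration relative constraint residuals of the
#' decomposition solver on a log scale (one panel per orientation fitted).
#'
#' @param x a fitted [mdhgi()] model with decomposition enabled.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.mdhgi <- function(x, ...) {
  if (is.null(x$decomposition))
    stop("no decomposition diagnostics: model fitted with decompose = FALSE",
         call. = FALSE)
  fits <- Filter(Negate(is.null),
                 x$decomposition[c("disease_fit", "mirna_fit")])
  old <- graphics::par(mfrow = c(1, length(fits)))
  on.exit(graphics::par(old))
  for (nm in names(fits)) {
    r <- fits[[nm]]$residuals
    graphics::matplot(r$iteration, cbind(r$constraint, r$split),
                      type = "l", log = "y", lty = 1:2, col = c(1, 2),
                      xlab = "iteration", ylab = "relative residual",
                      main = nm, ...)
    graphics::legend("topright", c("constraint", "split"), lty = 1:2,
                     col = c(1, 2), bty = "n")
  }
  invisible(x)
}
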