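#' Decay-model semantic contributions of ancestor terms
#'
#' In the decay model, a disease contributes 1 to its own semantic value and
#' every ancestor term contributes `delta` times the maximal contribution of
#' its children inside the disease's DAG, so contributions shrink
#' geometrically with distance from the disease.
#'
#' @param dag one disease's DAG: `list(terms =, edges =)` as stored in a
#'   [disease_ontology()]; the first element of `terms` is the disease
#'   itself.
#' @param control a [semantic_control()] list.
#' @return list with `contrib` (named numeric over `dag$terms`) and
#'   `semantic_value` (their sum).
#' @export
contributions_model1 <- function(dag, control = semantic_control()) {
  if (is.null(dag)) stop("disease has no DAG", call. = FALSE)
  delta <- control$delta
  terms <- dag$terms
  d0 <- terms[1L]
  contrib <- stats::setNames(rep(NA_real_, length(terms)), terms)
  contrib[d0] <- 1
  edges <- dag$edges
  # children listed before parents is not guaranteed; sweep until stable
  # (bounded by the DAG depth <= number of terms)
  for (pass in seq_along(terms)) {
    changed <- FALSE
    for (t in terms) {
      if (t == d0) next
      kids <- edges$child[edges$parent == t]
      kids <- kids[!is.na(contrib[kids])]
      if (length(kids) == 0L) next
      v <- delta * max(contrib[kids])
      if (is.na(contrib[t]) || v != contrib[t]) {
        contrib[t] <- v
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (anyNA(contrib))
    stop("DAG terms unreachable from the disease: ",
         paste(terms[is.na(contrib)], collapse = ", "), call. = FALSE)
  list(contrib = contrib, semantic_value = sum(contrib))
}

#' DAG-frequency semantic contributions of ancestor terms
#'
#' In the frequency model, a term's contribution to every disease containing
#' it is the negative log of the fraction of disease DAGs that include the
#' term, so rare (specific) terms contribute more than ubiquitous (general)
#' ones.
#'
#' @param disease disease name (must have a DAG in `ontology`).
#' @param ontology a [disease_ontology()].
#' @param control a [semantic_control()] list; `log_base` selects the
#'   logarithm base.
#' @return list with `contrib` (named numeric over the disease's terms) and
#'   `semantic_value` (their sum).
#' @export
contributions_model2 <- function(disease, ontology,
                                 control = semantic_control()) {
  stopifnot(inherits(ontology, "disease_ontology"))
  disease <- tolower(trimws(disease))
  if (!isTRUE(ontology$has_dag[disease]))
    stop("disease '", disease, "' has no DAG", call. = FALSE)
  terms <- ontology$dag[[disease]]$terms
  cnt <- ontology$dag_count[terms]
  if (anyNA(cnt) || any(cnt < 1L))
    stop("internal error: term with zero DAG count", call. = FALSE)
  contrib <- -log(cnt / ontology$n_dag_diseases, base = control$log_base)
  names(contrib) <- terms
  list(contrib = contrib, semantic_value = sum(contrib))
}

#' Pairwise disease semantic similarity
#'
#' For two DAG-bearing diseases the similarity is the sum, over shared
#' ancestor terms, of both diseases' contributions to those terms, divided by
#' the sum of the two semantic values.  Diseases without a DAG get `NA`
#' rows/columns (undefined, to be backfilled by the interaction-profile
#' kernel).  If both semantic values are zero (every shared term occurs in
#' every DAG under the frequency model) the similarity is defined as 0.
#'
#' @param ontology a [disease_ontology()].
#' @param model 1 (decay contributions) or 2 (DAG-frequency contributions).
#' @param control a [semantic_control()] list.
#' @param diseases names to index the output by; defaults to the ontology's
#'   disease list.  Names absent from the ontology are treated as DAG-less.
#' @return a [similarity_matrix()] of kind `"SS1"` or `"SS2"`.
#' @export
pairwise_semantic <- function(ontology, model = 1,
                              control = semantic_control(),
                              diseases = ontology$diseases) {
  stopifnot(inherits(ontology, "disease_ontology"), model %in% c(1, 2))
  diseases <- tolower(trimws(diseases))
  if (ontology$n_dag_diseases < 1L)
    stop("no disease in the ontology has a DAG", call. = FALSE)
  withdag <- diseases[diseases %in% ontology$diseases &
                        ontology$has_dag[diseases] %in% TRUE]
  tabs <- lapply(withdag, function(d) {
    if (model == 1) contributions_model1(ontology$dag[[d]], control)
    else contributions_model2(d, ontology, control)
  })
  names(tabs) <- withdag
  k <- length(diseases)
  S <- matrix(NA_real_, k, k, dimnames = list(diseases, diseases))
  for (i in seq_along(withdag)) {
    di <- withdag[i]
    ci <- tabs[[di]]
    for (j in seq_len(i)) {
      dj <- withdag[j]
      cj <- tabs[[dj]]
      shared <- intersect(names(ci$contrib), names(cj$contrib))
      denom <- ci$semantic_value + cj$semantic_value
      val <- if (denom == 0) 0 else
        sum(ci$contrib[shared] + cj$contrib[shared]) / denom
      S[di, dj] <- S[dj, di] <- val
    }
  }
  similarity_matrix(S, kind = if (model == 1) "SS1" else "SS2")
}

#' Average two semantic similarity matrices
#'
#' Entrywise mean of the decay-model and frequency-model similarities;
#' an entry undefined (`NA`) in either input stays undefined.
#'
#' @param ss1,ss2 similarity matrices over the same index.
#' @return a [similarity_matrix()] of kind `"SS"`.
#' @export
combined_semantic <- function(ss1, ss2) {
  if (!identical(dimnames(ss1), dimnames(ss2)))
    stop("similarity matrices are indexed differently", call. = FALSE)
  similarity_matrix((unclass(ss1) + unclass(ss2)) / 2, kind = "SS")
}

#' Disease semantic similarity (both models, averaged)
#'
#' Convenience wrapper computing the decay-model and frequency-model
#' similarities and their entrywise mean.
#'
#' @inheritParams pairwise_semantic
#' @return a [similarity_matrix()] of kind `"SS"`, with attribute `has_dag`
#'   (named logical over `diseases`).
#' @export
semantic_similarity <- function(ontology, control = semantic_control(),
                                diseases = ontology$diseases) {
  ss1 <- pairwise_semantic(ontology, 1, control, diseases)
  ss2 <- pairwise_semantic(ontology, 2, control, diseases)
  ss <- combined_semantic(ss1, ss2)
  diseases <- tolower(trimws(diseases))
  hd <- diseases %in% ontology$diseases & ontology$has_dag[diseases] %in% TRUE
  attr(ss, "has_dag") <- stats::setNames(hd, diseases)
  ss
}
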