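#' Configuration for the synthetic dataset generator
#'
#' Defines the statistical structure the association model assumes: a
#' low-rank true association pattern, sparse flip noise, a random disease
#' ontology, and a functional similarity matrix correlated with shared
#' associations.
#'
#' @param n_mirnas,n_diseases numbers of miRNAs and diseases.
#' @param rank latent rank of the generating matrix (>= 1).
#' @param density fraction of miRNA-disease pairs that are true
#'   associations, in (0, 1).
#' @param hidden_frac fraction of true associations withheld from the
#'   observed catalog as a recovery test set, in \[0, 1).
#' @param flip_frac fraction of all matrix entries flipped at random (the
#'   sparse noise), in \[0, 1).
#' @param dag_depth maximum depth of the random ontology term forest.
#' @param dag_frac fraction of diseases given a DAG.
#' @param ms_blend weight of the association-derived (Jaccard) component in
#'   the functional similarity matrix; the complement is uniform noise.
#' @param seed integer seed; all generator randomness derives from it.
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(n_mirnas = 40L, n_diseases = 30L, rank = 3L,
                         density = 0.1, hidden_frac = 0.2, flip_frac = 0.05,
                         dag_depth = 4L, dag_frac = 0.8, ms_blend = 0.8,
                         seed = 1L) {
  stopifnot(n_mirnas >= 2L, n_diseases >= 2L, rank >= 1L,
            rank <= min(n_mirnas, n_diseases),
            density > 0, density < 1,
            hidden_frac >= 0, hidden_frac < 1,
            flip_frac >= 0, flip_frac < 1,
            dag_depth >= 1L, dag_frac >= 0, dag_frac <= 1,
            ms_blend >= 0, ms_blend <= 1)
  structure(list(n_mirnas = as.integer(n_mirnas),
                 n_diseases = as.integer(n_diseases),
                 rank = as.integer(rank), density = density,
                 hidden_frac = hidden_frac, flip_frac = flip_frac,
                 dag_depth = as.integer(dag_depth), dag_frac = dag_frac,
                 ms_blend = ms_blend, seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic miRNA-disease dataset with ground truth
#'
#' The latent association pattern is `L = U V'` with non-negative factors of
#' the configured rank; the top `density` quantile of its entries (by count,
#' so the target density is hit exactly) becomes the true association
#' matrix.  A fraction of the true associations is withheld as
#' `hidden_truth`; a fraction of all entries is then flipped as sparse
#' noise.  The ontology is a random term forest of bounded depth with
#' DAG-bearing diseases attached beneath random terms, and the functional
#' similarity matrix blends the Jaccard similarity of true association
#' profiles with uniform noise.
#'
#' @param config a [synth_config()].
#' @return an object of class `synthetic_dataset`: list with `observed`
#'   (binary matrix, the training data), `catalog`
#'   ([association_catalog()] of the observed matrix), `hidden_truth`
#'   (data.frame of withheld true pairs), `A_true` (noise-free truth),
#'   `latent` (the generating low-rank matrix), `ontology`, `ms`, `config`.
#' @export
generate_synthetic <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  old <- local_seed(config$seed)
  on.exit(restore_seed(old))
  m <- config$n_mirnas
  n <- config$n_diseases
  mirnas <- sprintf("mir-%03d", seq_len(m))
  diseases <- sprintf("disease-%03d", seq_len(n))

  U <- matrix(stats::rgamma(m * config$rank, shape = 2, rate = 2), m)
  V <- matrix(stats::rgamma(n * config$rank, shape = 2, rate = 2), n)
  L <- U %*% t(V)
  dimnames(L) <- list(mirnas, diseases)

  k <- max(1L, round(config$density * m * n))
  A_true <- matrix(0, m, n, dimnames = dimnames(L))
  A_true[order(L, decreasing = TRUE)[seq_len(k)]] <- 1

  ones <- which(A_true == 1)
  n_hidden <- floor(config$hidden_frac * length(ones))
  hidden <- if (n_hidden > 0) sort(sample(ones, n_hidden)) else integer()
  observed <- A_true
  observed[hidden] <- 0

  n_flip <- round(config$flip_frac * m * n)
  if (n_flip > 0) {
    flippable <- setdiff(seq_len(m * n), hidden)
    flip <- sample(flippable, min(n_flip, length(flippable)))
    observed[flip] <- 1 - observed[flip]
  }
  if (sum(observed) == 0)
    stop("degenerate configuration: observed matrix has no associations",
         call. = FALSE)

  hid_idx <- arrayInd(hidden, c(m, n))
  hidden_truth <- data.frame(mirna = mirnas[hid_idx[, 1L]],
                             disease = diseases[hid_idx[, 2L]],
                             stringsAsFactors = FALSE)

  ontology <- random_ontology(diseases, config$dag_frac, config$dag_depth)
  ms <- synthetic_ms(A_true, config$ms_blend)

  structure(list(observed = observed,
                 catalog = adjacency_to_catalog(observed),
                 hidden_truth = hidden_truth,
                 A_true = A_true, latent = L,
                 ontology = ontology, ms = ms, config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic miRNA-disease dataset: ",
      nrow(x$observed), " miRNAs x ", ncol(x$observed), " diseases, ",
      sum(x$observed), " observed associations, ",
      nrow(x$hidden_truth), " hidden true pairs, rank ",
      x$config$rank, " truth\n", sep = "")
  invisible(x)
}

# Random shared term forest: terms indexed so that a term's parent always has
# a smaller index (acyclic by construction) and depth is bounded; DAG-bearing
# diseases hang beneath a uniformly chosen term.
random_ontology <- function(diseases, dag_frac, dag_depth) {
  n <- length(diseases)
  n_terms <- max(4L, ceiling(n / 2))
  terms <- sprintf("term-%03d", seq_len(n_terms))
  parent <- rep(NA_integer_, n_terms)
  depth <- rep(1L, n_terms)
  n_roots <- max(1L, ceiling(n_terms / 8))
  for (t in seq.int(n_roots + 1L, length.out = max(0L, n_terms - n_roots))) {
    ok <- which(depth[seq_len(t - 1L)] < dag_depth)
    p <- if (length(ok)) ok[sample.int(length(ok), 1L)] else NA_integer_
    parent[t] <- p
    depth[t] <- if (is.na(p)) 1L else depth[p] + 1L
  }
  with_dag <- sort(sample.int(n, round(dag_frac * n)))
  dags <- stats::setNames(vector("list", n), diseases)
  for (d in with_dag) {
    att <- sample.int(n_terms, 1L)
    chain <- att
    while (!is.na(parent[chain[length(chain)]]))
      chain <- c(chain, parent[chain[length(chain)]])
    edges <- data.frame(child = c(diseases[d], terms[chain[-length(chain)]]),
                        parent = terms[chain],
                        stringsAsFactors = FALSE)
    dags[[diseases[d]]] <- edges
  }
  disease_ontology(dags)
}

# Functional similarity: Jaccard of true association profiles blended with
# symmetric uniform noise; diagonal 1.
synthetic_ms <- function(A_true, blend) {
  m <- nrow(A_true)
  inter <- tcrossprod(A_true)
  deg <- rowSums(A_true)
  uni <- outer(deg, deg, `+`) - inter
  J <- ifelse(uni > 0, inter / uni, 0)
  noise <- matrix(stats::runif(m * m), m)
  noise <- (noise + t(noise)) / 2
  S <- blend * J + (1 - blend) * noise
  diag(S) <- 1
  dimnames(S) <- dimnames(A_true)[c(1L, 1L)]
  similarity_matrix(S, kind = "MS")
}

#' Hidden-association recovery AUC
#'
#' Scores the generator's withheld true associations against the pairs that
#' are negative in both the observed matrix and the noise-free truth, using
#' the half-credit ROC of [roc_auc()].
#'
#' @param dataset a [generate_synthetic()] result.
#' @param scores miRNA x disease score matrix (or `mdhgi_scores`).
#' @return list with `auc`, `roc`, and the counts `n_pos`, `n_neg`.
#' @export
recovery_score <- function(dataset, scores) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (inherits(scores, "mdhgi_scores")) scores <- scores$P
  pos <- as.matrix(dataset$hidden_truth[, c("mirna", "disease")])
  if (nrow(pos) == 0L) stop("dataset has no hidden truth", call. = FALSE)
  neg <- dataset$observed == 0 & dataset$A_true == 0
  s <- c(scores[pos], scores[neg])
  l <- c(rep(1, nrow(pos)), rep(0, sum(neg)))
  if (sum(neg) == 0L) stop("no never-true negative pairs", call. = FALSE)
  r <- roc_auc(s, l)
  list(auc = r$auc, roc = r$roc, n_pos = nrow(pos), n_neg = sum(neg))
}

#' Permutation p-value for an AUC
#'
#' One-sided permutation test of AUC > 0.5 by shuffling the labels over the
#' pooled scores.
#'
#' @param scores numeric score vector.
#' @param labels binary label vector.
#' @param n_perm number of permutations.
#' @param seed seed for the permutation draws.
#' @return list with `auc` (observed) and `p_value`
#'   (`(1 + #{perm AUC >= observed}) / (n_perm + 1)`).
#' @export
auc_permutation_test <- function(scores, labels, n_perm = 999L, seed = 1L) {
  obs <- roc_auc(scores, labels)$auc
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  # rank-sum formulation: AUC is a linear function of the positive ranks,
  # so permuting labels only permutes which ranks are summed
  rk <- rank(scores)
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  auc_from_ranks <- function(pos_idx)
    (sum(rk[pos_idx]) - np * (np + 1) / 2) / (np * nn)
  perm <- replicate(n_perm, auc_from_ranks(sample(length(labels), np)))
  list(auc = obs,
       p_value = (1 + sum(perm >= obs)) / (n_perm + 1))
}
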