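# Independent oracles, written directly from the model definitions and kept
# free of the package's own code paths.

# Decay-model contribution of every ancestor term, by direct recursion on
# the raw child -> parent edge list (no memoization, no topological order).
oracle_contrib1 <- function(disease, edges, delta = 0.5) {
  anc <- disease
  repeat {
    more <- setdiff(edges$parent[edges$child %in% anc], anc)
    if (!length(more)) break
    anc <- c(anc, more)
  }
  contrib_of <- function(t) {
    if (t == disease) return(1)
    kids <- intersect(edges$child[edges$parent == t], anc)
    delta * max(vapply(kids, contrib_of, 0))
  }
  vapply(anc, contrib_of, 0)
}

# Frequency-model contributions from the raw per-disease edge lists.
oracle_contrib2 <- function(disease, dags) {
  anc_of <- function(d) {
    anc <- d
    e <- dags[[d]]
    if (is.null(e)) return(anc)
    repeat {
      more <- setdiff(e$parent[e$child %in% anc], anc)
      if (!length(more)) break
      anc <- c(anc, more)
    }
    anc
  }
  withdag <- names(dags)[!vapply(dags, is.null, TRUE)]
  all_anc <- lapply(withdag, anc_of)
  names(all_anc) <- withdag
  terms <- all_anc[[disease]]
  cnt <- vapply(terms, function(t)
    sum(vapply(all_anc, function(a) t %in% a, TRUE)), 0)
  -log(cnt / length(withdag))
}

# Pairwise semantic similarity from contribution vectors.
oracle_pair_sim <- function(ci, cj) {
  shared <- intersect(names(ci), names(cj))
  denom <- sum(ci) + sum(cj)
  if (denom == 0) return(0)
  sum(ci[shared] + cj[shared]) / denom
}

# Random ontology of small per-disease DAGs over a shared term pool.
# Acyclic by construction: a term's parents always have smaller pool index.
random_dag_set <- function(n_diseases = 4L, pool = 8L, max_terms = 5L) {
  terms <- sprintf("t%02d", seq_len(pool))
  dags <- list()
  for (d in seq_len(n_diseases)) {
    name <- sprintf("dz%02d", d)
    picked <- sort(sample.int(pool, sample(1:max_terms, 1L)))
    edges <- data.frame(child = name, parent = terms[picked[length(picked)]],
                        stringsAsFactors = FALSE)
    if (length(picked) > 1L) {
      for (i in seq.int(2L, length(picked))) {
        p <- sample(picked[seq_len(i - 1L)], 1L)
        edges <- rbind(edges, data.frame(child = terms[picked[i]],
                                         parent = terms[p]))
      }
    }
    dags[[name]] <- edges
  }
  dags
}

# Brute-force AUC over all positive-negative score pairs, ties half credit.
oracle_auc <- function(scores, labels) {
  p <- scores[labels == 1]
  n <- scores[labels == 0]
  mean(outer(p, n, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Small random binary matrix with no all-zero rows or columns.
random_binary <- function(m, n, p = 0.4) {
  repeat {
    A <- matrix(rbinom(m * n, 1, p), m, n) * 1
    if (all(rowSums(A) > 0) && all(colSums(A) > 0)) break
  }
  dimnames(A) <- list(sprintf("m%02d", 1:m), sprintf("d%02d", 1:n))
  A
}
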