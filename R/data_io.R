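#' Build an association catalog from miRNA-disease pairs
#'
#' An association catalog is the package's canonical representation of a set
#' of validated miRNA-disease associations: a de-duplicated pair list plus the
#' ordered (first-appearance) name universes for both node types.
#'
#' @param mirna character vector of miRNA names.
#' @param disease character vector of disease names, same length.
#' @param quiet suppress the message reporting dropped duplicate pairs.
#' @return an object of class `association_catalog` with elements `pairs`
#'   (data.frame with columns `mirna`, `disease`), `mirnas` and `diseases`
#'   (ordered unique name vectors).
#' @export
association_catalog <- function(mirna, disease, quiet = FALSE) {
  if (length(mirna) != length(disease))
    stop("'mirna' and 'disease' must have the same length", call. = FALSE)
  if (length(mirna) == 0L)
    stop("empty association list", call. = FALSE)
  mirna <- tolower(trimws(as.character(mirna)))
  disease <- tolower(trimws(as.character(disease)))
  if (any(!nzchar(mirna)) || any(!nzchar(disease)))
    stop("empty miRNA or disease name after trimming", call. = FALSE)
  key <- paste(mirna, disease, sep = "\r")
  dup <- duplicated(key)
  if (any(dup) && !quiet)
    message("dropped ", sum(dup), " duplicate association pair(s)")
  pairs <- data.frame(mirna = mirna[!dup], disease = disease[!dup],
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs,
                 mirnas = unique(pairs$mirna),
                 diseases = unique(pairs$disease)),
            class = "association_catalog")
}

#' @export
print.association_catalog <- function(x, ...) {
  cat("Association catalog:", nrow(x$pairs), "pairs,",
      length(x$mirnas), "miRNAs,", length(x$diseases), "diseases\n")
  invisible(x)
}

#' Read a miRNA-disease association table
#'
#' Expects a two-column text file, one association per line, columns
#' separated by a tab or comma.  Lines starting with `#` are comments.
#' Names are trimmed and case-folded; duplicate pairs are dropped with a
#' message.
#'
#' @param path path to the file.
#' @param quiet suppress the duplicate-drop message.
#' @return an [association_catalog()].
#' @export
read_associations <- function(path, quiet = FALSE) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) stop("no association records in ", path, call. = FALSE)
  fields <- strsplit(lines[idx], "[\t,]")
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    bad <- idx[which(nf < 2L)[1L]]
    stop("malformed association line ", bad, " in ", path,
         " (expected at least 2 tab- or comma-separated fields)",
         call. = FALSE)
  }
  association_catalog(vapply(fields, `[[`, "", 1L),
                      vapply(fields, `[[`, "", 2L), quiet = quiet)
}

#' Write an association catalog to a tab-separated file
#'
#' @param catalog an [association_catalog()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(catalog, path) {
  stopifnot(inherits(catalog, "association_catalog"))
  utils::write.table(catalog$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Build the binary miRNA x disease adjacency matrix
#'
#' Entry (i, j) is 1 when miRNA i is associated with disease j in the
#' catalog, 0 otherwise.  Rows are miRNAs, columns diseases, both in the
#' catalog's first-appearance order.
#'
#' @param catalog an [association_catalog()].
#' @return a binary matrix with miRNA row names and disease column names.
#' @export
build_adjacency <- function(catalog) {
  stopifnot(inherits(catalog, "association_catalog"))
  if (nrow(catalog$pairs) == 0L) stop("empty catalog", call. = FALSE)
  A <- matrix(0, length(catalog$mirnas), length(catalog$diseases),
              dimnames = list(catalog$mirnas, catalog$diseases))
  A[cbind(match(catalog$pairs$mirna, catalog$mirnas),
          match(catalog$pairs$disease, catalog$diseases))] <- 1
  A
}

#' Convert a binary adjacency matrix back to an association catalog
#'
#' Inverse of [build_adjacency()]; retains row/column names as the name
#' universes even for all-zero rows or columns.
#'
#' @param A binary matrix with dimnames.
#' @return an [association_catalog()] whose `mirnas`/`diseases` cover all of
#'   `A`'s rows/columns.
#' @export
adjacency_to_catalog <- function(A) {
  stopifnot(is.matrix(A), !is.null(rownames(A)), !is.null(colnames(A)))
  w <- which(A != 0, arr.ind = TRUE)
  if (nrow(w) == 0L) stop("adjacency matrix has no associations", call. = FALSE)
  cat <- association_catalog(rownames(A)[w[, 1L]], colnames(A)[w[, 2L]],
                             quiet = TRUE)
  # keep isolated nodes in the universes, in matrix order
  cat$mirnas <- tolower(trimws(rownames(A)))
  cat$diseases <- tolower(trimws(colnames(A)))
  cat
}

# ---- disease ontology ------------------------------------------------------

#' Construct a disease ontology from per-disease DAG edge lists
#'
#' Each disease is described by the directed acyclic graph (DAG) of its
#' ancestor terms, given as child -> parent edges over a shared term
#' universe.  The ancestor set T(D) is the transitive closure of the edges
#' starting from the disease itself; `dag_count` counts, for every term, the
#' number of disease DAGs whose ancestor set contains it.
#'
#' @param dags named list; one element per disease, each either `NULL` (the
#'   disease has no DAG) or a data.frame/matrix with two character columns
#'   `child`, `parent`.
#' @return an object of class `disease_ontology` with elements `diseases`,
#'   `has_dag` (named logical), `dag` (named list of
#'   `list(terms =, edges =)`), `dag_count` (named integer over terms) and
#'   `n_dag_diseases`.
#' @export
disease_ontology <- function(dags) {
  stopifnot(is.list(dags), !is.null(names(dags)), all(nzchar(names(dags))))
  names(dags) <- tolower(trimws(names(dags)))
  diseases <- names(dags)
  has_dag <- !vapply(dags, is.null, logical(1L))
  dag <- vector("list", length(diseases))
  names(dag) <- diseases
  counts <- new.env(parent = emptyenv())
  for (d in diseases[has_dag]) {
    e <- dags[[d]]
    e <- data.frame(child = tolower(trimws(as.character(e[[1L]]))),
                    parent = tolower(trimws(as.character(e[[2L]]))),
                    stringsAsFactors = FALSE)
    terms <- ancestor_closure(d, e)
    keep <- e$child %in% terms & e$parent %in% terms
    dag[[d]] <- list(terms = terms, edges = e[keep, , drop = FALSE])
    for (t in terms)
      assign(t, (if (exists(t, counts)) get(t, counts) else 0L) + 1L, counts)
  }
  dag_count <- unlist(as.list(counts))
  structure(list(diseases = diseases,
                 has_dag = has_dag,
                 dag = dag,
                 dag_count = if (length(dag_count)) dag_count else integer(),
                 n_dag_diseases = sum(has_dag)),
            class = "disease_ontology")
}

# Transitive ancestor closure of `d` (inclusive) under child -> parent edges;
# errors on a directed cycle anywhere in the block (Kahn peeling).
ancestor_closure <- function(d, edges) {
  e <- edges
  nodes <- unique(c(e$child, e$parent))
  while (nrow(e) > 0L) {
    starts <- setdiff(nodes, e$parent)       # in-degree 0 under child->parent
    if (length(starts) == 0L)
      stop("cycle detected in the DAG of disease '", d, "'", call. = FALSE)
    e <- e[!(e$child %in% starts), , drop = FALSE]
    nodes <- setdiff(nodes, starts)
  }
  seen <- d
  frontier <- d
  repeat {
    parents <- unique(edges$parent[edges$child %in% frontier])
    frontier <- setdiff(parents, seen)
    if (length(frontier) == 0L) return(seen)
    seen <- c(seen, frontier)
  }
}

#' @export
print.disease_ontology <- function(x, ...) {
  cat("Disease ontology:", length(x$diseases), "diseases (",
      x$n_dag_diseases, "with a DAG ),",
      length(x$dag_count), "terms\n")
  invisible(x)
}

#' Read a disease ontology from a block-format text file
#'
#' The file contains one block per disease: a header line `>disease name`
#' followed by zero or more `child<TAB>parent` edge lines.  A header with no
#' edge lines records a disease without a DAG.  Lines starting with `#` are
#' comments.
#'
#' @param path path to the file.
#' @return a [disease_ontology()].
#' @export
read_ontology <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty ontology file ", path, call. = FALSE)
  hdr <- grepl("^>", lines)
  if (!hdr[1L]) stop("ontology file must start with a '>disease' header",
                     call. = FALSE)
  block <- cumsum(hdr)
  dags <- list()
  for (b in seq_len(max(block))) {
    chunk <- lines[block == b]
    name <- trimws(sub("^>", "", chunk[1L]))
    body <- chunk[-1L]
    if (length(body) == 0L) {
      dags[name] <- list(NULL)
    } else {
      parts <- strsplit(body, "\t")
      if (any(lengths(parts) != 2L))
        stop("malformed edge line in ontology block '", name, "'",
             call. = FALSE)
      dags[[name]] <- data.frame(
        child = vapply(parts, `[[`, "", 1L),
        parent = vapply(parts, `[[`, "", 2L),
        stringsAsFactors = FALSE)
    }
  }
  disease_ontology(dags)
}

#' Write a disease ontology in the block text format read by [read_ontology()]
#'
#' @param ontology a [disease_ontology()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_ontology <- function(ontology, path) {
  stopifnot(inherits(ontology, "disease_ontology"))
  con <- file(path, "w")
  on.exit(close(con))
  for (d in ontology$diseases) {
    writeLines(paste0(">", d), con)
    if (ontology$has_dag[[d]]) {
      e <- ontology$dag[[d]]$edges
      if (nrow(e)) writeLines(paste(e$child, e$parent, sep = "\t"), con)
    }
  }
  invisible(path)
}

# ---- similarity matrices ---------------------------------------------------

#' Tag a square matrix as a similarity matrix
#'
#' Validates symmetry (within `sym_tol`, symmetrizing by averaging) and, for
#' raw kinds, the \[0, 1\] entry range; attaches the `kind` and `normalized`
#' attributes used by downstream functions to refuse raw input where a
#' normalized matrix is required.  `NA` entries mark undefined similarities
#' (e.g. diseases without a DAG).
#'
#' @param S square numeric matrix with matching row/column names.
#' @param kind provenance tag: one of `"SS1"`, `"SS2"`, `"SS"`, `"MS"`,
#'   `"GD"`, `"GR"`, `"SD"`, `"SR"`.
#' @param normalized whether the matrix has been symmetrically normalized.
#' @param sym_tol maximum tolerated max-abs asymmetry before erroring.
#' @return the matrix with `kind` and `normalized` attributes set.
#' @export
similarity_matrix <- function(S, kind, normalized = FALSE, sym_tol = 1e-6) {
  kinds <- c("SS1", "SS2", "SS", "MS", "GD", "GR", "SD", "SR")
  kind <- match.arg(kind, kinds)
  if (!is.matrix(S) || nrow(S) != ncol(S))
    stop("similarity matrix must be square", call. = FALSE)
  if (is.null(rownames(S)) || !identical(rownames(S), colnames(S)))
    stop("row and column names must match", call. = FALSE)
  asym <- max(abs(S - t(S)), na.rm = TRUE)
  if (is.finite(asym) && asym > sym_tol)
    stop("matrix is asymmetric beyond tolerance (max |S - t(S)| = ",
         format(asym), ")", call. = FALSE)
  S <- (S + t(S)) / 2
  if (!normalized) {
    rng <- range(S, na.rm = TRUE)
    if (rng[1L] < -1e-9 || rng[2L] > 1 + 1e-9)
      stop("raw ", kind, " entries must lie in [0, 1]", call. = FALSE)
  }
  attr(S, "kind") <- kind
  attr(S, "normalized") <- normalized
  S
}

#' Read a similarity matrix from a TSV file with name headers
#'
#' @param path path to a tab-separated table whose first row and first column
#'   hold the (matching) entity names.
#' @param kind provenance tag, see [similarity_matrix()].
#' @return the validated similarity matrix (attributes `kind`, `normalized =
#'   FALSE`).
#' @export
read_similarity <- function(path, kind = "MS") {
  tab <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
  S <- as.matrix(tab)
  if (nrow(S) != ncol(S))
    stop("similarity table in ", path, " is not square (",
         nrow(S), " x ", ncol(S), ")", call. = FALSE)
  rn <- tolower(trimws(rownames(S)))
  cn <- tolower(trimws(colnames(S)))
  if (!identical(rn, cn))
    stop("row and column headers differ in ", path, call. = FALSE)
  dimnames(S) <- list(rn, cn)
  storage.mode(S) <- "double"
  similarity_matrix(S, kind = kind, normalized = FALSE)
}

#' Write a similarity matrix as a TSV file with name headers
#'
#' Values are written with 15 significant digits so that a read/write
#' round-trip is lossless to well below 1e-12.
#'
#' @param S similarity matrix with dimnames.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(S, path) {
  stopifnot(is.matrix(S), !is.null(rownames(S)))
  txt <- apply(S, 1L, function(r) paste(formatC(r, digits = 15, format = "g"),
                                        collapse = "\t"))
  writeLines(c(paste(c("", colnames(S)), collapse = "\t"),
               paste(rownames(S), txt, sep = "\t")),
             path)
  invisible(path)
}
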