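#' Construct a weighted graph object
#'
#' A \code{prop_graph} holds an undirected, weighted network as a sparse
#' symmetric affinity matrix with zero diagonal, together with the node
#' identifiers that fix the row/column ordering for every vector and matrix
#' derived from the graph.
#'
#' @param A square matrix (dense or \pkg{Matrix} sparse) of non-negative link
#'   weights. Symmetrized by \code{symmetrize_rule} if needed; the diagonal is
#'   zeroed.
#' @param nodes character vector of node identifiers, one per row of \code{A}.
#'   Defaults to rownames of \code{A} or \code{"v1"..."vn"}.
#' @param symmetrize_rule how to reconcile \code{A[i,j] != A[j,i]}:
#'   \code{"max"} (default), \code{"sum"}, or \code{"error"}.
#' @return An object of class \code{prop_graph} with elements \code{A}
#'   (a \code{dgCMatrix}) and \code{nodes}.
#' @examples
#' g <- weighted_graph(matrix(c(0, 1, 1, 0), 2), nodes = c("a", "b"))
#' degree_vector(g)
#' @export
weighted_graph <- function(A, nodes = NULL,
                           symmetrize_rule = c("max", "sum", "error")) {
  symmetrize_rule <- match.arg(symmetrize_rule)
  A <- Matrix::Matrix(A, sparse = TRUE)   # also loads Matrix's coercions
  A <- methods::as(methods::as(methods::as(A, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  if (nrow(A) != ncol(A)) stop("affinity matrix must be square")
  if (is.null(nodes)) nodes <- rownames(A)
  if (is.null(nodes)) nodes <- paste0("v", seq_len(nrow(A)))
  if (length(nodes) != nrow(A)) stop("length(nodes) must equal nrow(A)")
  if (anyDuplicated(nodes)) stop("duplicate node identifiers")
  if (any(A@x < 0)) stop("negative link weights are not allowed")
  diag(A) <- 0
  if (!Matrix::isSymmetric(A, tol = 0)) {
    A <- switch(symmetrize_rule,
      max   = pmax_sparse(A, Matrix::t(A)),
      sum   = A + Matrix::t(A),
      error = stop("affinity matrix is not symmetric"))
  }
  A <- Matrix::drop0(A)
  dimnames(A) <- list(nodes, nodes)
  structure(list(A = A, nodes = nodes), class = "prop_graph")
}

# entrywise max of two sparse matrices with a shared candidate pattern
pmax_sparse <- function(X, Y) {
  D <- X - Y
  D@x <- pmax(D@x, 0)   # max(x, y) = y + max(x - y, 0)
  Matrix::drop0(Y + D)
}

#' @export
print.prop_graph <- function(x, ...) {
  nnz <- length(x$A@x)
  cat(sprintf("Undirected weighted graph: %d nodes, %d edges (total weight %.6g)\n",
              length(x$nodes), nnz / 2, sum(x$A@x) / 2))
  iso <- sum(degree_vector(x) == 0)
  if (iso > 0) cat(sprintf("  %d isolated node(s)\n", iso))
  invisible(x)
}

#' Read an undirected network from an edge-list file
#'
#' Parses a whitespace/tab-separated edge list with two columns
#' (\code{node_a node_b}, weight defaulting to 1) or three columns
#' (\code{node_a node_b weight}). Lines starting with \code{#} are skipped.
#' Self-links are dropped (with a message reporting the count), zero-weight
#' entries are dropped, and reciprocal or duplicate entries are reconciled by
#' \code{symmetrize_rule}. Nodes are ordered lexicographically by identifier,
#' fixing the indexing used by all downstream vectors and matrices.
#'
#' @param path path to the edge-list file.
#' @param symmetrize_rule \code{"max"} (default), \code{"sum"}, or
#'   \code{"error"} for conflicting duplicate entries.
#' @return A \code{prop_graph}.
#' @export
read_edge_list <- function(path, symmetrize_rule = c("max", "sum", "error")) {
  symmetrize_rule <- match.arg(symmetrize_rule)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  nf <- lengths(fields)
  bad <- nf < 2L | nf > 3L
  if (any(bad)) {
    stop(sprintf("malformed row at line %d: %s",
                 lineno[which(bad)[1]], lines[lineno[which(bad)[1]]]))
  }
  a <- vapply(fields, `[`, "", 1L)
  b <- vapply(fields, `[`, "", 2L)
  w <- rep(1.0, length(fields))
  has_w <- nf == 3L
  if (any(has_w)) {
    wtxt <- vapply(fields[has_w], `[`, "", 3L)
    wval <- suppressWarnings(as.numeric(wtxt))
    if (anyNA(wval)) {
      i <- which(has_w)[which(is.na(wval))[1]]
      stop(sprintf("malformed weight at line %d: %s", lineno[i], lines[lineno[i]]))
    }
    if (any(wval < 0)) {
      i <- which(has_w)[which(wval < 0)[1]]
      stop(sprintf("negative weight at line %d: %s", lineno[i], lines[lineno[i]]))
    }
    w[has_w] <- wval
  }
  self <- a == b
  if (any(self)) {
    message(sprintf("dropped %d self-link(s)", sum(self)))
    a <- a[!self]; b <- b[!self]; w <- w[!self]
  }
  nz <- w > 0
  a <- a[nz]; b <- b[nz]; w <- w[nz]
  nodes <- sort(unique(c(a, b)))
  if (length(nodes) == 0L) stop("edge list contains no usable edges")
  i <- match(a, nodes); j <- match(b, nodes)
  # stack both orientations; duplicates resolved below
  ii <- c(i, j); jj <- c(j, i); ww <- c(w, w)
  n <- length(nodes)
  key <- (ii - 1) * n + jj
  if (anyDuplicated(key)) {
    agg <- switch(symmetrize_rule,
      max   = tapply(ww, key, max),
      sum   = tapply(ww, key, sum),
      error = stop("duplicate or reciprocal entries present with symmetrize_rule = 'error'"))
    key2 <- as.numeric(names(agg))
    ii <- (key2 - 1) %/% n + 1
    jj <- (key2 - 1) %% n + 1
    ww <- as.numeric(agg)
    if (symmetrize_rule == "max")
      message("duplicate/reciprocal entries reconciled by max")
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(n, n))
  weighted_graph(A, nodes, symmetrize_rule = "max")
}

#' Read positive labels from a file
#'
#' Accepts either one node identifier per line (a single category) or a
#' two-column TSV \code{node<TAB>category} for multi-category label sets.
#' Lines starting with \code{#} are skipped.
#'
#' @param path path to the label file.
#' @return A named list of character vectors of positive node identifiers,
#'   one element per category (a single unnamed-category file yields a list
#'   of length one named \code{"positive"}).
#' @export
read_labels <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf > 2L)) stop("label file rows must have 1 or 2 columns")
  node <- vapply(fields, `[`, "", 1L)
  cat_ <- ifelse(nf == 2L, vapply(fields, function(f) f[length(f)], ""), "positive")
  split(node, cat_)
}

#' Build a 0/1 label vector over the graph's node ordering
#'
#' @param graph a \code{prop_graph}.
#' @param positives character vector of positive node identifiers.
#' @return Numeric vector \code{y} with \code{y[i] = 1} for positives, 0
#'   otherwise, named by node.
#' @export
label_vector <- function(graph, positives) {
  unknown <- setdiff(positives, graph$nodes)
  if (length(unknown) > 0)
    warning(sprintf("%d positive id(s) not in graph, ignored: %s",
                    length(unknown), paste(utils::head(unknown, 5), collapse = ", ")))
  y <- as.numeric(graph$nodes %in% positives)
  names(y) <- graph$nodes
  y
}

#' Weighted degrees
#'
#' @param graph a \code{prop_graph}.
#' @return Numeric vector \code{d} with \code{d[i]} the sum of weights of
#'   links incident to node \code{i}.
#' @export
degree_vector <- function(graph) {
  d <- Matrix::rowSums(graph$A)
  names(d) <- graph$nodes
  d
}

#' Normalize a graph for label propagation
#'
#' Produces one of the two propagation matrices: the symmetric normalization
#' \eqn{S = D^{-1/2} A D^{-1/2}} or the asymmetric row-stochastic random-walk
#' matrix \eqn{P = D^{-1} A}, where \eqn{D} is the diagonal matrix of weighted
#' degrees. The two are similar matrices (\eqn{S = D^{1/2} P D^{-1/2}}) and
#' share the sparsity pattern of \eqn{A}. Rows/columns of isolated nodes
#' (degree zero) are left identically zero; with
#' \code{isolated = "error"} their presence aborts instead.
#'
#' @param graph a \code{prop_graph}.
#' @param kind \code{"symmetric"} (default) or \code{"asymmetric"}.
#' @param isolated \code{"zero"} (default: keep isolated nodes with zero
#'   rows/columns) or \code{"error"}.
#' @return An object of class \code{prop_norm}: list with \code{M} (sparse
#'   matrix), \code{kind}, \code{d} (degree vector) and \code{nodes}.
#' @examples
#' g <- weighted_graph(1 - diag(3))            # triangle
#' normalize_graph(g)$M[1, 2]                  # 1/2
#' @export
normalize_graph <- function(graph, kind = c("symmetric", "asymmetric"),
                            isolated = c("zero", "error")) {
  kind <- match.arg(kind)
  isolated <- match.arg(isolated)
  d <- degree_vector(graph)
  if (any(d == 0)) {
    if (isolated == "error")
      stop(sprintf("isolated node(s) present: %s",
                   paste(utils::head(graph$nodes[d == 0], 5), collapse = ", ")))
  }
  dinv <- ifelse(d > 0, 1 / d, 0)
  M <- if (kind == "symmetric") {
    s <- sqrt(dinv)
    Matrix::Diagonal(x = s) %*% graph$A %*% Matrix::Diagonal(x = s)
  } else {
    Matrix::Diagonal(x = dinv) %*% graph$A
  }
  M <- methods::as(M, "CsparseMatrix")
  dimnames(M) <- list(graph$nodes, graph$nodes)
  structure(list(M = M, kind = kind, d = d, nodes = graph$nodes),
            class = "prop_norm")
}

#' @export
print.prop_norm <- function(x, ...) {
  cat(sprintf("%s propagation matrix (%d x %d, %d non-zeros)\n",
              x$kind, nrow(x$M), ncol(x$M), length(x$M@x)))
  invisible(x)
}

#' Write node scores to a TSV file
#'
#' Two columns (node, score), sorted by decreasing score with ties broken by
#' node identifier, so output is deterministic.
#'
#' @param scores named numeric score vector (names are node identifiers).
#' @param path output file path.
#' @return Invisibly, the ordered data frame written.
#' @export
write_scores <- function(scores, path) {
  stopifnot(!is.null(names(scores)))
  ord <- order(-scores, names(scores))
  df <- data.frame(node = names(scores)[ord], score = scores[ord],
                   row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
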