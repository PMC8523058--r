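#' Markov clustering (MCL) of the alignment graph
#'
#' From-scratch MCL on a sparse column-stochastic matrix: add self-loops,
#' normalize columns, then iterate expansion (matrix squaring) and inflation
#' (entrywise power followed by column renormalization), pruning entries
#' below `prune_threshold`, until the matrix changes by less than `tol` or
#' `max_iterations` is hit. Clusters are the connected components of the
#' converged matrix's nonzero structure; isolated nodes become singletons.
#'
#' @param graph an [build_graph()] `alignment_graph`, or a symmetric
#'   non-negative adjacency matrix (dense or sparse).
#' @param inflation inflation exponent (> 1); default 2.
#' @param self_loop_weight per-node self-loop; default (`NULL`) the node's
#'   maximum incident edge weight (1 for isolated nodes).
#' @param prune_threshold entries below this are dropped each iteration.
#' @param max_iterations iteration cap; on hitting it the current matrix is
#'   interpreted as-is and the result carries attribute `converged = FALSE`
#'   with a warning.
#' @param tol convergence tolerance on the max absolute entry change.
#' @return list of integer vectors (node indices), each sorted; a partition
#'   of all nodes. Attribute `converged` reports convergence.
#' @export
mcl_cluster <- function(graph, inflation = 2, self_loop_weight = NULL,
                        prune_threshold = 1e-8, max_iterations = 1000L,
                        tol = 1e-8) {
  adj <- if (inherits(graph, "alignment_graph")) graph$adjacency else graph
  if (inflation <= 1) config_error("inflation must be > 1")
  adj <- methods::as(methods::as(Matrix::Matrix(adj, sparse = TRUE), "generalMatrix"),
                     "CsparseMatrix")
  n <- nrow(adj)
  if (n == 0L) return(structure(list(), converged = TRUE))

  loops <- if (is.null(self_loop_weight)) {
    mx <- apply_sparse_colmax(adj)
    ifelse(mx > 0, mx, 1)
  } else rep(self_loop_weight, n)
  M <- adj + Matrix::Diagonal(n, loops)
  M <- normalize_columns(M)

  converged <- FALSE
  for (it in seq_len(max_iterations)) {
    M2 <- M %*% M                      # expansion
    M2@x <- M2@x^inflation             # inflation
    M2 <- Matrix::drop0(M2, tol = prune_threshold)
    M2 <- normalize_columns(M2)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge within ", max_iterations,
            " iterations; interpreting the current matrix", call. = FALSE)

  comps <- sparse_components(M)
  clusters <- unname(split(seq_len(n), comps))
  clusters <- lapply(clusters, sort)
  # deterministic order: by smallest node
  clusters <- clusters[order(vapply(clusters, min, integer(1)))]
  structure(clusters, converged = converged)
}

# column-wise max of a symmetric sparse matrix
apply_sparse_colmax <- function(m) {
  tri <- Matrix::summary(m)
  mx <- numeric(nrow(m))
  if (nrow(tri) > 0) {
    agg <- tapply(tri$x, tri$j, max)
    mx[as.integer(names(agg))] <- agg
  }
  mx
}

normalize_columns <- function(m) {
  cs <- Matrix::colSums(m)
  cs[cs == 0] <- 1
  m %*% Matrix::Diagonal(length(cs), 1 / cs)
}

# connected components of the nonzero pattern (symmetrized), via union-find
sparse_components <- function(m) {
  n <- nrow(m)
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  tri <- Matrix::summary(methods::as(m, "TsparseMatrix"))
  for (e in seq_len(nrow(tri))) {
    ra <- find(tri$i[e]); rb <- find(tri$j[e])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  vapply(seq_len(n), find, integer(1))
}
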