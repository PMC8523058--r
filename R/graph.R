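#' Build the alignment graph from backbone alignments
#'
#' Nodes are subalignment columns, numbered globally: node
#' `offsets[s] + c` is column `c` of subalignment `s`. For every backbone
#' column, every unordered pair of upper-case residues in that column adds
#' +1 support to the edge between the two residues' home columns (the
#' subalignment columns holding them, found via each sequence's ungapped
#' site index). Pairs within one subalignment are recorded too; cluster
#' validity is enforced later. Edge weights are therefore additive over the
#' backbone multiset.
#'
#' @param subalignments a [subalignment_store()], or a list of `msa` /
#'   FASTA paths (coerced to a store; subalignments are streamed one at a
#'   time).
#' @param backbones list of backbone `msa` objects or FASTA paths, loaded
#'   one at a time.
#' @return an `alignment_graph`: list with `adjacency` (symmetric sparse
#'   `dgCMatrix`, n_nodes x n_nodes), `n_cols` (columns per subalignment),
#'   `offsets` (0-based node offsets per subalignment), `node_subset` and
#'   `node_col` (per-node subset index and 1-based column).
#' @export
build_graph <- function(subalignments, backbones) {
  store <- if (inherits(subalignments, "subalignment_store")) subalignments
           else subalignment_store(subalignments)
  n_sub <- length(store)

  # stream subalignments once: column counts + per-row site -> column maps
  n_cols <- integer(n_sub)
  site_maps <- list()   # id -> integer vector over sites (1-based cols)
  row_subset <- integer(0)
  for (s in seq_len(n_sub)) {
    aln <- store_load(store, s)
    n_cols[s] <- alignment_length(aln)
    mat <- unclass(aln)
    for (r in seq_len(nrow(mat))) {
      id <- rownames(mat)[r]
      if (!is.null(site_maps[[id]]))
        data_error("row id '", id, "' appears in more than one subalignment")
      site_maps[[id]] <- which(mat[r, ] != GAP)
      row_subset[id] <- s
    }
    store_release(store, s)
  }
  offsets <- c(0L, cumsum(n_cols))[seq_len(n_sub)]
  n_nodes <- sum(n_cols)

  ii <- list(); jj <- list()
  for (b in seq_along(backbones)) {
    bb <- backbones[[b]]
    if (!inherits(bb, "msa")) bb <- read_fasta(bb, aligned = TRUE)
    mat <- unclass(bb)
    unknown <- setdiff(rownames(mat), names(row_subset))
    if (length(unknown))
      data_error("backbone rows not found in any subalignment: ",
                 paste(unknown, collapse = ", "))
    up <- is_upper_matrix(mat)
    site <- site_index_matrix(mat)
    # node of every (row, column) residue
    node_mat <- matrix(NA_integer_, nrow(mat), ncol(mat))
    for (r in seq_len(nrow(mat))) {
      id <- rownames(mat)[r]
      w <- which(!is.na(site[r, ]))
      node_mat[r, w] <- offsets[row_subset[id]] + site_maps[[id]][site[r, w] + 1L]
    }
    for (j in seq_len(ncol(mat))) {
      nodes <- node_mat[up[, j], j]
      nodes <- nodes[!is.na(nodes)]
      if (length(nodes) < 2L) next
      cmb <- utils::combn(nodes, 2L)
      keep <- cmb[1L, ] != cmb[2L, ]
      if (!any(keep)) next
      ii[[length(ii) + 1L]] <- cmb[1L, keep]
      jj[[length(jj) + 1L]] <- cmb[2L, keep]
    }
  }
  ii <- unlist(ii) %||% integer(0)
  jj <- unlist(jj) %||% integer(0)
  adjacency <- Matrix::sparseMatrix(
    i = c(ii, jj), j = c(jj, ii), x = rep(1, 2L * length(ii)),
    dims = c(n_nodes, n_nodes))
  structure(list(adjacency = adjacency, n_cols = n_cols, offsets = offsets,
                 node_subset = rep(seq_len(n_sub), n_cols),
                 node_col = unlist(lapply(n_cols, seq_len)) %||% integer(0)),
            class = "alignment_graph")
}

#' @export
print.alignment_graph <- function(x, ...) {
  cat(sprintf("<alignment_graph: %d nodes (%d subalignments), %d edges>\n",
              sum(x$n_cols), length(x$n_cols),
              length(x$adjacency@x) / 2L))
  invisible(x)
}

#' Write an alignment graph as a plain-text weighted edge list
#'
#' One line per undirected edge: `subset:column subset:column weight`
#' (1-based columns). A stable debugging/resume artifact.
#'
#' @param graph an `alignment_graph`.
#' @param path output file.
#' @export
write_graph_edgelist <- function(graph, path) {
  tri <- Matrix::summary(Matrix::triu(graph$adjacency))
  lab <- function(n) paste0(graph$node_subset[n], ":", graph$node_col[n])
  ord <- order(tri$i, tri$j)
  writeLines(sprintf("%s %s %g", lab(tri$i[ord]), lab(tri$j[ord]), tri$x[ord]), path)
  invisible(path)
}

#' Write clusters as plain text, one line per cluster
#'
#' Each line lists the cluster's member columns as `subset:column` tokens.
#'
#' @param clusters list of integer node vectors.
#' @param graph the `alignment_graph` the nodes refer to.
#' @param path output file.
#' @export
write_clusters <- function(clusters, graph, path) {
  lines <- vapply(clusters, function(nodes) {
    paste(paste0(graph$node_subset[nodes], ":", graph$node_col[nodes]),
          collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
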