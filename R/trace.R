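#' Enforce cluster validity: at most one column per subalignment
#'
#' A cluster of alignment-graph nodes can only become one merged column if
#' it holds at most one column of each subalignment. Offending clusters are
#' split: for each subalignment with several columns in the cluster, the
#' column with the greatest total edge weight into the rest of the cluster
#' is kept (ties: the lower column index); evicted columns become singleton
#' clusters.
#'
#' @param clusters list of integer node vectors partitioning the node set.
#' @param graph the `alignment_graph` providing weights and node identities.
#' @return list of valid clusters (deterministic order: by smallest node).
#' @export
enforce_cluster_validity <- function(clusters, graph) {
  adj <- graph$adjacency
  subset_of <- graph$node_subset
  out <- list()
  for (cl in clusters) {
    subs <- subset_of[cl]
    if (!anyDuplicated(subs)) {
      out[[length(out) + 1L]] <- sort(cl)
      next
    }
    keep <- integer(0)
    evicted <- integer(0)
    for (s in unique(subs)) {
      members <- cl[subs == s]
      if (length(members) == 1L) {
        keep <- c(keep, members)
      } else {
        w <- Matrix::rowSums(adj[members, cl, drop = FALSE])
        best <- members[order(-w, members)][1L]  # tie: lower column index
        keep <- c(keep, best)
        evicted <- c(evicted, setdiff(members, best))
      }
    }
    out[[length(out) + 1L]] <- sort(keep)
    for (ev in sort(evicted)) out[[length(out) + 1L]] <- ev
  }
  out[order(vapply(out, min, integer(1)))]
}

#' Order valid clusters into a trace
#'
#' A trace is a total order on the clusters in which every subalignment's
#' columns appear in strictly increasing column order -- the merged
#' alignment's column order. Ordering conflicts (cycles in the precedence
#' relation) are resolved by a deterministic frontier heuristic: clusters
#' whose members are all at their subalignments' frontiers are emitted
#' first (smallest (subalignment, column) key when several are ready);
#' when none is ready, a cycle exists, and the globally smallest frontier
#' node (by (subalignment, column)) is evicted from its cluster into a
#' singleton, sacrificing that node's within-cluster homology to restore
#' sortability with few changes.
#'
#' @param clusters list of valid clusters (integer node vectors; at most one
#'   column per subalignment each -- see [enforce_cluster_validity()]).
#' @param graph the `alignment_graph`.
#' @return a `trace`: list of integer node vectors in merged-column order.
#' @export
order_clusters <- function(clusters, graph) {
  n_sub <- length(graph$n_cols)
  n_cols <- graph$n_cols
  offsets <- graph$offsets
  subset_of <- graph$node_subset
  col_of <- graph$node_col
  key_of <- function(nodes) {
    if (length(nodes) == 0L) return(Inf)
    min(as.numeric(subset_of[nodes]) * (max(n_cols) + 1) + col_of[nodes])
  }

  nk <- length(clusters)
  for (cl in clusters) {
    if (anyDuplicated(subset_of[cl]))
      data_error("order_clusters requires valid clusters (<=1 column per subalignment)")
  }
  members <- clusters
  node_cluster <- integer(sum(n_cols))
  for (k in seq_len(nk)) node_cluster[members[[k]]] <- k
  if (any(node_cluster == 0L))
    data_error("clusters must cover every subalignment column")

  cl_size <- lengths(members)
  frontier <- rep(1L, n_sub)
  at_front <- integer(nk)
  for (s in seq_len(n_sub)) {
    if (n_cols[s] >= 1L) {
      k <- node_cluster[offsets[s] + 1L]
      at_front[k] <- at_front[k] + 1L
    }
  }
  minkey <- vapply(members, key_of, numeric(1))
  alive <- cl_size > 0L

  advance <- function(s) {
    frontier[s] <<- frontier[s] + 1L
    if (frontier[s] <= n_cols[s]) {
      k <- node_cluster[offsets[s] + frontier[s]]
      at_front[k] <<- at_front[k] + 1L
    }
  }

  trace <- vector("list", nk)  # grows if splits occur
  n_out <- 0L
  emit <- function(nodes) {
    n_out <<- n_out + 1L
    if (n_out > length(trace)) length(trace) <<- 2L * n_out
    trace[[n_out]] <<- sort(nodes)
  }

  remaining <- sum(n_cols)
  while (remaining > 0L) {
    ready_keys <- ifelse(alive & at_front == cl_size & cl_size > 0L, minkey, Inf)
    k <- which.min(ready_keys)
    if (is.finite(ready_keys[k])) {
      emit(members[[k]])
      remaining <- remaining - cl_size[k]
      alive[k] <- FALSE
      for (nd in members[[k]]) advance(subset_of[nd])
    } else {
      # deadlock: evict the smallest frontier node into a singleton
      open_s <- which(frontier <= n_cols)
      s <- open_s[1L]
      nd <- offsets[s] + frontier[s]
      k <- node_cluster[nd]
      members[[k]] <- setdiff(members[[k]], nd)
      cl_size[k] <- cl_size[k] - 1L
      at_front[k] <- at_front[k] - 1L
      minkey[k] <- key_of(members[[k]])
      if (cl_size[k] == 0L) alive[k] <- FALSE
      emit(nd)
      remaining <- remaining - 1L
      advance(s)
    }
  }
  structure(trace[seq_len(n_out)], class = "gcm_trace")
}

#' Check the trace invariants
#'
#' Every subalignment column appears in exactly one trace cluster, and each
#' subalignment's columns appear in strictly increasing order along the
#' trace. Errors if violated.
#'
#' @param trace a [order_clusters()] trace.
#' @param graph the `alignment_graph`.
#' @return `TRUE`, invisibly.
#' @export
validate_trace <- function(trace, graph) {
  seen <- integer(sum(graph$n_cols))
  last_col <- rep(0L, length(graph$n_cols))
  for (cl in trace) {
    subs <- graph$node_subset[cl]
    if (anyDuplicated(subs)) data_error("trace cluster with >1 column of one subalignment")
    for (i in seq_along(cl)) {
      seen[cl[i]] <- seen[cl[i]] + 1L
      s <- subs[i]; cc <- graph$node_col[cl[i]]
      if (cc <= last_col[s])
        data_error("trace visits subalignment ", s, " columns out of order")
      last_col[s] <- cc
    }
  }
  if (any(seen != 1L)) data_error("trace does not cover every column exactly once")
  invisible(TRUE)
}

#' Assemble the merged alignment from a trace
#'
#' One output column per trace cluster: each member column of the cluster
#' contributes its subalignment's residues (case preserved); rows whose
#' subalignment has no column in the cluster get gaps. Subalignments are
#' streamed one at a time.
#'
#' @param trace a [order_clusters()] trace.
#' @param subalignments a [subalignment_store()] or list of `msa`/paths.
#' @param graph the `alignment_graph`.
#' @return the merged `msa`; rows are the subalignments' rows in subset
#'   order; upcased-degapped rows equal the original sequences.
#' @export
assemble <- function(trace, subalignments, graph) {
  store <- if (inherits(subalignments, "subalignment_store")) subalignments
           else subalignment_store(subalignments)
  validate_trace(trace, graph)
  n_sub <- length(store)
  L <- length(trace)

  # trace position of every node
  node_pos <- integer(sum(graph$n_cols))
  for (t in seq_along(trace)) node_pos[trace[[t]]] <- t

  blocks <- vector("list", n_sub)
  all_ids <- character(0)
  for (s in seq_len(n_sub)) {
    aln <- store_load(store, s)
    mat <- unclass(aln)
    block <- matrix(GAP, nrow(mat), L, dimnames = list(rownames(mat), NULL))
    pos <- node_pos[graph$offsets[s] + seq_len(graph$n_cols[s])]
    block[, pos] <- mat
    blocks[[s]] <- block
    all_ids <- c(all_ids, rownames(mat))
    store_release(store, s)
  }
  new_msa(do.call(rbind, blocks))
}
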