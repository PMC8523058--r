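#' Read and write guide trees in Newick format
#'
#' Guide trees are `ape::phylo` objects whose tip labels are sequence ids.
#' They drive dataset decomposition only; branch lengths, if present, are
#' ignored by [centroid_edge_decompose()].
#'
#' @param path a Newick file.
#' @return an `ape` `phylo` tree.
#' @export
parse_newick <- function(path) {
  if (!file.exists(path)) format_error("file not found: ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) format_error("malformed Newick in ", path, ": ",
                                                    conditionMessage(e)))
  if (is.null(tree)) format_error("malformed Newick in ", path)
  if (inherits(tree, "multiPhylo")) tree <- tree[[1L]]
  if (anyDuplicated(tree$tip.label)) format_error("duplicate leaf labels in guide tree")
  tree
}

#' @rdname parse_newick
#' @param tree a `phylo` tree.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

single_tip_tree <- function(id) {
  structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
                 tip.label = id, Nnode = 1L, edge.length = 1),
            class = "phylo", order = "cladewise")
}

star_tree <- function(ids) {
  n <- length(ids)
  structure(list(edge = cbind(rep(n + 1L, n), seq_len(n)),
                 tip.label = ids, Nnode = 1L, edge.length = rep(1, n)),
            class = "phylo", order = "cladewise")
}

kmer_profile <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(table(seq))
  table(substring(seq, 1:(L - k + 1L), k:L))
}

#' Pairwise k-mer cosine distances
#'
#' Distance between two sequences is 1 minus the cosine similarity of their
#' k-mer count profiles -- an alignment-free distance adequate for a rough
#' guide tree.
#'
#' @param seqs named character vector of unaligned sequences.
#' @param k k-mer length; default 5 for nucleotide data, 3 for protein.
#' @return a `dist` object.
#' @export
kmer_distance <- function(seqs, k = NULL) {
  seqs <- validate_sequences(seqs)
  if (is.null(k)) k <- if (detect_alphabet(seqs) == "nt") 5L else 3L
  if (k < 1L) config_error("k must be >= 1")
  profiles <- lapply(seqs, kmer_profile, k = k)
  vocab <- unique(unlist(lapply(profiles, names)))
  m <- matrix(0, length(seqs), length(vocab), dimnames = list(names(seqs), vocab))
  for (i in seq_along(profiles)) m[i, names(profiles[[i]])] <- as.numeric(profiles[[i]])
  norms <- sqrt(rowSums(m^2))
  norms[norms == 0] <- 1
  d <- 1 - tcrossprod(m / norms)
  d[d < 0] <- 0
  stats::as.dist(d)
}

#' Built-in guide tree: neighbor joining on k-mer distances
#'
#' Fast, alignment-free fallback tree used when no external tree estimator
#' is configured and no user tree is supplied. Only a rough tree is needed
#' for decomposition. Deterministic for a fixed seed.
#'
#' @inheritParams kmer_distance
#' @param seed integer; reserved for strategies with random components (the
#'   k-mer NJ construction itself is deterministic).
#' @return a `phylo` guide tree over `names(seqs)`.
#' @export
build_fallback_tree <- function(seqs, k = NULL, seed = 0L) {
  seqs <- validate_sequences(seqs)
  n <- length(seqs)
  if (n == 1L) return(single_tip_tree(names(seqs)))
  if (n <= 3L) return(star_tree(names(seqs)))
  d <- kmer_distance(seqs, k)
  tree <- with_seed(seed, ape::nj(d))
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Random dataset decomposition
#'
#' Shuffles the ids and chunks them into `ceiling(n / max_subset_size)`
#' near-equal subsets; the fastest decomposition strategy, used when even a
#' rough guide tree is too expensive.
#'
#' @param ids sequence ids.
#' @param max_subset_size maximum subset size (>= 1).
#' @param seed integer seed; same seed, same decomposition.
#' @return list of character vectors (disjoint, covering all `ids`).
#' @export
random_decomposition <- function(ids, max_subset_size, seed = 0L) {
  if (max_subset_size < 1L) config_error("max_subset_size must be >= 1")
  n <- length(ids)
  m <- ceiling(n / max_subset_size)
  shuffled <- with_seed(seed, sample(ids))
  sizes <- rep(n %/% m, m)
  extra <- n %% m
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  split(shuffled, rep(seq_len(m), times = sizes))
}

# tips reachable below `node` in a postorder-ordered phylo
tips_below <- function(tree, node) {
  nt <- length(tree$tip.label)
  if (node <= nt) return(tree$tip.label[node])
  below <- logical(nt + tree$Nnode)
  below[node] <- TRUE
  edge <- tree$edge
  for (e in rev(seq_len(nrow(edge)))) {  # preorder pass
    if (below[edge[e, 1L]]) below[edge[e, 2L]] <- TRUE
  }
  tree$tip.label[which(below[seq_len(nt)])]
}

#' Centroid edge decomposition of a guide tree
#'
#' Recursively splits the leaf set: if a piece has at most `max_subset_size`
#' leaves it is emitted; otherwise the centroid edge -- the edge whose
#' removal minimizes the leaf count of the larger side -- is deleted and
#' both sides are decomposed recursively. Ties are broken by the first
#' minimizing edge in postorder, making the decomposition deterministic.
#'
#' @param tree a `phylo` guide tree.
#' @param max_subset_size maximum leaves per subset (>= 1).
#' @return list of character vectors: disjoint leaf subsets covering all
#'   tips, each of size `<= max_subset_size`.
#' @export
centroid_edge_decompose <- function(tree, max_subset_size) {
  if (max_subset_size < 1L) config_error("max_subset_size must be >= 1")
  n <- length(tree$tip.label)
  if (n <= max_subset_size) return(list(tree$tip.label))

  tr <- ape::reorder.phylo(tree, "postorder")
  nt <- n
  cnt <- c(rep(1L, nt), rep(0L, tr$Nnode))
  for (e in seq_len(nrow(tr$edge)))
    cnt[tr$edge[e, 1L]] <- cnt[tr$edge[e, 1L]] + cnt[tr$edge[e, 2L]]
  larger <- pmax(cnt[tr$edge[, 2L]], n - cnt[tr$edge[, 2L]])
  best <- which.min(larger)  # first minimizing edge in postorder
  side_a <- tips_below(tr, tr$edge[best, 2L])
  side_b <- setdiff(tree$tip.label, side_a)

  out <- list()
  for (side in list(side_a, side_b)) {
    if (length(side) <= max_subset_size) {
      out <- c(out, list(side))
    } else {
      sub <- ape::keep.tip(tree, side)
      out <- c(out, centroid_edge_decompose(sub, max_subset_size))
    }
  }
  out
}
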