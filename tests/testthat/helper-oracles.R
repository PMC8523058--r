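# Independent oracles and fixture generators. Everything here is written
# directly from first principles (double loops, dense matrices) and shares
# no code path with the package internals it checks.

# random gapped alignment with a mix of upper-case, lower-case and gaps
random_msa <- function(n, L, seed, p_gap = 0.3, p_lower = 0.1,
                       alphabet = c("A", "C", "G", "T")) {
  set.seed(seed)
  mat <- matrix(sample(alphabet, n * L, replace = TRUE), n, L)
  gaps <- matrix(stats::runif(n * L) < p_gap, n, L)
  mat[gaps] <- "-"
  low <- matrix(stats::runif(n * L) < p_lower, n, L) & !gaps
  mat[low] <- tolower(mat[low])
  for (r in seq_len(n)) if (all(mat[r, ] == "-")) mat[r, sample.int(L, 1)] <- "A"
  rownames(mat) <- paste0("s", seq_len(n))
  msa(apply(mat, 1L, paste, collapse = ""))
}

# brute-force homologous pair enumeration: explicit double loop over columns
# and row pairs, tracking ungapped site indices by hand
brute_pairs <- function(aln) {
  mat <- unclass(aln)
  ids <- rownames(mat)
  site <- matrix(NA_integer_, nrow(mat), ncol(mat))
  for (r in seq_len(nrow(mat))) {
    k <- 0L
    for (j in seq_len(ncol(mat))) {
      if (mat[r, j] != "-") { site[r, j] <- k; k <- k + 1L }
    }
  }
  keys <- character(0)
  if (nrow(mat) < 2L) return(keys)
  for (j in seq_len(ncol(mat))) {
    for (a in seq_len(nrow(mat) - 1L)) {
      for (b in (a + 1L):nrow(mat)) {
        ca <- mat[a, j]; cb <- mat[b, j]
        if (ca != "-" && cb != "-" &&
            ca %in% LETTERS && cb %in% LETTERS) {
          keys <- c(keys, pair_key(ids[a], site[a, j], ids[b], site[b, j]))
        }
      }
    }
  }
  keys
}

# dense, from-the-definition Markov clustering used as the reference for
# mcl_cluster: plain base-R matrices throughout
mcl_reference <- function(adj, inflation = 2, prune = 1e-8, tol = 1e-8,
                          max_iter = 1000L) {
  A <- as.matrix(adj)
  n <- nrow(A)
  mx <- apply(A, 2, max)
  diag(A) <- ifelse(mx > 0, mx, 1)
  colnorm <- function(M) {
    cs <- colSums(M); cs[cs == 0] <- 1
    sweep(M, 2, cs, "/")
  }
  M <- colnorm(A)
  for (it in seq_len(max_iter)) {
    M2 <- (M %*% M)^inflation
    M2[M2 < prune] <- 0
    M2 <- colnorm(M2)
    if (max(abs(M2 - M)) < tol) { M <- M2; break }
    M <- M2
  }
  nz <- (M > 0) | (t(M) > 0)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (v in seq_len(n)) {
    if (!is.na(comp[v])) next
    cid <- cid + 1L
    stack <- v
    while (length(stack)) {
      u <- stack[1L]; stack <- stack[-1L]
      if (!is.na(comp[u])) next
      comp[u] <- cid
      stack <- c(stack, which(nz[u, ] & is.na(comp)))
    }
  }
  cl <- unname(split(seq_len(n), comp))
  cl <- lapply(cl, sort)
  cl[order(vapply(cl, min, integer(1)))]
}

# random symmetric weighted graph as a dense adjacency matrix
random_graph <- function(n, seed, p_edge = 0.25, max_w = 5L) {
  set.seed(seed)
  A <- matrix(0, n, n)
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      if (stats::runif(1) < p_edge) A[a, b] <- A[b, a] <- sample.int(max_w, 1L)
    }
  }
  A
}

# plain pairwise global alignment score with affine gaps (Gotoh), used as
# the oracle for the compiled DP; returns only the optimal score
nw_affine_score <- function(s1, s2, match = 1, mismatch = -1,
                            gap_open = -4, gap_extend = -1) {
  x <- strsplit(s1, "")[[1]]
  y <- strsplit(s2, "")[[1]]
  n1 <- length(x); n2 <- length(y)
  NEG <- -1e30
  M <- matrix(NEG, n1 + 1, n2 + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in seq_len(n1)) X[i + 1, 1] <- gap_open + (i - 1) * gap_extend
  for (j in seq_len(n2)) Y[1, j + 1] <- gap_open + (j - 1) * gap_extend
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      sc <- if (x[i] == y[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + sc
      X[i + 1, j + 1] <- max(M[i, j + 1] + gap_open, Y[i, j + 1] + gap_open,
                             X[i, j + 1] + gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] + gap_open, X[i + 1, j] + gap_open,
                             Y[i + 1, j] + gap_extend)
    }
  }
  max(M[n1 + 1, n2 + 1], X[n1 + 1, n2 + 1], Y[n1 + 1, n2 + 1])
}

# consistent-backbone fixture: induced subalignments and induced backbones
# of a known reference alignment, with full column support guaranteed by
# one extra backbone per contiguous column block
consistent_fixture <- function(n_taxa = 60, n_subsets = 4, seed = 1,
                               n_backbones = 10, rows_per_subset = 3,
                               n_blocks = 6, root_length = 100,
                               pdist = 0.2) {
  sim <- simulate_evolution(sim_config(n_taxa, root_length = root_length,
                                       expected_pdistance = pdist, seed = seed))
  ref <- sim$true_alignment
  ids <- msa_ids(ref)
  subsets <- unname(split(ids, rep(seq_len(n_subsets), length.out = length(ids))))
  subs <- lapply(subsets, function(s) restrict_alignment(ref, s))
  set.seed(seed + 1000)
  bbs <- lapply(seq_len(n_backbones), function(b) {
    restrict_alignment(ref, unlist(lapply(subsets, sample, rows_per_subset)))
  })
  L <- alignment_length(ref)
  blocks <- split(seq_len(L), cut(seq_len(L), n_blocks, labels = FALSE))
  has_res <- unclass(ref) != "-"
  for (blk in blocks) {
    rows <- ids[rowSums(has_res[, blk, drop = FALSE]) > 0]
    bbs <- c(bbs, list(restrict_alignment(ref, rows)))
  }
  list(reference = ref, subalignments = subs, backbones = bbs,
       subsets = subsets, sequences = sim$sequences)
}

# run the consistent-backbone merge end to end through the gcm module
run_gcm <- function(subalignments, backbones) {
  g <- build_graph(subalignments, backbones)
  cl <- mcl_cluster(g)
  valid <- enforce_cluster_validity(cl, g)
  tr <- order_clusters(valid, g)
  list(alignment = assemble(tr, subalignments, g), graph = g, trace = tr)
}
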