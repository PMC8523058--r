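#' Configuration for the sequence-evolution simulator
#'
#' Sequences evolve down a random birth (Yule) tree: per branch, each site
#' substitutes with probability `1 - exp(-subst_rate * bl)` (replacement
#' uniform over the alphabet), deletions and insertions arrive as Poisson
#' events (`del_rate` / `ins_rate` per site per unit branch length) with
#' geometric run lengths (success probability `indel_geom_p`, mean run
#' `1/indel_geom_p`). Site homology is tracked through indels with
#' persistent site identifiers, so the true alignment is known exactly.
#'
#' When `expected_pdistance` is given, branch lengths are rescaled so the
#' expected average pairwise p-distance over the simulated tree equals it
#' (Jukes-Cantor-style expectation); otherwise `branch_scale` is applied
#' directly.
#'
#' @param n_taxa number of leaves (>= 1).
#' @param root_length residues at the root (default 200).
#' @param subst_rate substitutions per site per unit branch length.
#' @param ins_rate,del_rate indel events per site per unit branch length.
#' @param indel_geom_p geometric length parameter in (0, 1].
#' @param branch_scale multiplier on branch lengths (used when
#'   `expected_pdistance` is `NULL`).
#' @param expected_pdistance target average pairwise p-distance in (0, limit)
#'   where limit is `(k-1)/k` for alphabet size `k`.
#' @param alphabet `"nt"` or `"aa"`.
#' @param seed integer seed; the whole simulation is deterministic per seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_taxa, root_length = 200L, subst_rate = 1,
                       ins_rate = 0.02, del_rate = 0.02, indel_geom_p = 0.5,
                       branch_scale = 1, expected_pdistance = NULL,
                       alphabet = c("nt", "aa"), seed = 0L) {
  alphabet <- match.arg(alphabet)
  if (n_taxa < 1L) config_error("n_taxa must be >= 1")
  if (root_length < 1L) config_error("root_length must be >= 1")
  if (any(c(subst_rate, ins_rate, del_rate) < 0)) config_error("rates must be >= 0")
  if (indel_geom_p <= 0 || indel_geom_p > 1) config_error("indel_geom_p must be in (0, 1]")
  structure(list(n_taxa = as.integer(n_taxa), root_length = as.integer(root_length),
                 subst_rate = subst_rate, ins_rate = ins_rate, del_rate = del_rate,
                 indel_geom_p = indel_geom_p, branch_scale = branch_scale,
                 expected_pdistance = expected_pdistance,
                 alphabet = alphabet, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulator presets emulating common divergence regimes
#'
#' `"16s-like"` targets an average pairwise p-distance of about 0.2 (a
#' conserved rRNA-like regime); `"rnasim-like"` targets about 0.4 (a more
#' divergent simulated-RNA-like regime). Both produce gappy nucleotide
#' alignments.
#'
#' @param name preset name.
#' @param n_taxa,seed forwarded to [sim_config()].
#' @param ... further overrides for [sim_config()].
#' @return a `sim_config`.
#' @export
sim_preset <- function(name = c("16s-like", "rnasim-like"), n_taxa, seed = 0L, ...) {
  name <- match.arg(name)
  target <- switch(name, "16s-like" = 0.2, "rnasim-like" = 0.4)
  sim_config(n_taxa = n_taxa, expected_pdistance = target, seed = seed, ...)
}

sim_alphabet <- function(config) {
  if (config$alphabet == "nt") NT_ALPHABET else AA_ALPHABET
}

# scale factor s such that the mean over leaf pairs of
# (k-1)/k * (1 - exp(-rate * s * d_ij)) equals the target p-distance
calibrate_branch_scale <- function(tree, rate, k_alpha, target) {
  d <- ape::cophenetic.phylo(tree)
  d <- d[upper.tri(d)]
  pmax_theory <- (k_alpha - 1) / k_alpha
  if (target <= 0 || target >= pmax_theory)
    config_error("expected_pdistance must be in (0, ", pmax_theory, ")")
  f <- function(s) mean(pmax_theory * (1 - exp(-rate * s * d))) - target
  stats::uniroot(f, lower = 1e-9, upper = 1e9, tol = 1e-10)$root
}

#' Simulate sequence evolution with a known true alignment
#'
#' @param config a [sim_config()].
#' @return list with `true_alignment` (`msa`, all letters upper-case),
#'   `sequences` (named character vector, the unaligned leaves), and `tree`
#'   (the `phylo` tree the sequences evolved on).
#' @export
simulate_evolution <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  alpha <- sim_alphabet(config)
  with_seed(config$seed, {
    n <- config$n_taxa
    if (n == 1L) {
      res <- paste(sample(alpha, config$root_length, replace = TRUE), collapse = "")
      seqs <- stats::setNames(res, "t1")
      return(list(true_alignment = msa(seqs), sequences = seqs,
                  tree = single_tip_tree("t1")))
    }
    tree <- if (n == 2L) {
      structure(list(edge = matrix(c(3L, 3L, 1L, 2L), 2L, 2L),
                     tip.label = c("t1", "t2"), Nnode = 1L,
                     edge.length = stats::runif(2)),
                class = "phylo", order = "cladewise")
    } else {
      ape::rphylo(n, birth = 1, death = 0)
    }
    scale <- if (!is.null(config$expected_pdistance)) {
      calibrate_branch_scale(tree, config$subst_rate, length(alpha),
                             config$expected_pdistance)
    } else config$branch_scale
    tree$edge.length <- tree$edge.length * scale

    env <- new.env(parent = emptyenv())
    env$order <- seq_len(config$root_length)   # global column order of site ids
    env$next_id <- config$root_length + 1L

    root_state <- list(res = sample(alpha, config$root_length, replace = TRUE),
                       ids = seq_len(config$root_length))
    nt <- length(tree$tip.label)
    kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
    leaf_states <- vector("list", nt)
    walk <- function(node, state) {
      for (e in kids[[as.character(node)]]) {
        child <- tree$edge[e, 2L]
        st <- evolve_branch(state, tree$edge.length[e], config, alpha, env)
        if (child <= nt) leaf_states[[child]] <<- st else walk(child, st)
      }
    }
    walk(nt + 1L, root_state)

    used <- sort(unique(unlist(lapply(leaf_states, `[[`, "ids"))))
    cols <- env$order[env$order %in% used]
    mat <- matrix(GAP, nt, length(cols),
                  dimnames = list(tree$tip.label, NULL))
    for (i in seq_len(nt)) {
      st <- leaf_states[[i]]
      mat[i, match(st$ids, cols)] <- st$res
    }
    seqs <- stats::setNames(
      vapply(leaf_states, function(st) paste(st$res, collapse = ""), character(1)),
      tree$tip.label)
    if (any(!nzchar(seqs)))
      data_error("a simulated sequence was fully deleted; lower del_rate or branch lengths")
    list(true_alignment = new_msa(mat), sequences = seqs, tree = tree)
  })
}

evolve_branch <- function(state, bl, config, alpha, env) {
  res <- state$res
  ids <- state$ids
  len <- length(res)
  # substitutions
  if (len > 0L && config$subst_rate > 0) {
    p <- 1 - exp(-config$subst_rate * bl)
    hit <- stats::runif(len) < p
    if (any(hit)) res[hit] <- sample(alpha, sum(hit), replace = TRUE)
  }
  # deletions
  n_del <- stats::rpois(1L, config$del_rate * bl * len)
  for (d in seq_len(n_del)) {
    len <- length(res)
    if (len == 0L) break
    start <- sample.int(len, 1L)
    glen <- 1L + stats::rgeom(1L, config$indel_geom_p)
    idx <- start:min(len, start + glen - 1L)
    res <- res[-idx]; ids <- ids[-idx]
  }
  # insertions
  len <- length(res)
  n_ins <- stats::rpois(1L, config$ins_rate * bl * (len + 1L))
  for (d in seq_len(n_ins)) {
    len <- length(res)
    pos <- sample.int(len + 1L, 1L) - 1L    # insert after `pos` (0 = front)
    glen <- 1L + stats::rgeom(1L, config$indel_geom_p)
    new_ids <- env$next_id + seq_len(glen) - 1L
    env$next_id <- env$next_id + glen
    new_res <- sample(alpha, glen, replace = TRUE)
    # register the new site ids in the global column order
    at <- if (pos > 0L) match(ids[pos], env$order)
          else if (len > 0L) match(ids[1L], env$order) - 1L
          else length(env$order)
    env$order <- append(env$order, new_ids, after = at)
    res <- append(res, new_res, after = pos)
    ids <- append(ids, new_ids, after = pos)
  }
  list(res = res, ids = ids)
}

#' Average and maximum pairwise p-distance of an alignment
#'
#' p-distance is the normalized Hamming distance: the fraction of sites
#' where both rows have letters (case-insensitive) that do not match. Pairs
#' with no comparable site are skipped.
#'
#' @param x an `msa` with at least 2 rows.
#' @return list with `avg` and `max`.
#' @export
measure_pdistance <- function(x) {
  mat <- toupper(unclass(x))
  if (nrow(mat) < 2L) data_error("p-distance needs at least 2 rows")
  vals <- numeric(0)
  for (i in seq_len(nrow(mat) - 1L)) {
    for (j in (i + 1L):nrow(mat)) {
      both <- mat[i, ] != GAP & mat[j, ] != GAP
      nc <- sum(both)
      if (nc == 0L) next
      vals <- c(vals, sum(mat[i, both] != mat[j, both]) / nc)
    }
  }
  list(avg = mean(vals), max = max(vals))
}
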