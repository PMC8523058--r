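#' Sum-of-pairs alignment error (SPFP / SPFN / SP error)
#'
#' Compares an estimated alignment against a reference over the reference's
#' sequences. Homologous pairs are residue pairs placed upper-case in the
#' same column (see [homologous_pairs()]); lower-case letters are excluded
#' on *both* sides, so dissolved letters of a compressed alignment do not
#' count as homology claims. SPFP is the fraction of estimated pairs absent
#' from the reference; SPFN is the fraction of reference pairs absent from
#' the estimate; SP error is their arithmetic mean. An alignment with zero
#' pairs contributes 0 to its rate.
#'
#' The estimate is first restricted to the reference ids
#' ([restrict_alignment()]), so references over a subset of the sequences
#' score only those sequences.
#'
#' @param estimated an `msa`; its ids must be a superset of the reference's.
#' @param reference an `msa`.
#' @return list with `spfp`, `spfn`, `sp_error` and integer `counts`
#'   (`shared`, `estimated_only`, `reference_only`, `estimated`, `reference`).
#' @export
compare_alignments <- function(estimated, reference) {
  ref_ids <- msa_ids(reference)
  missing <- setdiff(ref_ids, msa_ids(estimated))
  if (length(missing))
    data_error("reference ids missing from estimate: ", paste(missing, collapse = ", "))
  est <- restrict_alignment(estimated, ref_ids)

  seq_e <- ungapped_sequences(est)
  seq_r <- ungapped_sequences(reference)
  bad <- names(seq_r)[seq_r != seq_e[names(seq_r)]]
  if (length(bad))
    data_error("sequences differ between estimate and reference for: ",
               paste(bad, collapse = ", "))

  n_est <- pair_count(est)
  n_ref <- pair_count(reference)
  shared <- shared_pair_count(est, reference)

  spfp <- if (n_est > 0) (n_est - shared) / n_est else 0
  spfn <- if (n_ref > 0) (n_ref - shared) / n_ref else 0
  list(spfp = spfp, spfn = spfn, sp_error = (spfp + spfn) / 2,
       counts = list(shared = shared,
                     estimated_only = n_est - shared,
                     reference_only = n_ref - shared,
                     estimated = n_est, reference = n_ref))
}

# pairs upper-case-homologous in both alignments, counted column-wise:
# map every (row, site) upper in the reference to its reference column; in
# each estimate column, residues sharing a reference column form C(g,2)
# shared pairs.
shared_pair_count <- function(est, ref) {
  ids <- msa_ids(ref)
  ref_mat <- unclass(ref)
  ref_site <- site_index_matrix(ref_mat)
  ref_up <- is_upper_matrix(ref_mat)
  # per id: vector over 0-based sites -> reference column or NA
  site_to_refcol <- lapply(ids, function(id) {
    r <- match(id, rownames(ref_mat))
    n_sites <- sum(!is.na(ref_site[r, ]))
    v <- rep(NA_integer_, n_sites)
    w <- which(!is.na(ref_site[r, ]) & ref_up[r, ])
    v[ref_site[r, w] + 1L] <- w
    v
  })
  names(site_to_refcol) <- ids

  est_mat <- unclass(est)
  est_site <- site_index_matrix(est_mat)
  est_up <- is_upper_matrix(est_mat)
  total <- 0
  for (j in seq_len(ncol(est_mat))) {
    rows <- which(est_up[, j])
    if (length(rows) < 2L) next
    refcols <- vapply(rows, function(r) {
      v <- site_to_refcol[[rownames(est_mat)[r]]]
      v[est_site[r, j] + 1L]
    }, integer(1))
    refcols <- refcols[!is.na(refcols)]
    if (length(refcols) < 2L) next
    total <- total + sum(choose(tabulate(match(refcols, unique(refcols))), 2))
  }
  total
}
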