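#' Sample backbone row sets across subalignments
#'
#' Each backbone draws an equal-sized random sample from every subalignment:
#' `floor(backbone_size / n_subsets)` rows per subset, with the remainder
#' distributed one row each to the first subsets; a subset smaller than its
#' quota contributes all of its rows. Sampling is without replacement,
#' deterministic per seed, and independent across backbones.
#'
#' @param subalignments list of `msa` objects (or of character id vectors),
#'   one per subset; at least 2.
#' @param num_backbones number of backbones to sample.
#' @param backbone_size target rows per backbone; must be >= the number of
#'   subsets.
#' @param seed integer seed.
#' @return list of backbone samples, each a data.frame with columns
#'   `subset` (1-based index) and `id`.
#' @export
sample_backbones <- function(subalignments, num_backbones, backbone_size, seed = 0L) {
  id_sets <- lapply(subalignments, function(x) if (inherits(x, "msa")) msa_ids(x) else x)
  k <- length(id_sets)
  if (k < 2L) config_error("backbones need at least 2 subalignments")
  if (backbone_size < k) config_error("backbone_size must be >= number of subsets")
  quota <- rep(backbone_size %/% k, k)
  extra <- backbone_size %% k
  if (extra > 0L) quota[seq_len(extra)] <- quota[seq_len(extra)] + 1L

  lapply(seq_len(num_backbones), function(b) {
    with_seed(child_seed(seed, b), {
      picks <- lapply(seq_len(k), function(s) {
        ids <- id_sets[[s]]
        take <- min(quota[s], length(ids))
        sample(ids, take)
      })
      data.frame(subset = rep(seq_len(k), lengths(picks)),
                 id = unlist(picks), stringsAsFactors = FALSE)
    })
  })
}

#' Align one backbone sample
#'
#' The sampled rows are degapped back to raw sequences and realigned from
#' scratch by the base aligner. If an external aligner fails, the built-in
#' progressive aligner is used instead, with a warning.
#'
#' @param sample one element of [sample_backbones()].
#' @param subalignments list of `msa` objects indexed by `sample$subset`.
#' @param aligner a base aligner function `(sequences, seed) -> msa`
#'   (see [resolve_aligner()] values); default the built-in aligner.
#' @param seed seed forwarded to the aligner.
#' @return an `msa` over exactly the sampled ids.
#' @export
align_backbone <- function(sample, subalignments, aligner = NULL, seed = 0L) {
  seqs <- character(0)
  for (s in unique(sample$subset)) {
    ids <- sample$id[sample$subset == s]
    sub_seqs <- ungapped_sequences(subalignments[[s]])
    missing <- setdiff(ids, names(sub_seqs))
    if (length(missing)) data_error("backbone ids not in subalignment ", s, ": ",
                                    paste(missing, collapse = ", "))
    seqs <- c(seqs, sub_seqs[ids])
  }
  aligner <- aligner %||% function(x, seed = 0L) builtin_progressive_align(x, seed = seed)
  aln <- tryCatch(aligner(seqs, seed = seed), error = function(e) {
    warning("base aligner failed (", conditionMessage(e),
            "); falling back to the built-in aligner", call. = FALSE)
    builtin_progressive_align(seqs, seed = seed)
  })
  check_aligner_output(aln, seqs)
  aln
}
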