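#' Naive block-concatenation of subalignments
#'
#' The trivial way to combine independently aligned subsets: stack them into
#' disjoint column blocks, padding every other subset's rows with gaps. No
#' cross-subset residue is ever placed in a shared column, so all
#' cross-subset homology is lost. Serves as the do-nothing merge baseline
#' against which the graph-clustering merge is measured.
#'
#' @param subalignments list of `msa` objects over disjoint id sets.
#' @return an `msa` of length `sum(lengths)` with block-diagonal structure.
#' @export
concat_disjoint <- function(subalignments) {
  lens <- vapply(subalignments, alignment_length, integer(1))
  total <- sum(lens)
  offs <- c(0L, cumsum(lens))
  blocks <- vector("list", length(subalignments))
  for (s in seq_along(subalignments)) {
    mat <- unclass(subalignments[[s]])
    block <- matrix(GAP, nrow(mat), total, dimnames = list(rownames(mat), NULL))
    block[, offs[s] + seq_len(lens[s])] <- mat
    blocks[[s]] <- block
  }
  new_msa(do.call(rbind, blocks))
}
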