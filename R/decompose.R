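#' Plan the decomposition and recursion behaviour of a run
#'
#' The dataset is broken into at most `max_num_subsets` pieces, giving a
#' target subset size of `ceiling(n / max_num_subsets)`. Subsets larger than
#' the recursion threshold are aligned by a nested pipeline run instead of
#' the base aligner; the default threshold is the greater of the backbone
#' size and the target subset size, and can be overridden by the user.
#'
#' @param n_sequences dataset size (>= 1).
#' @param max_num_subsets maximum number of decomposition subsets (default 25).
#' @param backbone_size rows per backbone alignment (default 200).
#' @param user_threshold optional recursion threshold override.
#' @param recurse_enabled allow nested runs at all?
#' @return list of class `decomposition_plan` with fields `max_num_subsets`,
#'   `target_subset_size`, `recursion_threshold`, `recurse_enabled`.
#' @export
make_plan <- function(n_sequences, max_num_subsets = 25L, backbone_size = 200L,
                      user_threshold = NULL, recurse_enabled = TRUE) {
  if (n_sequences < 1L) config_error("n_sequences must be >= 1")
  if (max_num_subsets < 1L) config_error("max_num_subsets must be >= 1")
  if (backbone_size < 1L) config_error("backbone_size must be >= 1")
  target <- as.integer(ceiling(n_sequences / max_num_subsets))
  threshold <- if (!is.null(user_threshold)) {
    if (user_threshold < 1L) config_error("recursion threshold must be >= 1")
    as.integer(user_threshold)
  } else {
    as.integer(max(backbone_size, target))
  }
  structure(list(max_num_subsets = as.integer(max_num_subsets),
                 target_subset_size = target,
                 recursion_threshold = threshold,
                 recurse_enabled = isTRUE(recurse_enabled)),
            class = "decomposition_plan")
}

#' Should a subset be aligned by a nested pipeline run?
#'
#' True iff recursion is enabled and the subset is strictly larger than the
#' plan's recursion threshold; smaller subsets go to the base aligner.
#'
#' @param subset_size number of sequences in the subset.
#' @param plan a [make_plan()] result.
#' @return logical flag.
#' @export
should_recurse <- function(subset_size, plan) {
  stopifnot(inherits(plan, "decomposition_plan"))
  plan$recurse_enabled && subset_size > plan$recursion_threshold
}
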