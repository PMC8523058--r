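#' On-disk subalignment store with a one-at-a-time loading contract
#'
#' During graph building and final assembly, subalignments are streamed from
#' disk one at a time, bounding the merge's memory footprint by the largest
#' subalignment instead of their sum. The store counts concurrently loaded
#' subalignments and records the maximum, which instruments this contract.
#'
#' @param x list of FASTA paths (one aligned file per subset) or a list of
#'   in-memory `msa` objects (wrapped for interface uniformity; in-memory
#'   objects are not counted against the contract).
#' @return a `subalignment_store` environment. Use [store_load()],
#'   [store_release()], [store_max_loaded()], `length()`.
#' @export
subalignment_store <- function(x) {
  st <- new.env(parent = emptyenv())
  is_path <- function(e) is.character(e) && length(e) == 1L && !inherits(e, "msa")
  if (length(x) > 0L && all(vapply(x, is_path, logical(1)))) {
    st$paths <- unlist(x)
    st$objects <- NULL
    st$n <- length(st$paths)
  } else {
    st$paths <- NULL
    st$objects <- x
    st$n <- length(x)
  }
  st$active <- 0L
  st$max_active <- 0L
  class(st) <- "subalignment_store"
  st
}

#' @export
length.subalignment_store <- function(x) x$n

#' @rdname subalignment_store
#' @param store a `subalignment_store`.
#' @param i subset index.
#' @return [store_load()] returns the `msa`; the caller must call
#'   [store_release()] before loading another subset.
#' @export
store_load <- function(store, i) {
  store$active <- store$active + 1L
  store$max_active <- max(store$max_active, store$active)
  if (is.null(store$paths)) store$objects[[i]] else read_fasta(store$paths[i], aligned = TRUE)
}

#' @rdname subalignment_store
#' @export
store_release <- function(store, i) {
  store$active <- store$active - 1L
  invisible(NULL)
}

#' @rdname subalignment_store
#' @export
store_max_loaded <- function(store) store$max_active
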