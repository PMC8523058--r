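#' Estimated on-disk size of an alignment
#'
#' The size in bytes of the alignment written as single-line FASTA
#' ([write_fasta()] with `wrap_width = 0`): per row, `1 + nchar(id) + 1`
#' header bytes plus `L + 1` sequence bytes (trailing newlines included).
#'
#' @param x an `msa`.
#' @return numeric byte count.
#' @export
estimate_size <- function(x) {
  sum(nchar(msa_ids(x)) + 2) + nrow(x) * (ncol(x) + 1)
}

# nearest gap reachable from `col` in direction `dir` for row `r`, crossing
# only lower-case letters; NA when blocked by an upper-case letter or the
# alignment edge
find_gap <- function(mat, r, col, dir) {
  j <- col + dir
  while (j >= 1L && j <= ncol(mat)) {
    ch <- mat[r, j]
    if (ch == GAP) return(j)
    if (ch == toupper(ch)) return(NA_integer_)  # upper-case blocks
    j <- j + dir
  }
  NA_integer_
}

#' Dissolve one alignment column
#'
#' Every letter in the column is demoted to lower-case (it no longer claims
#' homology) and shunted sideways into the nearest gap in its own row:
#' leftward if possible, else rightward. Lower-case letters standing in the
#' way are shunted one step further in the same direction (the domino
#' effect); an upper-case letter blocks the direction, and if any letter in
#' the column is blocked in both directions the whole move is invalid and
#' the alignment is returned unchanged. On success the emptied column is
#' deleted, shortening the alignment by one.
#'
#' @param x an `msa`.
#' @param col 1-based column index.
#' @return list with `alignment` (an `msa`) and `moved` (logical).
#' @export
dissolve_column <- function(x, col) {
  mat <- unclass(x)
  if (col < 1L || col > ncol(mat)) config_error("column index out of range")
  rows <- which(mat[, col] != GAP)

  dest <- integer(length(rows))
  dir <- integer(length(rows))
  for (i in seq_along(rows)) {
    r <- rows[i]
    g <- find_gap(mat, r, col, -1L)
    if (!is.na(g)) { dest[i] <- g; dir[i] <- -1L; next }
    g <- find_gap(mat, r, col, +1L)
    if (!is.na(g)) { dest[i] <- g; dir[i] <- +1L; next }
    return(list(alignment = x, moved = FALSE))
  }

  for (i in seq_along(rows)) {
    r <- rows[i]; g <- dest[i]
    if (dir[i] == -1L) {
      if (g < col - 1L) mat[r, g:(col - 2L)] <- mat[r, (g + 1L):(col - 1L)]
      mat[r, col - 1L] <- tolower(mat[r, col])
    } else {
      if (g > col + 1L) mat[r, (col + 2L):g] <- mat[r, (col + 1L):(g - 1L)]
      mat[r, col + 1L] <- tolower(mat[r, col])
    }
    mat[r, col] <- GAP
  }
  list(alignment = new_msa(mat[, -col, drop = FALSE]), moved = TRUE)
}

#' Conservative lossy (or lossless) alignment compression
#'
#' Shrinks an alignment toward a target serialized size by dissolving
#' columns one at a time ([dissolve_column()]), always choosing the column
#' with the fewest upper-case letters (ties: leftmost) that admits a valid
#' move. Dissolving a column with `u` upper-case letters destroys exactly
#' `choose(u, 2)` homologous pairs, so dissolving columns with at most one
#' upper-case letter is lossless; `lossless_only = TRUE` restricts the
#' procedure to such columns. The loop stops when the size threshold is
#' reached or no dissolvable candidate remains.
#'
#' @param x an `msa`.
#' @param size_threshold_bytes target size (default 1e11, i.e. 100 GB);
#'   compare with [estimate_size()].
#' @param lossless_only only dissolve columns with <= 1 upper-case letter.
#' @return list with `alignment` and `report` (fields `columns_dissolved`,
#'   `pairs_lost`, `size_before`, `size_after`, `lossless`).
#' @export
compress_alignment <- function(x, size_threshold_bytes = 1e11,
                               lossless_only = FALSE) {
  size_before <- estimate_size(x)
  dissolved <- 0L
  pairs_lost <- 0
  repeat {
    if (estimate_size(x) <= size_threshold_bytes) break
    u <- colSums(is_upper_matrix(unclass(x)))
    cand <- order(u, seq_along(u))
    if (lossless_only) cand <- cand[u[cand] <= 1L]
    moved <- FALSE
    for (col in cand) {
      res <- dissolve_column(x, col)
      if (res$moved) {
        x <- res$alignment
        dissolved <- dissolved + 1L
        pairs_lost <- pairs_lost + choose(u[col], 2)
        moved <- TRUE
        break
      }
    }
    if (!moved) break
  }
  list(alignment = x,
       report = list(columns_dissolved = dissolved,
                     pairs_lost = pairs_lost,
                     size_before = size_before,
                     size_after = estimate_size(x),
                     lossless = pairs_lost == 0))
}
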