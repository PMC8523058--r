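#' Multiple sequence alignment objects
#'
#' An `msa` is a rectangular gapped character matrix with one row per
#' sequence. Each cell is an upper-case letter (aligned, homology-bearing),
#' a lower-case letter (present in the sequence but not aligned -- e.g. a
#' letter dissolved by [compress_alignment()]), or the gap character `"-"`.
#' Row names are the sequence ids. Stripping gaps and upcasing any row
#' recovers the input sequence for that id, exactly.
#'
#' @param rows character vector of gapped strings, all the same length.
#' @param ids sequence ids; defaults to `names(rows)`.
#' @return An object of class `msa` (a character matrix).
#' @examples
#' a <- msa(c(s1 = "AC-GT", s2 = "ACTGT"))
#' alignment_length(a)
#' @export
msa <- function(rows, ids = names(rows)) {
  if (length(rows) == 0L) format_error("an alignment needs at least one row")
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
    format_error("every alignment row needs a non-empty id")
  if (anyDuplicated(ids)) format_error("duplicate sequence ids: ",
                                       paste(unique(ids[duplicated(ids)]), collapse = ", "))
  L <- unique(nchar(rows))
  if (length(L) != 1L) format_error("alignment rows have unequal lengths")
  mat <- matrix(GAP, nrow = length(rows), ncol = L, dimnames = list(ids, NULL))
  if (L > 0L) {
    for (i in seq_along(rows)) mat[i, ] <- strsplit(rows[[i]], "", fixed = TRUE)[[1L]]
  }
  new_msa(mat)
}

new_msa <- function(mat) {
  stopifnot(is.matrix(mat), is.character(mat), !is.null(rownames(mat)))
  structure(mat, class = c("msa", "matrix", "array"))
}

#' @export
print.msa <- function(x, n = 6L, width = 60L, ...) {
  cat(sprintf("<msa: %d sequences x %d columns>\n", nrow(x), ncol(x)))
  show <- utils::head(seq_len(nrow(x)), n)
  s <- msa_strings(x)[show]
  trunc <- nchar(s) > width
  s[trunc] <- paste0(substr(s[trunc], 1, width), "...")
  cat(sprintf("%-12s %s\n", substr(names(s), 1, 12), s), sep = "")
  if (nrow(x) > n) cat(sprintf("... and %d more rows\n", nrow(x) - n))
  invisible(x)
}

#' @rdname msa
#' @param x an `msa` object.
#' @export
alignment_length <- function(x) ncol(x)

#' @rdname msa
#' @export
msa_ids <- function(x) rownames(x)

#' Rows of an alignment as gapped strings
#' @param x an `msa`.
#' @return named character vector of gapped row strings.
#' @export
msa_strings <- function(x) {
  stats::setNames(apply(unclass(x), 1L, paste, collapse = ""), rownames(x))
}

#' Recover the unaligned sequences from an alignment
#'
#' Strips gaps and upcases every row. For every alignment produced by this
#' package this is exactly the set of input sequences (letter conservation).
#'
#' @param x an `msa`.
#' @return named character vector of ungapped, upper-case sequences.
#' @export
ungapped_sequences <- function(x) {
  toupper(gsub(GAP, "", msa_strings(x), fixed = TRUE))
}

#' Validate a set of unaligned sequences
#'
#' @param seqs named character vector: ids -> residue strings (no gaps).
#' @return `seqs`, upcased, invisibly on success; errors otherwise.
#' @export
validate_sequences <- function(seqs) {
  if (length(seqs) == 0L) format_error("no sequences")
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) format_error("sequences must be named with non-empty ids")
  if (anyDuplicated(ids)) format_error("duplicate sequence ids")
  if (any(!nzchar(seqs))) format_error("empty sequence for id: ",
                                       paste(ids[!nzchar(seqs)], collapse = ", "))
  if (any(grepl("-", seqs, fixed = TRUE))) format_error("unaligned sequences must not contain gaps")
  if (any(grepl("[^A-Za-z]", seqs))) format_error("sequences contain non-letter characters")
  invisible(stats::setNames(toupper(seqs), ids))
}

#' Guess whether sequences are nucleotide or amino acid
#'
#' Case-insensitive membership test: if every letter is an IUPAC nucleotide
#' code the dataset is treated as nucleotide, otherwise as protein.
#'
#' @param seqs character vector of sequences (gaps tolerated).
#' @return `"nt"` or `"aa"`.
#' @export
detect_alphabet <- function(seqs) {
  letters_used <- unique(strsplit(toupper(paste(seqs, collapse = "")), "", fixed = TRUE)[[1L]])
  letters_used <- setdiff(letters_used, GAP)
  if (all(letters_used %in% NT_IUPAC)) "nt" else "aa"
}

# per-row ungapped site index (0-based) for each alignment cell; NA at gaps
site_index_matrix <- function(mat) {
  isres <- unclass(mat) != GAP
  idx <- matrix(NA_integer_, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  for (i in seq_len(nrow(mat))) {
    w <- which(isres[i, ])
    idx[i, w] <- seq_along(w) - 1L
  }
  idx
}

is_upper_matrix <- function(mat) {
  m <- unclass(mat)
  m != GAP & m == toupper(m)
}

#' Homologous residue pairs of an alignment
#'
#' Two residues are homologous iff they are both upper-case letters in the
#' same alignment column. Lower-case (unaligned) letters and gaps contribute
#' nothing. Residues are identified by their 0-based ungapped site index
#' within their sequence, so the pair set is invariant under insertion or
#' removal of alignment columns.
#'
#' @param x an `msa`.
#' @return character vector of canonical pair keys, one per unordered pair;
#'   see [pair_key()] for the encoding. Treat as a set.
#' @export
homologous_pairs <- function(x) {
  mat <- unclass(x)
  up <- is_upper_matrix(mat)
  site <- site_index_matrix(mat)
  ids <- rownames(mat)
  out <- vector("list", ncol(mat))
  for (j in seq_len(ncol(mat))) {
    rows <- which(up[, j])
    u <- length(rows)
    if (u < 2L) next
    cmb <- utils::combn(rows, 2L)
    out[[j]] <- pair_key(ids[cmb[1L, ]], site[cbind(cmb[1L, ], j)],
                         ids[cmb[2L, ]], site[cbind(cmb[2L, ], j)])
  }
  unlist(out) %||% character(0)
}

#' Canonical key for an unordered homology pair
#'
#' @param id_a,site_a,id_b,site_b pair components (vectorized); sites are
#'   0-based ungapped positions.
#' @return character keys, invariant under swapping the two endpoints.
#' @export
pair_key <- function(id_a, site_a, id_b, site_b) {
  swap <- id_a > id_b
  ifelse(swap,
         paste(id_b, site_b, id_a, site_a, sep = "\r"),
         paste(id_a, site_a, id_b, site_b, sep = "\r"))
}

#' Number of homologous pairs, without materializing them
#'
#' Column-wise accumulation of `choose(u, 2)` over the upper-case letter
#' count `u` of each column; equals `length(homologous_pairs(x))`.
#'
#' @param x an `msa`.
#' @return integer count.
#' @export
pair_count <- function(x) {
  u <- colSums(is_upper_matrix(unclass(x)))
  sum(choose(u, 2))
}

#' Restrict an alignment to a subset of its rows
#'
#' Keeps the given rows and removes columns that become all-gap, so that the
#' result is the induced subalignment. The homologous pair set of the result
#' equals the input's pairs restricted to `keep_ids`.
#'
#' @param x an `msa`.
#' @param keep_ids ids to keep (must all be rows of `x`); row order of the
#'   result follows `x`, not `keep_ids`.
#' @return an `msa`.
#' @export
restrict_alignment <- function(x, keep_ids) {
  missing <- setdiff(keep_ids, rownames(x))
  if (length(missing)) data_error("ids not in alignment: ", paste(missing, collapse = ", "))
  mat <- unclass(x)[rownames(x)[rownames(x) %in% keep_ids], , drop = FALSE]
  keep_cols <- colSums(mat != GAP) > 0L
  new_msa(mat[, keep_cols, drop = FALSE])
}
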