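#' Scoring matrix for profile columns
#'
#' Nucleotide data uses match +1 / mismatch -1; protein data uses BLOSUM62
#' (letters outside the BLOSUM62 alphabet are scored as 'X').
#' @keywords internal
#' @noRd
scoring_matrix <- function(letters_used, alphabet_kind) {
  if (alphabet_kind == "nt") {
    m <- matrix(-1, length(letters_used), length(letters_used),
                dimnames = list(letters_used, letters_used))
    diag(m) <- 1
    m
  } else {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    b62 <- e$BLOSUM62
    map <- ifelse(letters_used %in% rownames(b62), letters_used, "X")
    m <- b62[map, map, drop = FALSE]
    dimnames(m) <- list(letters_used, letters_used)
    m
  }
}

# letter-frequency profile of an alignment block: |letters| x L, gaps excluded
profile_freq <- function(mat, letters_used) {
  f <- matrix(0, length(letters_used), ncol(mat),
              dimnames = list(letters_used, NULL))
  for (a in letters_used) f[a, ] <- colSums(mat == a)
  f / nrow(mat)
}

# align two alignment blocks (character matrices) by profile-profile DP
merge_profiles <- function(m1, m2, sm, letters_used, gap_open, gap_extend) {
  f1 <- profile_freq(m1, letters_used)
  f2 <- profile_freq(m2, letters_used)
  S <- crossprod(f1, sm %*% f2)
  res <- .affine_align_path(S, gap_open, gap_extend)
  p1 <- res$path1
  p2 <- res$path2
  out <- matrix(GAP, nrow(m1) + nrow(m2), length(p1),
                dimnames = list(c(rownames(m1), rownames(m2)), NULL))
  out[seq_len(nrow(m1)), p1 > 0L] <- m1[, p1[p1 > 0L], drop = FALSE]
  out[nrow(m1) + seq_len(nrow(m2)), p2 > 0L] <- m2[, p2[p2 > 0L], drop = FALSE]
  out
}

#' Built-in progressive aligner
#'
#' Profile-profile Needleman-Wunsch with affine gap penalties, merged in the
#' order given by the k-mer neighbor-joining guide tree
#' ([build_fallback_tree()]). Nucleotide columns are scored match +1 /
#' mismatch -1; protein columns with BLOSUM62. Deterministic; letters are
#' conserved exactly. This is the package's self-contained base aligner;
#' any external tool can be plugged in instead via [external_aligner()].
#'
#' @param sequences named character vector of unaligned sequences.
#' @param gap_open gap opening penalty (applied to the first position of a
#'   gap run; default -4).
#' @param gap_extend gap extension penalty (default -1).
#' @param seed integer seed forwarded to the guide-tree construction.
#' @return an `msa` over exactly the input ids.
#' @export
builtin_progressive_align <- function(sequences, gap_open = -4, gap_extend = -1,
                                      seed = 0L) {
  sequences <- validate_sequences(sequences)
  ids <- names(sequences)
  if (length(sequences) == 1L)
    return(msa(sequences))
  kind <- detect_alphabet(sequences)
  letters_used <- sort(unique(strsplit(paste(sequences, collapse = ""), "",
                                       fixed = TRUE)[[1L]]))
  sm <- scoring_matrix(letters_used, kind)
  tree <- build_fallback_tree(sequences, seed = seed)

  seq_mat <- function(id) {
    matrix(strsplit(sequences[[id]], "", fixed = TRUE)[[1L]], nrow = 1L,
           dimnames = list(id, NULL))
  }
  nt <- length(tree$tip.label)
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  align_node <- function(node) {
    if (node <= nt) return(seq_mat(tree$tip.label[node]))
    kids <- children[[as.character(node)]]
    acc <- align_node(kids[1L])
    for (kid in kids[-1L])
      acc <- merge_profiles(acc, align_node(kid), sm, letters_used,
                            gap_open, gap_extend)
    acc
  }
  mat <- align_node(nt + 1L)
  new_msa(mat[ids, , drop = FALSE])
}

#' Wrap an external command-line aligner as a base aligner
#'
#' The contract is a command template with `{input}` and `{output}`
#' placeholders; the tool must read unaligned FASTA from `{input}` and
#' write aligned FASTA over exactly the same ids to `{output}`. Example:
#' `external_aligner("mafft --localpair --quiet {input} > {output}")`.
#'
#' @param command_template shell command template.
#' @return a function `(sequences) -> msa` usable as the `aligner` of
#'   [pipeline_config()].
#' @export
external_aligner <- function(command_template) {
  force(command_template)
  function(sequences, ...) {
    sequences <- validate_sequences(sequences)
    fin <- tempfile(fileext = ".fasta")
    fout <- tempfile(fileext = ".fasta")
    on.exit(unlink(c(fin, fout)), add = TRUE)
    write_fasta(sequences, fin)
    cmd <- gsub("{input}", fin, gsub("{output}", fout, command_template,
                                     fixed = TRUE), fixed = TRUE)
    status <- system(cmd, ignore.stdout = TRUE, ignore.stderr = TRUE)
    if (status != 0L || !file.exists(fout))
      stop_gcm("external aligner failed (exit ", status, "): ", cmd,
               class = "gcmalign_task_error")
    aln <- read_fasta(fout, aligned = TRUE)
    check_aligner_output(aln, sequences)
    aln
  }
}

# shared contract checks for any base aligner's output
check_aligner_output <- function(aln, sequences) {
  if (!setequal(msa_ids(aln), names(sequences)))
    data_error("aligner output ids do not match input ids")
  got <- ungapped_sequences(aln)[names(sequences)]
  if (!identical(unname(got), unname(toupper(sequences))))
    data_error("aligner output does not conserve the input letters")
  invisible(aln)
}

# resolve the `aligner` config value to a function(sequences, seed) -> msa
resolve_aligner <- function(aligner, gap_open = -4, gap_extend = -1) {
  if (is.function(aligner)) return(aligner)
  if (identical(aligner, "builtin")) {
    return(function(sequences, seed = 0L)
      builtin_progressive_align(sequences, gap_open, gap_extend, seed))
  }
  if (is.character(aligner) && length(aligner) == 1L)
    return(external_aligner(aligner))
  config_error("aligner must be 'builtin', a command template, or a function")
}
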