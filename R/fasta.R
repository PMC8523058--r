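#' Read sequences or an alignment from FASTA
#'
#' Ids are the header token up to the first whitespace and must be unique.
#' Only `"-"` is accepted as the gap character; `"."` is rejected with an
#' explicit error. When `aligned = TRUE` all records must have equal length
#' and letter case is preserved verbatim (lower-case encodes unaligned
#' letters, see [msa()]). When `aligned = FALSE` gaps are rejected and
#' lower-case input is upcased: unaligned input carries no homology
#' semantics.
#'
#' @param path FASTA file.
#' @param aligned read as an alignment (`msa`) rather than raw sequences.
#' @return an `msa` if `aligned`, else a named character vector of sequences.
#' @export
read_fasta <- function(path, aligned = FALSE) {
  if (!file.exists(path)) format_error("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) format_error("cannot parse FASTA ", path, ": ",
                                                   conditionMessage(e)))
  if (length(set) == 0L) format_error("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) format_error("record with empty id in ", path)
  if (anyDuplicated(ids))
    format_error("duplicate ids in ", path, ": ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", "))
  txt <- as.character(set)
  names(txt) <- ids
  if (any(grepl(".", txt, fixed = TRUE)))
    format_error("'.' characters found; only '-' is accepted as gap")
  if (aligned) {
    if (length(unique(nchar(txt))) != 1L)
      format_error("records have unequal lengths but aligned = TRUE")
    if (any(grepl("[^A-Za-z-]", txt))) format_error("invalid characters in alignment")
    msa(txt)
  } else {
    if (any(grepl("-", txt, fixed = TRUE)))
      format_error("gap characters in unaligned input")
    validate_sequences(txt)
  }
}

#' Write sequences or an alignment to FASTA
#'
#' Case is preserved; output is deterministic for identical input. With
#' `wrap_width = 0` (the default) each sequence is written on a single line,
#' which is the layout assumed by [estimate_size()].
#'
#' @param x an `msa` or a named character vector of sequences.
#' @param path output file.
#' @param wrap_width line width for sequence bodies; 0 = no wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, wrap_width = 0L) {
  if (inherits(x, "msa")) x <- msa_strings(x)
  if (is.null(names(x)) || any(!nzchar(names(x)))) format_error("records must be named")
  if (wrap_width < 0L) config_error("wrap_width must be >= 0")
  con <- tryCatch(file(path, "wb"), error = function(e) stop_gcm(
    "cannot open ", path, " for writing", class = "gcmalign_io_error"))
  on.exit(close(con), add = TRUE)
  lines <- character(0)
  for (i in seq_along(x)) {
    body <- x[[i]]
    if (wrap_width > 0L && nchar(body) > wrap_width) {
      starts <- seq(1L, nchar(body), by = wrap_width)
      body <- substring(body, starts, pmin(starts + wrap_width - 1L, nchar(body)))
    }
    lines <- c(lines, paste0(">", names(x)[i]), body)
  }
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
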