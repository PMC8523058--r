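#' @useDynLib gcmalign, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @keywords internal
"_PACKAGE"

GAP <- "-"

NT_ALPHABET <- c("A", "C", "G", "T")
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# IUPAC codes accepted on input (membership is case-insensitive)
NT_IUPAC <- c(NT_ALPHABET, "U", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
AA_IUPAC <- c(AA_ALPHABET, "B", "Z", "X", "J", "U", "O")

stop_gcm <- function(..., class) {
  stop(structure(
    class = c(class, "gcmalign_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

format_error <- function(...) stop_gcm(..., class = "gcmalign_format_error")
config_error <- function(...) stop_gcm(..., class = "gcmalign_config_error")
data_error   <- function(...) stop_gcm(..., class = "gcmalign_data_error")

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals do not disturb the
#' caller's RNG stream.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Derive a child seed from a parent seed and an index
#'
#' Deterministic seed streams for nested runs and per-task sampling; results
#' stay within the 32-bit integer range.
#' @param seed parent seed (integer).
#' @param index non-negative integer stream index.
#' @return integer seed.
#' @export
child_seed <- function(seed, index) {
  m <- 2147483647
  as.integer((as.numeric(seed) %% m * 1000003 + as.numeric(index) + 1) %% m)
}

# md5 of a character scalar (used for deterministic task ids)
hash_string <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  writeChar(x, f, eos = NULL)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
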