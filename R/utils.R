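#' Run code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' seeded helpers do not perturb the global random stream.
#'
#' @param seed integer seed, or `NULL` to leave the RNG untouched.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Derive a child seed from a master seed by a fixed offset, kept inside the
# 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000 + offset) %% .Machine$integer.max)
}

abort_format <- function(message, ...) {
  abort(message, class = "mirten_error_format", ...)
}

abort_usage <- function(message, ...) {
  abort(message, class = "mirten_error_usage", ...)
}

abort_domain <- function(message, ...) {
  abort(message, class = "mirten_error_domain", ...)
}

abort_lookup <- function(message, ...) {
  abort(message, class = "mirten_error_lookup", ...)
}

abort_parameter <- function(message, ...) {
  abort(message, class = "mirten_error_parameter", ...)
}

# Normalize identifiers: miRNA IDs are case-meaningful (miRBase convention),
# gene symbols are matched upper-cased.
normalize_mirna <- function(x) stringr::str_trim(as.character(x))

normalize_gene <- function(x) toupper(stringr::str_trim(as.character(x)))

# Read a plain-text identifier list: one per line, '#' comments and blank
# lines ignored.
read_id_list <- function(path) {
  if (!file.exists(path)) {
    abort_usage(paste0("input list not found: ", path))
  }
  lines <- readr::read_lines(path)
  lines <- stringr::str_trim(stringr::str_remove(lines, "#.*$"))
  lines[nzchar(lines)]
}
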