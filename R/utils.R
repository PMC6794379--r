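# Internal helpers shared across modules.

#' Run code under a temporary RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Normalize gene identifiers: strip whitespace and uppercase
#'
#' Applied identically by every reader so cross-file joins never fail on
#' letter case. Pass `normalize = FALSE` to a reader to keep ids verbatim.
#' @noRd
normalize_ids <- function(ids, normalize = TRUE) {
  ids <- trimws(ids)
  if (normalize) ids <- toupper(ids)
  ids
}

#' Canonical unordered edge key ("A|B" with A < B)
#' @noRd
edge_keys <- function(from, to) {
  paste(pmin(from, to), pmax(from, to), sep = "\r")
}

#' Lightweight rolling hash of a character scalar (provenance stamping only)
#' @noRd
rolling_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 0
  mod <- 2147483647  # 2^31 - 1; 31 * mod < 2^53 so doubles stay exact
  for (b in bytes) h <- (h * 31 + b) %% mod
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
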