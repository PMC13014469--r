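# Classed error conditions used across the package.
ccb_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "cciboost_error")))
}

ccb_assert <- function(cond, class, msg, ...) {
  if (!isTRUE(cond)) ccb_stop(class, msg, ...)
  invisible(TRUE)
}

#' @noRd
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

# FNV-1a 32-bit hash of a string, returned as 8 hex digits.  Used for the
# run-manifest config hash; deterministic across platforms and sessions.
# 32-bit arithmetic is done exactly in doubles (xor on 16-bit halves,
# multiplication by 16777619 = 2^24 + 403 split to stay below 2^53).
fnv1a_hash <- function(s) {
  xor32 <- function(a, b) {
    bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536)) * 65536 +
      bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  }
  h <- 2166136261
  for (b in as.integer(charToRaw(s))) {
    h <- xor32(h, b)
    h <- ((h %% 256) * 16777216 + h * 403) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# canonical JSON of a (possibly nested) config list for hashing
config_json <- function(x) {
  sort_rec <- function(v) {
    if (is.list(v)) {
      v <- v[order(names(v))]
      lapply(v, sort_rec)
    } else v
  }
  jsonlite::toJSON(sort_rec(x), auto_unbox = TRUE, digits = NA)
}

#' Hash an effective run configuration
#'
#' Produces a short deterministic hex digest of a configuration list, used in
#' run manifests so that identical runs can be recognized.
#'
#' @param config a named list (may be nested).
#' @return an 8-character hex string.
#' @export
config_hash <- function(config) {
  fnv1a_hash(as.character(config_json(config)))
}
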