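## Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded package internals
#' never disturb a user's random stream.
#' @noRd
with_seed <- function(seed, expr) {
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
  force(expr)
}

## Derive a child seed from a parent seed and a character key, staying
## within 32-bit integer range. Simple polynomial string hash.
child_seed <- function(seed, key) {
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(paste(key, collapse = "|"))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

stop_validation <- function(...) {
  stop(structure(
    class = c("cytoscreen_validation_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_key <- function(...) {
  stop(structure(
    class = c("cytoscreen_key_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_format <- function(...) {
  stop(structure(
    class = c("cytoscreen_format_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

## scalar checks
is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x == floor(x) && x >= 0
}

`%||%` <- function(a, b) if (is.null(a)) b else a
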