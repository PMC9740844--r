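#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stop_ctx <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "muscleomics_error")))
}

assert_count <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) ||
      (positive && x <= 0) || (!positive && x < 0))
    stop_ctx(name, " must be a ", if (positive) "positive " else "non-negative ",
             "integer", class = "config_error")
  as.integer(x)
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_ctx(name, " must lie in [0, 1]", class = "config_error")
  as.numeric(x)
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop_ctx(name, " must be a positive number", class = "config_error")
  as.numeric(x)
}

## FNV-1a 32-bit hash of a character scalar, as 8 hex digits.  Used to stamp
## every output table with the configuration that produced it.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 0x811c9dc5
  for (b in bytes) {
    ## xor only touches the low byte (b < 256); keeps h representable exactly
    h <- h - h %% 256 + bitwXor(h %% 256, b)
    ## 32-bit modular multiply by the FNV prime 16777619, done in two halves
    ## because R doubles lose integer precision past 2^53
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
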