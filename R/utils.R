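# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' @keywords internal
is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)
}

#' Deterministic fingerprint of an R object
#'
#' Polynomial rolling hash (mod 2^31 - 1) over the object's deparsed form.
#' Used to stamp pipeline manifests with a reproducible configuration id;
#' not cryptographic.
#' @keywords internal
config_fingerprint <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 0
  m <- 2147483647
  for (b in bytes) h <- (h * 31 + b) %% m
  sprintf("%08x", as.integer(h))
}

# derive a stream-specific seed below 2^31 from a base seed
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * offset) %% 2147483647L)
}
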