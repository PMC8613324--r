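#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so package functions never clobber global randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

#' Derive a child seed from a parent seed and a key
#'
#' Deterministic 31-bit hash of the parent seed and any number of key parts
#' (fold index, classifier name, ...). Used so that one experiment seed fans
#' out to generator, fold and classifier seeds without shared RNG streams.
#'
#' @param seed parent integer seed.
#' @param ... key parts, coerced to character.
#' @return an integer in [0, 2^31 - 2].
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(format(as.integer(seed)), vapply(list(...), function(x)
    paste(format(x), collapse = ","), character(1))), collapse = "|")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
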