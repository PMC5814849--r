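#' Derive a reproducible sub-stream seed
#'
#' Mixes a master seed with a character tag so that independent stochastic
#' components (the two arm samplers, per-condition burst generators,
#' bootstraps) each get their own deterministic stream.
#'
#' @param seed Integer master seed.
#' @param tag Character label of the sub-stream.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  h <- abs(as.numeric(seed)) %% 2147483647
  for (code in utf8ToInt(as.character(tag))) {
    h <- (h * 31 + code) %% 2147483629
  }
  as.integer(h %% 2147483647)
}

# internal: scalar positive / non-negative checks with a readable message
.check_num <- function(x, name, min = -Inf, strict = FALSE, allow_inf = FALSE) {
  if (!is.numeric(x) || anyNA(x)) {
    stop(sprintf("'%s' must be numeric and non-missing", name), call. = FALSE)
  }
  if (!allow_inf && any(!is.finite(x))) {
    stop(sprintf("'%s' must be finite", name), call. = FALSE)
  }
  bad <- if (strict) any(x <= min) else any(x < min)
  if (bad) {
    stop(sprintf(
      "'%s' must be %s %g", name, if (strict) ">" else ">=", min
    ), call. = FALSE)
  }
  invisible(x)
}
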