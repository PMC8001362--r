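# Internal helpers: classed errors and scoped RNG.

stop_domain <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("steatoquant_domain_error", "steatoquant_error")))
}

stop_io <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("steatoquant_io_error", "steatoquant_error")))
}

stop_format <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("steatoquant_format_error", "steatoquant_error")))
}

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state so no
# package operation disturbs global randomness.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

is_binary_mask <- function(x) {
  is.matrix(x) && all(x %in% c(0, 1))
}

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_domain("`%s` must be a positive finite scalar (got %s)", name,
                paste(format(x), collapse = ","))
  invisible(x)
}
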