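# Evaluate expr with a private RNG state seeded by `seed`; the caller's
# .Random.seed is untouched.  Every stochastic operation in the package
# funnels through this so that a single integer seed fixes all output.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  has_old <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stream index, staying below 2^31.
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + 104729 * as.numeric(stream)) %% 2147483587
}

#' Harmonic number
#'
#' \code{harmonic_alpha(n)} returns \eqn{\alpha = \sum_{i=1}^{n-1} 1/i}, the
#' normalization constant used to compare pan-genome sizes across species
#' with different numbers of sampled strains.
#'
#' @param n integer number of strains (>= 2).
#' @return the harmonic sum as a double.
#' @export
harmonic_alpha <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n))
    stop("n must be a single integer >= 2")
  sum(1 / seq_len(n - 1L))
}

abort_category <- function(category, msg) {
  cond <- structure(
    class = c(category, "nepan_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_symmetric <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m) ||
      !isTRUE(all.equal(m, t(m), tolerance = 1e-8, check.attributes = FALSE)))
    abort_category("validation_error", "distance matrix must be symmetric")
  invisible(TRUE)
}
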