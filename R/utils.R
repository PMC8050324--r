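## Internal helpers shared across modules.

## Evaluate a seeded expression without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(old <- get0(".Random.seed", envir = globalenv()))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

## Deterministic sub-seed derivation; stays inside 32-bit integer range.
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483647)
}

## Polynomial coefficient arithmetic (ascending powers).
poly_add <- function(a, b) {
  n <- max(length(a), length(b))
  c(a, rep(0, n - length(a))) + c(b, rep(0, n - length(b)))
}

poly_mult <- function(a, b) {
  out <- rep(0, length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    out[i + seq_along(b) - 1L] <- out[i + seq_along(b) - 1L] + a[i] * b
  }
  out
}

#' Evaluate a polynomial given ascending coefficients
#'
#' @param coefs Numeric coefficients \code{c(a0, a1, ..., ad)} of
#'   \eqn{a_0 + a_1 x + \dots + a_d x^d}.
#' @param x Points at which to evaluate.
#' @return Numeric vector \code{p(x)}.
#' @export
eval_poly <- function(coefs, x) {
  out <- rep(0, length(x))
  for (j in rev(seq_along(coefs))) out <- out * x + coefs[j]
  out
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "ch4hyst_domain_error")
  }
}
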