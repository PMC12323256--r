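# Internal numeric helpers shared across modules.

#' @keywords internal
softplus <- function(x) {
  # log(1 + exp(x)), stable for large |x|
  out <- pmax(x, 0) + log1p(exp(-abs(x)))
  out
}

#' @keywords internal
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Numerically stable log(sigmoid(x)).
#' Finite for |x| up to well beyond 1e4.
#' @keywords internal
log_sigmoid <- function(x) {
  -(pmax(-x, 0) + log1p(exp(-abs(x))))
}

#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' @keywords internal
relu <- function(x) pmax(x, 0)

#' Derive a child seed from a parent seed and a stream label, staying
#' inside 32-bit integer range.
#' @keywords internal
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483587L)
}

#' Row-normalize a matrix to unit L2 norm.
#' @keywords internal
l2_normalize_rows <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm == 0)) stop("cannot L2-normalize a zero row")
  x / nrm
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
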