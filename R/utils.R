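# internal numerical helpers

# log(sum(exp(x))) without overflow; -Inf-safe
logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

logMeanExp <- function(x) logSumExp(x) - log(length(x))

# log(1 - exp(-h)) for hazard h >= 0, stable at both ends
log1mexpNeg <- function(h) {
  out <- numeric(length(h))
  small <- h <= log(2)
  out[small] <- log(-expm1(-h[small]))
  out[!small] <- log1p(-exp(-h[!small]))
  out
}

cloglogInv <- function(eta) -expm1(-exp(eta))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
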