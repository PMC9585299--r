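# Internal numerical helpers.

# log(sum(exp(x))) without overflow; x may contain -Inf.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Orders q within this window of 1 are evaluated with the exponential-entropy
# limit formula; the power-mean form is singular at q = 1.
Q_ONE_EPS <- 1e-8

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x > 0 && x == round(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
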