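#' @importFrom stats rnorm rbinom runif qnorm pnorm dnorm pchisq qchisq sd var
#' @importFrom stats integrate uniroot optimize optim plogis cor glm.fit
#' @importFrom stats binomial pt complete.cases setNames
#' @importFrom utils head
NULL

# Derive a stream-specific 32-bit seed from a master seed; keeps every source
# of randomness tied to one user-visible integer.
sub_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((abs(seed) * 7919 + stream * 104729) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

msg <- function(...) message("[gatescores] ", ...)

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
  invisible(TRUE)
}
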