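# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# state; seed = NULL means "use the current RNG stream".
with_seed_or_current <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

# log(sum(exp(x))) along rows of a matrix, numerically stable.
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_named <- function(class, msg, call. = FALSE) {
  cnd <- structure(
    class = c(class, "streamscore_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  )
  stop(cnd)
}

assert_that <- function(ok, class, msg) {
  if (!isTRUE(ok)) stop_named(class, msg)
  invisible(TRUE)
}
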