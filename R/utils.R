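#' @importFrom rlang abort warn .data
#' @importFrom stats sd cor lm pf pt coef predict optim rnorm runif rbinom var
#' @importFrom utils head
NULL

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. All exported stochastic operations route through
# this so that a seed argument fully determines their output.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministically derive a substream seed from a master seed and a tag path
# (e.g. region label, outer iteration, inner iteration). Keeps results per
# region / iteration independently reproducible. Stays below 2^31.
mix_seed <- function(seed, ...) {
  parts <- c(as.numeric(seed), as.numeric(c(...)))
  h <- 0
  for (p in parts) h <- (h * 7919 + (p %% 2147483647) + 1) %% 2147483629
  as.integer(h %% 2147483587 + 1)
}

assert_that <- function(ok, msg, class = "regionbag_error") {
  if (!isTRUE(ok)) abort(msg, class = c(class, "regionbag_error"))
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
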