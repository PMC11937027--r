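#' @keywords internal
"_PACKAGE"

# numerical floor shared by all variance / denominator guards
EPS <- 1e-8

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a temporary RNG seed, restoring the caller's RNG state.
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
    set.seed(seed)
  }
  force(code)
}

stop_if_not_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  }
}

frobenius <- function(M) sqrt(sum(M^2))
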