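# Internal helpers shared across modules.

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so library code never perturbs user seeds.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
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
  force(expr)
}

# Derive a reproducible child seed from a base seed, kept inside 32-bit range.
derive_seed <- function(seed, k) {
  (as.double(seed) * 48271 + 11 * as.double(k)) %% 2147483587
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cfg <- function(...) stop(sprintf(...), call. = FALSE)

assert_expr_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop_cfg("expression input must be a numeric matrix (genes x samples)")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m))) stop_cfg("gene ids must be unique rownames")
  if (is.null(colnames(m)) || anyDuplicated(colnames(m))) stop_cfg("sample ids must be unique colnames")
  if (!all(is.finite(m))) stop_cfg("expression matrix contains non-finite values")
  invisible(m)
}

expr_scale <- function(m) attr(m, "scale") %||% "log2"

set_expr_scale <- function(m, scale) {
  attr(m, "scale") <- match.arg(scale, c("counts", "log2"))
  m
}
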