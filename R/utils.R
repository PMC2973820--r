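# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without clobbering the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# log(exp(a) - exp(b)) for a >= b, stable when a ~ b or both very negative.
logspace_sub <- function(a, b) {
  stopifnot(all(a >= b | is.nan(b)))
  a + log1p(-exp(b - a))
}

# log(sum(exp(x))) without overflow.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Gauss-Legendre nodes/weights on [a, b]; cached per order.
.gl_cache <- new.env(parent = emptyenv())
gauss_legendre <- function(n, a = -1, b = 1) {
  key <- as.character(n)
  if (is.null(.gl_cache[[key]])) {
    .gl_cache[[key]] <- pracma::gaussLegendre(n, -1, 1)
  }
  gl <- .gl_cache[[key]]
  list(x = (b - a) / 2 * gl$x + (a + b) / 2, w = (b - a) / 2 * gl$w)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

is_point <- function(x) is.numeric(x) && length(x) == 2L && all(is.finite(x))
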