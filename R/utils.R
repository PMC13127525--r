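#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so seeded package functions do not disturb
# the global stream.
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

sigmoid <- function(z) 1 / (1 + exp(-z))

# log(1 + exp(x)) without overflow for large |x|
softplus <- function(x) {
  out <- x
  pos <- x > 0
  out[pos] <- x[pos] + log1p(exp(-x[pos]))
  out[!pos] <- log1p(exp(x[!pos]))
  out
}

# Stable elementwise BCE-with-logits, optionally with a positive-class weight:
#   l(z, y; w) = (1 - y) * z + (1 + (w - 1) * y) * softplus(-z) ... rearranged
# from -[w y log s(z) + (1 - y) log(1 - s(z))].
bce_with_logits <- function(z, y, pos_weight = 1) {
  # -log s(z) = softplus(-z); -log(1 - s(z)) = softplus(z)
  pos_weight * y * softplus(-z) + (1 - y) * softplus(z)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# deterministic child seed from a base seed and a stream label, kept < 2^31
child_seed <- function(seed, stream) {
  s <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  (as.integer(seed) * 7919L + as.integer(s %% 104729L)) %% 2147483647L
}

task_names <- function() c("alcohol", "nicotine", "cannabis", "any")
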