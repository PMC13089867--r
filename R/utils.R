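# internal helpers shared across modules

# Run `expr` under a local RNG state seeded with `seed`; the caller's RNG
# stream is untouched. `seed = NULL` means "use the current stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
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
  force(expr)
}

# Derive a child seed from a parent seed and a stream label, staying well
# below .Machine$integer.max so downstream set.seed() calls are valid.
child_seed <- function(seed, ...) {
  if (is.null(seed)) return(NULL)
  key <- paste(c(seed, ...), collapse = "/")
  raw <- as.numeric(utils::head(utf8ToInt(key), 50))
  as.integer((sum(raw * seq_along(raw) * 2654435) + as.numeric(seed)) %%
               2147480000)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
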