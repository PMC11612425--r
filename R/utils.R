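# internal helpers

# Evaluate `expr` under a temporary RNG state seeded with `seed`;
# the caller's RNG stream is restored afterwards.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a reproducible child seed from a master seed
#'
#' All randomness in the synthetic-data generator flows from one master
#' seed; per-sample and per-module streams are derived with this splitting
#' rule so that results do not depend on the order in which samples are
#' generated.
#'
#' @param seed master seed (integer).
#' @param ... further integers or strings identifying the child stream.
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
childSeed <- function(seed, ...) {
  tags <- list(...)
  h <- as.double(seed %% 2147483647L)
  for (tag in tags) {
    if (is.character(tag)) tag <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
    for (v in as.double(tag)) {
      h <- (h * 48271 + v + 1) %% 2147483647
    }
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
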