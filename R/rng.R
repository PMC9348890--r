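# Reproducibility: every stochastic operation takes a seed, and experiments
# derive an independent child seed per shot from (root seed, shot index), so
# shot i is reproducible regardless of execution order.

#' Derive a child seed from a root seed and stream indices
#'
#' Deterministic integer mixing via repeated Lehmer (Park-Miller) steps modulo
#' 2^31 - 1; all arithmetic stays below 2^53 so the result is exact in doubles
#' and platform independent. The returned seed is in `[1, 2^31 - 2]`.
#'
#' @param seed Root seed (integer-valued).
#' @param ... Further integer stream indices (e.g. shot index, stage id).
#' @return An integer seed suitable for [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647  # 2^31 - 1
  a <- 48271
  x <- (abs(as.numeric(seed)) %% (m - 1)) + 1
  for (k in c(...)) {
    x <- (a * x) %% m
    x <- (x + (abs(as.numeric(k)) %% (m - 1))) %% m
    if (x == 0) x <- 1
    x <- (a * x) %% m
  }
  x <- (a * x) %% m
  as.integer(x)
}

# run expr with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
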