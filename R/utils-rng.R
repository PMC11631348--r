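# Evaluate an expression under a local RNG stream seeded with 'seed',
# restoring the caller's RNG state afterwards. Every seeded function in
# the package uses this, so calling it never perturbs the caller's
# random-number stream (important inside permutation loops).
.withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}
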