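#' @include AllClasses.R
NULL

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards, so seeded package functions never disturb user code.
withSeed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

.edgeKey <- function(edges) {
  paste(edges$domain_protein, edges$class_id, edges$target_protein, sep = "\r")
}
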