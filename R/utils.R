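# Run code with a private RNG stream seeded from `seed`, restoring the
# caller's RNG state afterwards. All package randomness flows through this,
# so no function perturbs the global RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) stop("an explicit seed is required")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
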