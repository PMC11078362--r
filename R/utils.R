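# Evaluate expr under a temporary RNG seed, restoring the caller's
# RNG state afterwards; a NULL seed uses the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# observable-channel slab of a state array
obs_channels <- function(x, C_obs = state_C_obs(x)) {
  x[, , seq_len(C_obs), drop = FALSE]
}
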