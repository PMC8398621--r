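# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Raised-cosine bump of unit height centred at `centre` with total width
# `width`, evaluated at (vector) position s; zero outside the support.
raised_cosine <- function(s, centre, width) {
  ifelse(abs(s - centre) < width / 2,
         0.5 * (1 + cos(2 * pi * (s - centre) / width)),
         0)
}
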