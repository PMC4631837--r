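# internal helpers shared across modules

# Run code with a temporarily seeded RNG, restoring the caller's stream.
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

stopifnotScalarCount <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  as.integer(x)
}

# canonical property codes / antonym pairs / layers
aestheticProperties <- function() {
  data.frame(
    code = c("G1", "G2", "G3", "T1", "T2", "T3", "T4", "Q"),
    pair = c("warm-cold", "rough-smooth", "dark-light",
             "disordered-harmonious", "inelegant-elegant",
             "simple-complex", "artificial-natural", "like-dislike"),
    layer = c(rep("affective", 3), rep("judgment", 4), "emotional"),
    stringsAsFactors = FALSE)
}
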