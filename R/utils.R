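# Internal helpers shared across modules.

# Fixed base order used for major/minor tie-breaking (A < C < G < T).
.BASES <- c("A", "C", "G", "T")

# Column order of the six pileup categories in the sync format.
.SYNC_CATEGORIES <- c("A", "T", "C", "G", "N", "del")

# Evaluate `expr` under a locally seeded RNG stream, restoring the caller's
# stream afterwards so seeded calls never perturb surrounding randomness.
# seed = NULL uses (and advances) the global stream.
.withSeed <- function(seed, expr) {
  expr <- substitute(expr)
  pf <- parent.frame()
  if (is.null(seed))
    return(eval(expr, pf))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single non-missing number or NULL")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had)
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had)
      assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval(expr, pf)
}

.assertCount <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min))
  as.integer(x)
}

.assertProb <- function(x, name, maxExclusive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1 ||
      (maxExclusive && x == 1))
    stop(sprintf("'%s' must be a probability in [0,%s", name,
                 if (maxExclusive) "1)" else "1]"))
  as.numeric(x)
}
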