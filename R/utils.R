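# internal helpers shared across modules

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards: generators stay pure functions of
# (parameters, seed) without clobbering the session RNG.
.with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# derive a per-item child seed from a master seed, kept inside 32-bit range
.child_seed <- function(seed, k) {
  (as.numeric(seed) * 10007 + as.numeric(k) * 7919) %% 2147483647
}

# Euclidean torsion angle a-b-c-d in degrees, vectorized over rows of
# n x 3 matrices; standard IUPAC sign convention.
.dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- .vcross(b1, b2)
  n2 <- .vcross(b2, b3)
  m1 <- .vcross(n1, .vunit(b2))
  atan2(rowSums(m1 * n2), rowSums(n1 * n2)) * 180 / pi
}
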