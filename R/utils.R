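# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
mk_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "mk_error")))
}

# Round half away from zero (report convention for integer tables).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Minimum-image convention on an orthorhombic box.
# d: n x 3 matrix of displacement vectors; box: length-3 edge vector (Angstrom).
min_image <- function(d, box) {
  d <- as.matrix(d)
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

# Pairwise minimum-image distances between two coordinate sets (n x 3, m x 3).
pair_dist_pbc <- function(a, b, box) {
  a <- matrix(as.numeric(a), ncol = 3)
  b <- matrix(as.numeric(b), ncol = 3)
  d2 <- matrix(0, nrow(a), nrow(b))
  for (k in 1:3) {
    dk <- outer(a[, k], b[, k], "-")
    dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}

# Mass-weighted centre of mass.
centre_of_mass <- function(coords, masses = NULL) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (is.null(masses)) masses <- rep(1, nrow(coords))
  colSums(coords * masses) / sum(masses)
}

# Deterministic per-operation seed stream: each stochastic operation draws from
# its own stream derived from (seed, op-name) so adding one operation never
# perturbs another.
mk_seed <- function(seed, op) {
  v <- utf8ToInt(op)
  h <- sum(v * seq_along(v)) %% 100000L
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483629)
}

# Evaluate expr under a given seed without disturbing the caller's RNG state.
with_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Uniform random unit vectors (n x 3).
runif_sphere <- function(n) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}

# An arbitrary unit vector orthogonal to d (length-3 unit vector).
orthogonal_unit <- function(d) {
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- ref - sum(ref * d) * d
  v / sqrt(sum(v^2))
}
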