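# Hand-built configurations and independent oracles used across tests.

# Build an mk_config from a list of molecules, each a list with fields
# species, roles (character), coords (n x 3), and optional names/resname.
toy_config <- function(mols, box, frames = NULL, time_per_frame = 1) {
  rows <- list(); coords <- list()
  for (i in seq_along(mols)) {
    m <- mols[[i]]
    n <- nrow(m$coords)
    rows[[i]] <- data.frame(
      name = m$names %||% paste0("X", seq_len(n)),
      resname = m$resname %||% substr(m$species, 1, 3),
      element = m$element %||% rep("C", n),
      molecule_id = i, species = m$species, role = m$roles,
      mass = m$mass %||% rep(1, n), stringsAsFactors = FALSE)
    coords[[i]] <- m$coords
  }
  xyz <- do.call(rbind, coords)
  mk_configuration(frames %||% list(xyz), box, do.call(rbind, rows),
                   time_per_frame = time_per_frame)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a minimal two-bead amphiphile (tail + terminal carbon)
bead_mol <- function(species, at, roles = c("TAIL_C", "TERMINAL_C"),
                     spread = 1.9) {
  k <- length(roles)
  list(species = species, roles = roles,
       coords = cbind(at[1] + (seq_len(k) - 1) * spread, at[2], at[3]))
}

# brute-force single-linkage clustering oracle: transitive closure of the
# molecule contact matrix
brute_force_clusters <- function(cfg, cutoff = 4.5,
                                 roles = c("TAIL_C", "TERMINAL_C"), frame = 1) {
  a <- cfg$atoms
  mols <- unique(a$molecule_id[a$species != "WATER"])
  box <- cfg$box[frame, ]
  n <- length(mols)
  adj <- diag(TRUE, n)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    xi <- cfg$frames[[frame]][a$molecule_id == mols[i] & a$role %in% roles, , drop = FALSE]
    xj <- cfg$frames[[frame]][a$molecule_id == mols[j] & a$role %in% roles, , drop = FALSE]
    if (nrow(xi) && nrow(xj) &&
        min(micellekit:::pair_dist_pbc(xi, xj, box)) <= cutoff)
      adj[i, j] <- adj[j, i] <- TRUE
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  # membership sets as sorted lists
  memb <- apply(adj, 1, function(r) paste(sort(mols[r]), collapse = ","))
  unname(memb)
}

# closed-form eigenvalues of a symmetric 3x3 matrix via the trigonometric
# solution of the characteristic cubic (independent of LAPACK)
eigen3_closed_form <- function(M) {
  p1 <- M[1, 2]^2 + M[1, 3]^2 + M[2, 3]^2
  q <- sum(diag(M)) / 3
  p2 <- sum((diag(M) - q)^2) + 2 * p1
  p <- sqrt(p2 / 6)
  if (p < 1e-300) return(rep(q, 3))
  B <- (M - q * diag(3)) / p
  r <- det(B) / 2
  r <- min(max(r, -1), 1)
  phi <- acos(r) / 3
  l1 <- q + 2 * p * cos(phi)
  l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  l2 <- 3 * q - l1 - l3
  sort(c(l1, l2, l3))
}

# closed-form prolate spheroid surface area (a > b = c)
prolate_area <- function(a, b) {
  e <- sqrt(1 - b^2 / a^2)
  2 * pi * b^2 * (1 + a / (b * e) * asin(e))
}

# Thomsen approximation to the triaxial ellipsoid area (p = 1.6075)
thomsen_area <- function(a, b, c, p = 1.6075) {
  4 * pi * (((a * b)^p + (a * c)^p + (b * c)^p) / 3)^(1 / p)
}

# uniform points inside an ellipsoid (rejection from the bounding box)
runif_ellipsoid <- function(n, axes) {
  out <- matrix(numeric(0), ncol = 3)
  while (nrow(out) < n) {
    p <- matrix(stats::runif(3 * 2 * n, -1, 1), ncol = 3)
    p <- p[rowSums(p^2) < 1, , drop = FALSE]
    out <- rbind(out, p)
  }
  sweep(out[seq_len(n), , drop = FALSE], 2, axes, "*")
}

# ideal-gas reference system: fixed tagged centers plus uniformly
# re-drawn water oxygens each frame
ideal_gas_config <- function(n_centers, n_b, box, n_frames, seed = 17) {
  set.seed(seed)
  centers <- matrix(runif(3 * n_centers, 0, box), ncol = 3)
  atoms <- data.frame(
    name = c(rep("C", n_centers), rep("OW", n_b)),
    resname = c(rep("FA6", n_centers), rep("SOL", n_b)),
    element = c(rep("C", n_centers), rep("O", n_b)),
    molecule_id = seq_len(n_centers + n_b),
    species = c(rep("FA", n_centers), rep("WATER", n_b)),
    role = c(rep("OTHER", n_centers), rep("WATER_O", n_b)),
    mass = 1)
  frames <- lapply(seq_len(n_frames), function(i)
    rbind(centers, matrix(runif(3 * n_b, 0, box), ncol = 3)))
  mk_configuration(frames, rep(box, 3), atoms)
}
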