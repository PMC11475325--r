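#' Specify a synthetic micelle-in-water system
#'
#' Defines the ground-truth structure the generator plants: a single micelle
#' with the given per-species composition and triaxial core geometry, free
#' monomers, and water filling the rest of an orthorhombic box. The
#' generator plants structure (it does not simulate dynamics): amphiphile
#' terminal carbons are sampled inside the core ellipsoid -- PC2C6 and FA
#' biased toward the centre, LYSO terminal carbons kept at radii of at least
#' 0.6 of the core (emulating partial interdigitation) -- while head-group
#' atoms sit at the outer (core + shell) surface for PC2C6/LYSO and just
#' outside the core boundary for FA.
#'
#' @param composition Named counts of micelle members,
#'   `c(PC2C6 = , LYSO = , FA = )` (missing names default to 0).
#' @param n_monomers Named counts of free monomers per species.
#' @param core_semi_axes Core ellipsoid semi-axes (Angstrom); sorted so that
#'   a >= b >= c.
#' @param headgroup_shell Head-group shell thickness (Angstrom).
#' @param box Box edge (Angstrom); must exceed
#'   `2 * (a + headgroup_shell + 10)`. Default is that bound plus 2.
#' @param water_density Water number density, molecules / Angstrom^3
#'   (0.0334 is bulk water at 300 K; 0 disables water).
#' @param n_frames Number of frames for [build_trajectory()].
#' @param jitter_sigma Per-frame Gaussian jitter of solute atoms (Angstrom).
#' @param time_per_frame Frame spacing, ns.
#' @param include_water_h Also place two water hydrogens per oxygen.
#' @param seed Integer seed; every stochastic step draws from its own stream
#'   derived from this seed, so results are fully reproducible.
#' @return An object of class `mk_micelle_spec`.
#' @export
micelle_spec <- function(composition = c(PC2C6 = 35, LYSO = 0, FA = 0),
                         n_monomers = c(PC2C6 = 0, LYSO = 0, FA = 0),
                         core_semi_axes = c(27.1, 15.7, 6.3),
                         headgroup_shell = 5, box = NULL,
                         water_density = 0.0334, n_frames = 1,
                         jitter_sigma = 0.5, time_per_frame = 1,
                         include_water_h = FALSE, seed = 1) {
  full <- function(x) {
    x <- unlist(x)
    out <- c(PC2C6 = 0, LYSO = 0, FA = 0)
    out[names(x)] <- x
    if (any(out < 0) || any(out != round(out)))
      mk_stop("species counts must be non-negative integers", "mk_spec_error")
    out
  }
  composition <- full(composition)
  n_monomers <- full(n_monomers)
  axes <- sort(as.numeric(core_semi_axes), decreasing = TRUE)
  if (length(axes) != 3 || any(axes <= 0))
    mk_stop("core_semi_axes must be three positive lengths", "mk_spec_error")
  min_box <- 2 * (axes[1] + headgroup_shell + 10)
  box <- box %||% (min_box + 2)
  if (box <= min_box)
    mk_stop(sprintf("box edge must exceed 2*(a + shell + 10) = %.1f Angstrom", min_box),
            "mk_spec_error")
  if (water_density < 0 || n_frames < 1 || jitter_sigma < 0)
    mk_stop("invalid water_density, n_frames or jitter_sigma", "mk_spec_error")
  structure(list(composition = composition, n_monomers = n_monomers,
                 core_semi_axes = axes, headgroup_shell = headgroup_shell,
                 box = box, water_density = water_density,
                 n_frames = as.integer(n_frames), jitter_sigma = jitter_sigma,
                 time_per_frame = time_per_frame,
                 include_water_h = include_water_h, seed = as.integer(seed)),
            class = "mk_micelle_spec")
}

#' Preset synthetic systems mirroring the simulated digestion series
#'
#' Presets `"C6"`, `"C6-25"`, `"C6-50"`, `"C6-75"`, `"C6-100"`, `"LYSO"` and
#' `"FA"` reproduce the total compositions of the seven simulated systems
#' (see [table3_compositions()]). The split between planted micelle members
#' and free monomers keeps most molecules in the micelle, with a few free
#' monomers of the more soluble species (all 35 PC2C6 in the micelle for
#' `C6`; 16/15/15 of 17/18/18 for `C6-50`); the pure-LYSO system forms no
#' micelle, so all 35 molecules are placed as monomers. Core semi-axes for the micelle-forming
#' presets use the 150 mM triaxial SANS fit (27.1, 15.7, 6.3 Angstrom); the
#' smaller pure-FA micelle uses a volume roughly proportional to its single
#' hexanoyl chain count.
#'
#' @param name Preset name.
#' @param seed Integer seed.
#' @param ... Overrides passed to [micelle_spec()] (e.g. `water_density = 0`,
#'   `n_frames`).
#' @return An `mk_micelle_spec`.
#' @export
micelle_preset <- function(name = c("C6", "C6-25", "C6-50", "C6-75", "C6-100",
                                    "LYSO", "FA"),
                           seed = 1, ...) {
  name <- match.arg(name)
  members <- switch(name,
    "C6"     = c(PC2C6 = 35, LYSO = 0,  FA = 0),
    "C6-25"  = c(PC2C6 = 25, LYSO = 7,  FA = 7),
    "C6-50"  = c(PC2C6 = 16, LYSO = 15, FA = 15),
    "C6-75"  = c(PC2C6 = 9,  LYSO = 21, FA = 23),
    "C6-100" = c(PC2C6 = 0,  LYSO = 30, FA = 33),
    "LYSO"   = c(PC2C6 = 0,  LYSO = 0,  FA = 0),
    "FA"     = c(PC2C6 = 0,  LYSO = 0,  FA = 31))
  monomers <- switch(name,
    "C6"     = c(PC2C6 = 0, LYSO = 0, FA = 0),
    "C6-25"  = c(PC2C6 = 1, LYSO = 2, FA = 2),
    "C6-50"  = c(PC2C6 = 1, LYSO = 3, FA = 3),
    "C6-75"  = c(PC2C6 = 0, LYSO = 5, FA = 3),
    "C6-100" = c(PC2C6 = 0, LYSO = 5, FA = 2),
    "LYSO"   = c(PC2C6 = 0, LYSO = 35, FA = 0),
    "FA"     = c(PC2C6 = 0, LYSO = 0, FA = 4))
  axes <- switch(name,
    "FA"   = c(18, 12, 6.2),
    "LYSO" = c(15, 12, 6),
    c(27.1, 15.7, 6.3))
  args <- list(composition = members, n_monomers = monomers,
               core_semi_axes = axes, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(micelle_spec, args)
}

# distance from the centre to the ellipsoid surface along unit vector d
ray_radius <- function(d, axes) 1 / sqrt(sum((d / axes)^2))

# Rodrigues rotation of vector v about unit axis k by angle th
rotate_about <- function(v, k, th) {
  v * cos(th) + pracma::cross(k, v) * sin(th) + k * sum(k * v) * (1 - cos(th))
}

# idealised straight-conformation template for a free monomer, head at origin
monomer_template <- function(species) {
  chain <- function(sx) rbind(
    c(1.5 * sx, 0, -4.0), c(2.9 * sx, 0, -5.2), c(1.5 * sx, 1.0, -6.0),
    c(1.5 * sx, -1.0, -7.5), c(1.5 * sx, 1.0, -9.0), c(1.5 * sx, -1.0, -10.5),
    c(1.5 * sx, 0, -12.2))
  switch(species,
    PC2C6 = rbind(c(0, 0, 0), c(0, 0, -2.5), chain(1), chain(-1)),
    LYSO = rbind(c(0, 0, 0), c(0, 0, -2.5), chain(1)),
    FA = rbind(c(1.1, 0, 0), c(-1.1, 0, 0), c(0, 1.0, -1.6), c(0, -1.0, -3.2),
               c(0, 1.0, -4.8), c(0, -1.0, -6.4), c(0, 0, -8.0)))
}

# atom metadata rows (tagging-table order) for one molecule of a species
species_atoms <- function(species, tagging) {
  rows <- tagging[tagging$species == species, ]
  if (species == "WATER") rows <- rows[rows$role == "WATER_O", , drop = FALSE]
  rows
}

# micelle-embedded coordinates for one molecule; returns a matrix in the same
# atom order as species_atoms()
micelle_member_coords <- function(species, core, outer) {
  d <- runif_sphere(1)[1, ]
  rc <- ray_radius(d, core)
  ro <- ray_radius(d, outer)
  build_chain <- function(dj, f, phase = 0, r_min = 1.5) {
    rcj <- ray_radius(dj, core)
    perp1 <- orthogonal_unit(dj)
    perp1 <- rotate_about(perp1, dj, stats::runif(1, 0, 2 * pi))
    perp2 <- pracma::cross(dj, perp1)
    # spread terminals that would fall below the steric floor over a radial
    # band, so they never jam onto a single inner shell
    r_term <- f * rcj
    if (r_term < r_min) r_term <- stats::runif(1, r_min, r_min + 3)
    r_term <- min(r_term, rcj - 1.3)
    # the ester/carbonyl anchor floats +-1.2 A around the core boundary:
    # strict pinning would jam the boundary layer sterically
    r_surf <- rcj + stats::runif(1, -1.2, 1.2)
    ester <- r_surf * dj - 0.6 * perp1
    carbonyl <- (r_surf + 1.3) * dj + 1.2 * perp1
    # carbon beads descend radially from the core boundary to the terminal
    # radius on a pentagonal helix whose lateral radius keeps every bead
    # pair >= 1.8 Angstrom apart even when the radial span is compressed
    radii <- seq(r_surf - 1.2, r_term, length.out = 5)
    s <- abs(radii[1] - radii[2])
    bond <- 1.9
    rad <- max(sqrt(max(0, bond^2 - s^2)) / (2 * sin(pi / 5)), 1.0)
    ang <- (0:4) * 2 * pi / 5 + phase
    beads <- outer(radii, dj) +
      rad * (outer(cos(ang), perp1) + outer(sin(ang), perp2))
    rbind(ester, carbonyl, beads)
  }
  f_core <- function() stats::runif(1, 0.05, 0.45)
  # N at the outer surface (small radial float), P about two Angstrom below
  # it, clear of the chain carbonyls near the core boundary
  p_depth <- min(2, outer[1] / 10 + 1)
  ro <- ro + stats::runif(1, -1, 1)
  switch(species,
    PC2C6 = {
      # the two acyl chains splay +/-16 degrees about a common axis so they
      # can never coincide; antiphase pentagon helices keep deep beads apart
      ax <- rotate_about(orthogonal_unit(d), d, stats::runif(1, 0, 2 * pi))
      d1 <- rotate_about(d, ax, 20 * pi / 180)
      d2 <- rotate_about(d, ax, -20 * pi / 180)
      head <- rbind(ro * d, (ro - p_depth) * d)
      rbind(head, build_chain(d1 / sqrt(sum(d1^2)), f_core(), r_min = 3.0),
            build_chain(d2 / sqrt(sum(d2^2)), f_core(), phase = pi / 5, r_min = 3.0))
    },
    LYSO = {
      head <- rbind(ro * d, (ro - p_depth) * d)
      rbind(head, build_chain(d, stats::runif(1, 0.6, 0.9)))
    },
    FA = {
      perp <- orthogonal_unit(d)
      rcd <- rc + 2.2
      head <- rbind(rcd * d + 1.1 * perp, rcd * d - 1.1 * perp)
      ch <- build_chain(d, f_core())
      rbind(head, ch[-(1:2), , drop = FALSE])
    })
}

min_self_dist <- function(x) {
  if (nrow(x) < 2) return(Inf)
  min(stats::dist(x))
}

# minimum distance from each row of `pts` to any row of `ref` (minimum image)
min_dist_to <- function(pts, ref, box, chunk = 2000L) {
  if (is.null(ref) || nrow(ref) == 0) return(rep(Inf, nrow(pts)))
  out <- numeric(nrow(pts))
  idx <- split(seq_len(nrow(pts)), ceiling(seq_len(nrow(pts)) / chunk))
  for (ii in idx) {
    out[ii] <- apply(pair_dist_pbc(pts[ii, , drop = FALSE], ref, box), 1, min)
  }
  out
}

#' Build a labeled micelle-in-water configuration with known ground truth
#'
#' Places the planted micelle at the box centre, free monomers at least 15
#' Angstrom from the micelle surface and from each other, and water oxygens
#' at the requested number density excluding a 2.6 Angstrom shell around
#' every solute heavy atom. The planted micelle is verified to form a single
#' connected tail-contact network (4.0 Angstrom, i.e. tighter than the 4.5
#' Angstrom default clustering cutoff), so the planted aggregation number is
#' recoverable by [cluster_molecules()]; the whole construction is
#' re-sampled if the check fails. Fully deterministic given `spec$seed`.
#'
#' @param spec An [micelle_spec()].
#' @return List with elements `configuration` ([mk_configuration()]) and
#'   `ground_truth` (class `mk_ground_truth`: planted member molecule ids,
#'   aggregation number, per-species counts, core semi-axes, monomer ids).
#' @export
build_micelle_configuration <- function(spec) {
  with_rng(mk_seed(spec$seed, "build_micelle"), build_micelle_impl(spec))
}

build_micelle_impl <- function(spec, max_rebuilds = 50L) {
  tagging <- default_tagging()
  core <- spec$core_semi_axes
  outer_axes <- core + spec$headgroup_shell
  centre <- rep(spec$box / 2, 3)
  box3 <- rep(spec$box, 3)
  member_species <- rep(names(spec$composition), spec$composition)
  monomer_species <- rep(names(spec$n_monomers), spec$n_monomers)

  for (rebuild in seq_len(max_rebuilds)) {
    coords_list <- list(); atom_rows <- list(); placed <- NULL
    mol_id <- 0L; ok <- TRUE
    link_idx <- list()   # member tail/terminal atom rows for connectivity check
    # --- micelle members ---
    # The planted core sits at liquid-like bead density, where whole-molecule
    # rejection sampling against the full 1.8 A steric floor stalls. Members
    # are therefore placed against a looser 1.2 A floor and the assembly is
    # then relaxed by soft-sphere push-off until the 1.8 A floor holds.
    for (sp in member_species) {
      rows <- species_atoms(sp, tagging)
      success <- FALSE
      for (attempt in seq_len(10000L)) {
        xyz <- micelle_member_coords(sp, core, outer_axes)
        xyz <- sweep(xyz, 2, centre, "+")
        if (min_self_dist(xyz) < 1.8) next
        if (min(min_dist_to(xyz, placed, box3)) < 1.2) next
        success <- TRUE
        break
      }
      if (!success) { ok <- FALSE; break }
      mol_id <- mol_id + 1L
      coords_list[[mol_id]] <- xyz
      rows$molecule_id <- mol_id
      atom_rows[[mol_id]] <- rows
      placed <- rbind(placed, xyz)
    }
    if (!ok) next
    n_members <- mol_id
    if (n_members > 0) {
      placed <- relax_overlaps(placed, box3, floor_dist = 1.8)
      if (is.null(placed)) next
      n_per_mol <- vapply(coords_list, nrow, integer(1))
      stops <- cumsum(n_per_mol)
      starts <- stops - n_per_mol + 1L
      for (m in seq_len(n_members)) {
        coords_list[[m]] <- placed[starts[m]:stops[m], , drop = FALSE]
        rr <- atom_rows[[m]]
        link_idx[[m]] <- coords_list[[m]][rr$role %in% c("TAIL_C", "TERMINAL_C"), ,
                                          drop = FALSE]
      }
    }
    # connectivity of the planted tail network with margin below the 4.5
    # Angstrom default clustering cutoff
    if (n_members >= 2) {
      link_mol <- rep(seq_len(n_members), vapply(link_idx, nrow, integer(1)))
      link_xyz <- do.call(rbind, link_idx)
      dm <- pair_dist_pbc(link_xyz, link_xyz, box3)
      contact <- dm <= 4.0
      adj <- rowsum(contact + 0, link_mol)
      adj <- t(rowsum(t(adj), link_mol)) > 0
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
      if (igraph::count_components(g) != 1L) next
    }
    # --- monomers ---
    mono_ok <- TRUE
    mono_coms <- NULL
    for (sp in monomer_species) {
      rows <- species_atoms(sp, tagging)
      tpl <- monomer_template(sp)
      success <- FALSE
      for (attempt in seq_len(10000L)) {
        u <- runif_sphere(1)[1, ]
        ang <- stats::runif(1, 0, 2 * pi)
        rot <- rotate_matrix(u, ang)
        pos <- stats::runif(3, 0, spec$box)
        xyz <- sweep(tpl %*% t(rot), 2, pos, "+")
        # keep every atom >= 15 Angstrom outside the outer micelle surface:
        # reject if any atom lies inside the outer ellipsoid grown by 15 A
        if (sum(spec$composition) > 0) {
          rel <- min_image(sweep(xyz, 2, centre, "-"), box3)
          sc <- sweep(rel, 2, outer_axes + 15, "/")
          if (any(rowSums(sc^2) < 1)) next
        }
        com <- centre_of_mass(xyz, rows$mass)
        if (!is.null(mono_coms) &&
            min(pair_dist_pbc(matrix(com, 1), mono_coms, box3)) < 15) next
        if (min(min_dist_to(xyz, placed, box3)) < 6) next
        success <- TRUE
        break
      }
      if (!success) { mono_ok <- FALSE; break }
      mol_id <- mol_id + 1L
      coords_list[[mol_id]] <- xyz
      rows$molecule_id <- mol_id
      atom_rows[[mol_id]] <- rows
      mono_coms <- rbind(mono_coms, com)
      placed <- rbind(placed, xyz)
    }
    if (!mono_ok)
      mk_stop("could not place all monomers after 10^4 attempts; enlarge the box",
              "mk_placement_error")
    # --- water ---
    wat <- place_waters(spec, placed, box3)
    solute_atoms <- do.call(rbind, atom_rows)
    atoms <- assemble_atoms(solute_atoms, nrow(wat), mol_id, spec, tagging)
    coords <- rbind(do.call(rbind, coords_list), water_coords(wat, spec))
    cfg <- mk_configuration(coords, box3, atoms, spec$time_per_frame)
    gt <- structure(list(
      micelle_member_ids = if (n_members) seq_len(n_members) else integer(0),
      aggregation_number = n_members,
      per_species_in_micelle = spec$composition,
      core_semi_axes = core,
      monomer_ids = if (length(monomer_species))
        seq(n_members + 1L, n_members + length(monomer_species)) else integer(0)),
      class = "mk_ground_truth")
    return(list(configuration = cfg, ground_truth = gt))
  }
  mk_stop("could not build a connected planted micelle; check spec geometry",
          "mk_placement_error")
}

# Iteratively push apart atom pairs closer than floor_dist (minimum image):
# each clashing pair moves symmetrically along its separation vector until
# the floor holds everywhere. Returns NULL if it fails to converge.
relax_overlaps <- function(xyz, box3, floor_dist = 1.8, max_iter = 2000L) {
  n <- nrow(xyz)
  if (n < 2) return(xyz)
  for (it in seq_len(max_iter)) {
    dm <- pair_dist_pbc(xyz, xyz, box3)
    dm[upper.tri(dm, diag = TRUE)] <- Inf
    clash <- which(dm < floor_dist, arr.ind = TRUE)
    if (!nrow(clash)) return(xyz)
    for (k in seq_len(nrow(clash))) {
      i <- clash[k, 1]; j <- clash[k, 2]
      d <- min_image(matrix(xyz[i, ] - xyz[j, ], 1), box3)[1, ]
      dist <- sqrt(sum(d^2))
      u <- if (dist < 1e-9) runif_sphere(1)[1, ] else d / dist
      push <- (floor_dist - dist) / 2 + 0.02
      xyz[i, ] <- xyz[i, ] + push * u
      xyz[j, ] <- xyz[j, ] - push * u
    }
  }
  NULL
}

rotate_matrix <- function(axis, theta) {
  k <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# uniform water oxygens at spec$water_density excluding a 2.6 A shell around
# solute heavy atoms; count is round(density * box^3) minus excluded points
place_waters <- function(spec, solute_xyz, box3) {
  if (spec$water_density <= 0) return(matrix(numeric(0), ncol = 3))
  n_target <- round(spec$water_density * spec$box^3)
  pts <- matrix(stats::runif(3 * n_target, 0, spec$box), ncol = 3)
  keep <- min_dist_to(pts, solute_xyz, box3) >= 2.6
  pts[keep, , drop = FALSE]
}

water_coords <- function(wat_o, spec) {
  if (!nrow(wat_o)) return(matrix(numeric(0), ncol = 3))
  if (!spec$include_water_h) return(wat_o)
  h1 <- sweep(wat_o, 2, c(0.76, 0.59, 0), "+")
  h2 <- sweep(wat_o, 2, c(-0.76, 0.59, 0), "+")
  m <- matrix(0, 3 * nrow(wat_o), 3)
  m[seq(1, nrow(m), 3), ] <- wat_o
  m[seq(2, nrow(m), 3), ] <- h1
  m[seq(3, nrow(m), 3), ] <- h2
  m
}

assemble_atoms <- function(solute_atoms, n_water, last_solute_mol, spec, tagging) {
  solute <- solute_atoms[, c("resname", "atom", "species", "role", "element",
                             "mass", "molecule_id")]
  names(solute)[2] <- "name"
  if (n_water > 0) {
    wrows <- tagging[tagging$species == "WATER", ]
    if (!spec$include_water_h) wrows <- wrows[wrows$role == "WATER_O", ]
    per <- nrow(wrows)
    wat <- wrows[rep(seq_len(per), n_water), ]
    wat$molecule_id <- last_solute_mol + rep(seq_len(n_water), each = per)
    names(wat)[names(wat) == "atom"] <- "name"
    wat <- wat[, names(solute)]
    solute <- rbind(solute, wat)
  }
  data.frame(name = solute$name, resname = solute$resname,
             element = solute$element, molecule_id = solute$molecule_id,
             species = solute$species, role = solute$role, mass = solute$mass,
             stringsAsFactors = FALSE)
}

#' Build a synthetic multi-frame trajectory
#'
#' Frame 1 comes from [build_micelle_configuration()]; each later frame adds
#' independent Gaussian jitter (`spec$jitter_sigma`) to the solute atoms and
#' re-draws the water positions, so the planted membership (the ground
#' truth) holds for every frame.
#'
#' @param spec An [micelle_spec()] with `n_frames >= 1`.
#' @return List with `configuration` (n_frames frames) and `ground_truth`.
#' @export
build_trajectory <- function(spec) {
  base <- build_micelle_configuration(spec)
  if (spec$n_frames == 1L) return(base)
  cfg <- base$configuration
  is_solute <- cfg$atoms$species != "WATER"
  n_sol <- sum(is_solute)
  solute0 <- cfg$frames[[1]][is_solute, , drop = FALSE]
  box3 <- cfg$box[1, ]
  frames <- vector("list", spec$n_frames)
  frames[[1]] <- cfg$frames[[1]]
  n_wat_atoms <- sum(!is_solute)
  n_wat_mol <- length(unique(cfg$atoms$molecule_id[!is_solute]))
  for (fi in 2:spec$n_frames) {
    fr <- with_rng(mk_seed(spec$seed, paste0("frame", fi)), {
      jit <- matrix(stats::rnorm(3 * n_sol, sd = spec$jitter_sigma), ncol = 3)
      sol <- solute0 + jit
      wat <- redraw_waters(n_wat_mol, sol, box3, spec)
      rbind(sol, water_coords(wat, spec))
    })
    frames[[fi]] <- fr
  }
  base$configuration <- mk_configuration(frames, box3, cfg$atoms, spec$time_per_frame)
  base
}

# re-draw exactly n water oxygens outside the solute exclusion shell
redraw_waters <- function(n, solute_xyz, box3, spec) {
  if (n == 0) return(matrix(numeric(0), ncol = 3))
  out <- matrix(numeric(0), ncol = 3)
  guard <- 0L
  while (nrow(out) < n && guard < 100L) {
    guard <- guard + 1L
    pts <- matrix(stats::runif(3 * ceiling(1.3 * (n - nrow(out))), 0, box3[1]), ncol = 3)
    keep <- min_dist_to(pts, solute_xyz, box3) >= 2.6
    out <- rbind(out, pts[keep, , drop = FALSE])
  }
  if (nrow(out) < n)
    mk_stop("could not re-draw water positions", "mk_placement_error")
  out[seq_len(n), , drop = FALSE]
}

#' Synthesize a noisy SANS curve from the scattering model
#'
#' Evaluates [model_intensity()] on the q grid and applies multiplicative
#' Gaussian noise: `I = model * (1 + eps)` with `eps ~ N(0, noise_frac^2)`
#' i.i.d., and `sigma = noise_frac * model`. `noise_frac = 0` returns the
#' exact model curve (with zero uncertainties).
#'
#' @param params A [triaxial_params()] object.
#' @param qgrid Momentum-transfer grid, 1/Angstrom.
#' @param noise_frac Relative noise level (>= 0).
#' @param seed Integer seed for the noise realisation.
#' @param label Curve label.
#' @return A [sans_curve()].
#' @export
synthesize_sans_curve <- function(params, qgrid, noise_frac = 0, seed = 1,
                                  label = "synthetic") {
  if (noise_frac < 0) mk_stop("noise_frac must be >= 0", "mk_spec_error")
  model <- model_intensity(params, qgrid)
  eps <- if (noise_frac > 0)
    with_rng(mk_seed(seed, "sans_noise"), stats::rnorm(length(qgrid), sd = noise_frac))
  else rep(0, length(qgrid))
  sans_curve(qgrid, model * (1 + eps), noise_frac * model, label = label)
}

#' @export
print.mk_ground_truth <- function(x, ...) {
  cat(sprintf("<mk_ground_truth> aggregation number %d (%s); %d monomer(s)\n",
              x$aggregation_number,
              paste(sprintf("%s=%d", names(x$per_species_in_micelle),
                            x$per_species_in_micelle), collapse = ", "),
              length(x$monomer_ids)))
  invisible(x)
}
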