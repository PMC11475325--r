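#' Unwrap a cluster of molecules across periodic boundaries
#'
#' Periodic wrapping corrupts second moments, so before any geometry is
#' computed the cluster is made whole: each molecule is first unwrapped
#' internally (atoms shifted to the minimum image of the molecule's first
#' atom), then molecules are attached one at a time by a minimum-image walk
#' from a seed molecule, each new molecule translated by the whole box
#' vectors that bring its centroid closest to the already-placed part.
#' Membership itself is image-independent; only coordinates change.
#'
#' @param cfg An [mk_configuration()].
#' @param molecule_ids Molecules forming the cluster.
#' @param frame Frame index.
#' @return List with `coords` (unwrapped coordinates, rows in atom order),
#'   `masses`, and `atom_index` (row indices into the atom table).
#' @export
unwrap_cluster <- function(cfg, molecule_ids, frame = 1) {
  a <- cfg$atoms
  box <- cfg$box[frame, ]
  sel <- which(a$molecule_id %in% molecule_ids)
  xyz <- cfg$frames[[frame]][sel, , drop = FALSE]
  mol <- a$molecule_id[sel]
  mols <- unique(mol)
  # make each molecule whole
  for (m in mols) {
    idx <- which(mol == m)
    ref <- xyz[idx[1], ]
    d <- min_image(sweep(xyz[idx, , drop = FALSE], 2, ref, "-"), box)
    xyz[idx, ] <- sweep(d, 2, ref, "+")
  }
  # walk molecules outward from the seed, shifting by whole box vectors
  cents <- do.call(rbind, lapply(mols, function(m)
    colMeans(xyz[mol == m, , drop = FALSE])))
  placed <- c(TRUE, rep(FALSE, length(mols) - 1))
  while (!all(placed)) {
    dp <- pair_dist_pbc(cents[!placed, , drop = FALSE],
                        cents[placed, , drop = FALSE], box)
    pick <- which(dp == min(dp), arr.ind = TRUE)[1, ]
    i <- which(!placed)[pick[1]]
    j <- which(placed)[pick[2]]
    delta <- cents[i, ] - cents[j, ]
    shift <- -box * round(delta / box)
    idx <- which(mol == mols[i])
    xyz[idx, ] <- sweep(xyz[idx, , drop = FALSE], 2, shift, "+")
    cents[i, ] <- cents[i, ] + shift
    placed[i] <- TRUE
  }
  list(coords = xyz, masses = a$mass[sel], atom_index = sel)
}

#' Mass-weighted radius of gyration
#'
#' `Rg = sqrt(sum(m_i |r_i - r_com|^2) / sum(m_i))` on (unwrapped)
#' coordinates.
#'
#' @param coords n x 3 coordinate matrix, Angstrom.
#' @param masses Atom masses (unit masses if omitted).
#' @return Rg in Angstrom; a single atom yields 0 with a warning.
#' @export
radius_of_gyration <- function(coords, masses = NULL) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (nrow(coords) < 2) {
    warning("radius of gyration of fewer than 2 atoms is 0")
    return(0)
  }
  if (is.null(masses)) masses <- rep(1, nrow(coords))
  com <- centre_of_mass(coords, masses)
  d2 <- rowSums(sweep(coords, 2, com, "-")^2)
  sqrt(sum(masses * d2) / sum(masses))
}

#' Principal moments of inertia and shape descriptors
#'
#' Diagonalises the mass-weighted inertia tensor about the centre of mass
#' and reports the sorted principal moments `I1 <= I2 <= I3`, the ratios
#' `I1/I2` and `I2/I3`, and the eccentricity `e = 1 - I1 / Imean` (0 for a
#' sphere, where all three moments are equal).
#'
#' @inheritParams radius_of_gyration
#' @return List with `moments`, `i1_i2`, `i2_i3`, `eccentricity`.
#' @export
inertia_descriptors <- function(coords, masses = NULL) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (nrow(coords) < 3)
    mk_stop("inertia descriptors need at least 3 atoms", "mk_degenerate_geometry")
  if (is.null(masses)) masses <- rep(1, nrow(coords))
  com <- centre_of_mass(coords, masses)
  r <- sweep(coords, 2, com, "-")
  # collinearity check on the gyration tensor
  gyr <- crossprod(sqrt(masses) * r) / sum(masses)
  ev <- sort(eigen(gyr, symmetric = TRUE, only.values = TRUE)$values)
  if (ev[2] <= 1e-10 * max(ev[3], .Machine$double.eps))
    mk_stop("collinear point set: inertia tensor is degenerate",
            "mk_degenerate_geometry")
  r2 <- rowSums(r^2)
  inert <- diag(sum(masses * r2), 3) - crossprod(r * sqrt(masses))
  moments <- sort(eigen(inert, symmetric = TRUE, only.values = TRUE)$values)
  list(moments = moments,
       i1_i2 = moments[1] / moments[2],
       i2_i3 = moments[2] / moments[3],
       eccentricity = eccentricity_from_inertia(moments[1], moments[2], moments[3]))
}

#' Eccentricity from principal moments of inertia
#'
#' `e = 1 - Imin / Imean` with `Imean = (I1 + I2 + I3) / 3`; zero for a
#' sphere, increasing with anisotropy.
#'
#' @param i1,i2,i3 Principal moments (any order).
#' @return Eccentricity in `[0, 1)`.
#' @export
eccentricity_from_inertia <- function(i1, i2, i3) {
  m <- pmin(i1, pmin(i2, i3))
  1 - m / ((i1 + i2 + i3) / 3)
}

#' Eccentricity from printed moment ratios
#'
#' Reconstructs moments from the ratio pair by setting `I3 = 1`,
#' `I2 = i2_i3`, `I1 = i1_i2 * i2_i3`, then applies
#' [eccentricity_from_inertia()]. Useful for checking published tables that
#' print only the two ratios.
#'
#' @param i1_i2 Ratio of smallest to middle principal moment, in (0, 1].
#' @param i2_i3 Ratio of middle to largest principal moment, in (0, 1].
#' @return Eccentricity.
#' @export
eccentricity_from_ratios <- function(i1_i2, i2_i3) {
  eccentricity_from_inertia(i1_i2 * i2_i3, i2_i3, 1)
}

#' Classify micelle shape from moment-of-inertia ratios
#'
#' With tolerance `tol` on the ratios: `SPHERE` if both ratios are within
#' `tol` of 1; `PROLATE` if only `i2_i3` is (one long axis, two short);
#' `OBLATE` if only `i1_i2` is (one short axis, two long); otherwise
#' `TRIAXIAL`.
#'
#' @inheritParams eccentricity_from_ratios
#' @param tol Fractional tolerance on the ratios (default 0.05).
#' @return One of `"SPHERE"`, `"PROLATE"`, `"OBLATE"`, `"TRIAXIAL"`.
#' @export
classify_shape <- function(i1_i2, i2_i3, tol = 0.05) {
  if (i1_i2 <= 0 || i1_i2 > 1 || i2_i3 <= 0 || i2_i3 > 1)
    mk_stop("moment ratios must lie in (0, 1]", "mk_parameter_error")
  hi1 <- i1_i2 >= 1 - tol
  hi2 <- i2_i3 >= 1 - tol
  if (hi1 && hi2) "SPHERE"
  else if (hi2) "PROLATE"
  else if (hi1) "OBLATE"
  else "TRIAXIAL"
}

#' Maximum extent of a point set
#'
#' Largest pairwise Euclidean distance between atoms (coordinates must be
#' unwrapped).
#'
#' @param coords n x 3 coordinate matrix.
#' @return Maximum distance, Angstrom.
#' @export
max_extent <- function(coords) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (nrow(coords) < 2) mk_stop("max_extent needs at least 2 atoms", "mk_parameter_error")
  max(stats::dist(coords))
}

#' Radial distribution of a species about the micelle centre of mass
#'
#' For every molecule of `species` resident in the largest aggregate of each
#' frame, takes the distance of the molecule's farthest atom from the
#' micelle centre of mass (on unwrapped coordinates), histograms those
#' distances over all frames, and normalises the histogram so its maximum
#' is exactly 1.
#'
#' @param cfg An [mk_configuration()].
#' @param assignments List of per-frame `mk_clusters` (e.g. the
#'   `assignments` attribute of [aggregation_timeseries()]).
#' @param species Species to profile.
#' @param bin_width Histogram bin width, Angstrom.
#' @return Data frame (class `mk_radial_profile`) with `r` (bin centres) and
#'   `density` (max-normalised).
#' @export
com_distance_profile <- function(cfg, assignments, species, bin_width = 1) {
  a <- cfg$atoms
  dists <- numeric(0)
  for (fi in seq_along(assignments)) {
    cl <- assignments[[fi]]
    members <- largest_cluster_members(cl)
    uw <- unwrap_cluster(cfg, members, frame = fi)
    com <- centre_of_mass(uw$coords, uw$masses)
    mol <- a$molecule_id[uw$atom_index]
    sp <- a$species[uw$atom_index]
    for (m in members[a$species[match(members, a$molecule_id)] == species]) {
      idx <- which(mol == m)
      dists <- c(dists, max(sqrt(rowSums(sweep(uw$coords[idx, , drop = FALSE],
                                               2, com, "-")^2))))
    }
  }
  if (!length(dists)) {
    warning(sprintf("species %s absent from the micelle; empty profile", species))
    out <- data.frame(r = numeric(0), density = numeric(0))
  } else {
    breaks <- seq(0, (floor(max(dists) / bin_width) + 1) * bin_width, by = bin_width)
    h <- graphics::hist(dists, breaks = breaks, plot = FALSE)
    out <- data.frame(r = h$mids, density = h$counts / max(h$counts))
  }
  attr(out, "species") <- species
  class(out) <- c("mk_radial_profile", "data.frame")
  out
}

#' Per-frame micelle shape report
#'
#' Convenience wrapper: identifies the largest aggregate per frame, unwraps
#' it, and reports Rg, maximum extent, moment ratios, eccentricity and the
#' shape class, plus window means and standard deviations.
#'
#' @param cfg An [mk_configuration()].
#' @param assignments Per-frame `mk_clusters` list.
#' @param window Frames to summarise (default: last half).
#' @param tol Shape-classification tolerance.
#' @return List with `per_frame` (data frame) and `summary` (one row).
#' @export
shape_report <- function(cfg, assignments, window = NULL, tol = 0.05) {
  nf <- length(assignments)
  window <- window %||% seq(max(1L, floor(nf / 2) + 1L), nf)
  rows <- lapply(seq_len(nf), function(fi) {
    members <- largest_cluster_members(assignments[[fi]])
    uw <- unwrap_cluster(cfg, members, frame = fi)
    ine <- inertia_descriptors(uw$coords, uw$masses)
    data.frame(frame = fi,
               rg = radius_of_gyration(uw$coords, uw$masses),
               max_length = max_extent(uw$coords),
               i1_i2 = ine$i1_i2, i2_i3 = ine$i2_i3,
               eccentricity = ine$eccentricity)
  })
  pf <- do.call(rbind, rows)
  w <- pf[pf$frame %in% window, ]
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  summary <- data.frame(
    rg = mean(w$rg), rg_sd = sd0(w$rg),
    max_length = mean(w$max_length), max_length_sd = sd0(w$max_length),
    i1_i2 = mean(w$i1_i2), i2_i3 = mean(w$i2_i3),
    eccentricity = mean(w$eccentricity),
    shape_class = classify_shape(mean(w$i1_i2), mean(w$i2_i3), tol = tol))
  list(per_frame = pf, summary = summary)
}
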