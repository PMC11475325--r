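#' Species and role vocabularies
#'
#' Molecular species handled by the package: the parent lipid
#' dihexanoylphosphatidylcholine (`PC2C6`), its digestion products
#' 1-hexanoyl-lysophosphocholine (`LYSO`) and hexanoic acid (`FA`), and
#' `WATER`. Atom roles identify the chemically distinct sites the analytics
#' consume: the choline nitrogen, phosphate phosphorus, ester and carbonyl
#' oxygens, tail and terminal carbons, and water oxygen/hydrogen.
#'
#' @format Character vectors.
#' @export
mk_species <- c("PC2C6", "LYSO", "FA", "WATER")

#' @rdname mk_species
#' @export
mk_roles <- c("CHOLINE_N", "PHOSPHATE_P", "ESTER_O", "CARBONYL_O", "TAIL_C",
              "TERMINAL_C", "HEAD_OTHER", "WATER_O", "WATER_H", "OTHER")

#' Build a labeled molecular configuration
#'
#' The container all trajectory analytics operate on: one or more frames of
#' Cartesian coordinates in Angstrom inside an orthorhombic periodic box,
#' with a constant topology of species/role-tagged atoms grouped into
#' molecules.
#'
#' @param frames A single n x 3 coordinate matrix or a list of them (one per
#'   frame), in Angstrom.
#' @param box Length-3 vector of orthorhombic box edge lengths (Angstrom), or
#'   an n_frames x 3 matrix.
#' @param atoms Data frame with one row per atom and columns `name`,
#'   `resname`, `element`, `molecule_id`, `species`, `role`, `mass`.
#' @param time_per_frame Time spacing between frames in ns (`NA` if unknown).
#' @param validate Check basic invariants (finite coordinates, positive box,
#'   constant atom count).
#' @return An object of class `mk_config`.
#' @export
mk_configuration <- function(frames, box, atoms, time_per_frame = NA_real_,
                             validate = TRUE) {
  if (is.matrix(frames)) frames <- list(frames)
  frames <- lapply(frames, function(f) {
    f <- matrix(as.numeric(f), ncol = 3)
    dimnames(f) <- NULL
    f
  })
  if (is.null(dim(box))) box <- matrix(box, nrow = length(frames), ncol = 3, byrow = TRUE)
  box <- matrix(as.numeric(box), ncol = 3)
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  needed <- c("name", "resname", "element", "molecule_id", "species", "role", "mass")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols))
    mk_stop(paste("atoms table lacks columns:", paste(missing_cols, collapse = ", ")),
            "mk_type_error")
  if (validate) {
    if (nrow(box) != length(frames))
      mk_stop("box must have one row per frame", "mk_type_error")
    if (any(box <= 0)) mk_stop("box edges must be positive", "mk_type_error")
    n <- vapply(frames, nrow, integer(1))
    if (any(n != nrow(atoms)))
      mk_stop("atom count must be constant across frames and match the atoms table",
              "mk_type_error")
    if (!all(vapply(frames, function(f) all(is.finite(f)), logical(1))))
      mk_stop("coordinates must be finite", "mk_type_error")
    bad_sp <- setdiff(unique(atoms$species), mk_species)
    if (length(bad_sp))
      mk_stop(paste("unknown species:", paste(bad_sp, collapse = ", ")), "mk_type_error")
    bad_role <- setdiff(unique(atoms$role), mk_roles)
    if (length(bad_role))
      mk_stop(paste("unknown roles:", paste(bad_role, collapse = ", ")), "mk_type_error")
  }
  structure(list(frames = frames, box = box, atoms = atoms,
                 time_per_frame = as.numeric(time_per_frame)),
            class = "mk_config")
}

#' Check species/role topology invariants of a configuration
#'
#' Verifies that every water molecule has exactly one water oxygen, and that
#' every non-water molecule carries at least one tail carbon and the right
#' number of terminal carbons (two for the doubly chained PC2C6, one for
#' LYSO and FA).
#'
#' @param cfg An [mk_configuration()] object.
#' @return Invisibly `TRUE`; signals a classed error on violation.
#' @export
check_topology <- function(cfg) {
  a <- cfg$atoms
  sp <- split(a, a$molecule_id)
  for (m in sp) {
    species <- m$species[1]
    if (any(m$species != species))
      mk_stop(sprintf("molecule %s mixes species", m$molecule_id[1]), "mk_topology_error")
    if (species == "WATER") {
      if (sum(m$role == "WATER_O") != 1L)
        mk_stop(sprintf("water molecule %s must contain exactly one WATER_O",
                        m$molecule_id[1]), "mk_topology_error")
    } else {
      if (!any(m$role == "TAIL_C"))
        mk_stop(sprintf("molecule %s (%s) has no TAIL_C", m$molecule_id[1], species),
                "mk_topology_error")
      nt <- sum(m$role == "TERMINAL_C")
      want <- if (species == "PC2C6") 2L else 1L
      if (nt != want)
        mk_stop(sprintf("molecule %s (%s) has %d TERMINAL_C, expected %d",
                        m$molecule_id[1], species, nt, want), "mk_topology_error")
    }
  }
  invisible(TRUE)
}

#' @export
print.mk_config <- function(x, ...) {
  sp <- table(x$atoms$species[!duplicated(x$atoms$molecule_id)])
  cat(sprintf("<mk_config> %d frame(s), %d atoms, %d molecules\n",
              length(x$frames), nrow(x$atoms), length(unique(x$atoms$molecule_id))))
  cat("  box (frame 1):", paste(sprintf("%.2f", x$box[1, ]), collapse = " x "), "Angstrom\n")
  cat("  molecules:", paste(sprintf("%s=%d", names(sp), as.integer(sp)), collapse = ", "), "\n")
  invisible(x)
}

n_frames <- function(cfg) length(cfg$frames)

frame_coords <- function(cfg, i = 1) cfg$frames[[i]]

solute_molecule_ids <- function(cfg) {
  unique(cfg$atoms$molecule_id[cfg$atoms$species != "WATER"])
}

#' Construct a reduced SANS curve
#'
#' A reduced one-dimensional small-angle scattering curve: momentum transfer
#' `q` (1/Angstrom), absolute intensity (1/cm) and its uncertainty.
#'
#' @param q Momentum transfer values, 1/Angstrom; must be positive and are
#'   sorted (with a warning) if not already increasing.
#' @param intensity Scattering intensity, 1/cm.
#' @param sigma Intensity uncertainties, 1/cm (non-negative).
#' @param label Free-text label carried through reports.
#' @return An object of class `sans_curve`.
#' @export
sans_curve <- function(q, intensity, sigma, label = "") {
  q <- as.numeric(q); intensity <- as.numeric(intensity); sigma <- as.numeric(sigma)
  if (length(q) != length(intensity) || length(q) != length(sigma))
    mk_stop("q, intensity and sigma must have equal length", "mk_type_error")
  keep <- q > 0
  if (any(!keep)) {
    warning(sprintf("dropping %d point(s) with q <= 0", sum(!keep)))
    q <- q[keep]; intensity <- intensity[keep]; sigma <- sigma[keep]
  }
  if (length(q) < 5) mk_stop("a SANS curve needs at least 5 points", "mk_too_few_points")
  if (is.unsorted(q, strictly = TRUE)) {
    warning("q not strictly increasing; sorting")
    o <- order(q)
    q <- q[o]; intensity <- intensity[o]; sigma <- sigma[o]
    if (anyDuplicated(q)) mk_stop("duplicate q values", "mk_type_error")
  }
  if (any(sigma < 0)) mk_stop("sigma must be non-negative", "mk_type_error")
  structure(list(q = q, intensity = intensity, sigma = sigma, label = label),
            class = "sans_curve")
}

#' @export
print.sans_curve <- function(x, ...) {
  cat(sprintf("<sans_curve> %s%d points, q in [%.4g, %.4g] 1/Angstrom\n",
              if (nzchar(x$label)) paste0(x$label, ": ") else "",
              length(x$q), min(x$q), max(x$q)))
  invisible(x)
}
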