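#' Radial distribution function between two atom selections
#'
#' Standard pair-correlation estimator on minimum-image distances with
#' shell-volume normalisation `4 pi r^2 dr` and partner density
#' `rho_b = N_b / V` averaged over frames. The running coordination number
#' `n_of_r` (the integral of `4 pi rho_b r^2 g dr`, evaluated bin-by-bin so
#' it equals the average neighbour count at every bin edge) is returned at
#' the bin edges.
#'
#' @param cfg An [mk_configuration()].
#' @param sel_a,sel_b Integer or logical atom selections (rows of
#'   `cfg$atoms`). Identical selections are treated as a self-RDF with self
#'   pairs excluded.
#' @param dr Bin width, Angstrom.
#' @param r_max Histogram range; must not exceed half the smallest box edge
#'   (default `0.45 *` smallest edge).
#' @param frames Frames to average over (default all).
#' @return Object of class `mk_rdf`: list with `r` (bin centres), `g`,
#'   `rho_b`, `r_edges`, `n_of_r` (at `r_edges`).
#' @export
rdf <- function(cfg, sel_a, sel_b, dr = 0.05, r_max = NULL, frames = NULL) {
  sel_a <- normalize_selection(sel_a, nrow(cfg$atoms))
  sel_b <- normalize_selection(sel_b, nrow(cfg$atoms))
  if (!length(sel_a) || !length(sel_b))
    mk_stop("empty atom selection", "mk_selection_error")
  frames <- frames %||% seq_len(n_frames(cfg))
  min_edge <- min(cfg$box[frames, ])
  r_max <- r_max %||% (0.45 * min_edge)
  if (r_max > min_edge / 2 + 1e-9)
    mk_stop("r_max exceeds half the smallest box edge", "mk_box_error")
  self_mode <- identical(sort(sel_a), sort(sel_b))
  edges <- seq(0, r_max, by = dr)
  if (abs(edges[length(edges)] - r_max) > 1e-12) edges <- c(edges, r_max)
  counts <- numeric(length(edges) - 1L)
  vol <- 0
  for (fi in frames) {
    box <- cfg$box[fi, ]
    vol <- vol + prod(box)
    d <- pair_dist_pbc(cfg$frames[[fi]][sel_a, , drop = FALSE],
                       cfg$frames[[fi]][sel_b, , drop = FALSE], box)
    if (self_mode) diag(d) <- Inf
    d <- d[d <= r_max]
    counts <- counts + tabulate(findInterval(d, edges, rightmost.closed = TRUE,
                                             left.open = TRUE),
                                nbins = length(edges) - 1L)
  }
  nfr <- length(frames)
  vol <- vol / nfr
  rho_b <- length(sel_b) / vol
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  widths <- diff(edges)
  shell <- 4 * pi * centers^2 * widths
  g <- counts / (nfr * length(sel_a) * rho_b * shell)
  n_of_r <- c(0, cumsum(counts) / (nfr * length(sel_a)))
  structure(list(r = centers, g = g, rho_b = rho_b,
                 r_edges = edges, n_of_r = n_of_r),
            class = "mk_rdf")
}

normalize_selection <- function(sel, n) {
  if (is.logical(sel)) {
    if (length(sel) != n) mk_stop("logical selection has wrong length", "mk_selection_error")
    which(sel)
  } else {
    sel <- as.integer(sel)
    if (any(sel < 1 | sel > n)) mk_stop("selection index out of range", "mk_selection_error")
    sel
  }
}

#' @export
print.mk_rdf <- function(x, ...) {
  cat(sprintf("<mk_rdf> %d bins, r in [0, %.2f] Angstrom, rho_b = %.4g / Angstrom^3\n",
              length(x$r), max(x$r_edges), x$rho_b))
  invisible(x)
}

#' First minimum of a radial distribution function
#'
#' Location of the first local minimum of the 3-bin moving-average smoothed
#' g(r) after the first (dominant) peak, searched inside `window` (default
#' 2--6 Angstrom, bracketing the first hydration shell). Falls back to the
#' window end with a warning when no interior minimum exists.
#'
#' @param r An `mk_rdf` object.
#' @param window Length-2 search window, Angstrom.
#' @return Radius of the first minimum, Angstrom.
#' @export
first_minimum <- function(r, window = c(2, 6)) {
  g <- stats::filter(r$g, rep(1 / 3, 3), sides = 2)
  g[is.na(g)] <- r$g[is.na(g)]
  g <- as.numeric(g)
  inside <- which(r$r >= window[1] & r$r <= window[2])
  if (!length(inside)) mk_stop("window outside the rdf range", "mk_parameter_error")
  # the first hydration peak: the dominant maximum at or before the window
  # end (immune to sub-noise ripples in the flat region before the peak)
  pk <- which.max(g[seq_len(max(inside))])
  if (pk < max(inside)) {
    after <- inside[inside > pk]
    mins <- after[after > 1 & after < length(g)]
    mins <- mins[g[mins] <= g[mins - 1] & g[mins] <= g[mins + 1]]
    if (length(mins)) return(r$r[mins[1]])
  }
  warning("no interior minimum found; falling back to window end")
  window[2]
}

#' Running coordination number at a cutoff
#'
#' Evaluates the running neighbour count `n_of_r` of an RDF at `r_cut`,
#' interpolating linearly between bin edges.
#'
#' @param r An `mk_rdf` object.
#' @param r_cut Cutoff radius, Angstrom (within the RDF range).
#' @return Average neighbour count within `r_cut`.
#' @export
coordination_number <- function(r, r_cut) {
  if (r_cut < 0 || r_cut > max(r$r_edges) + 1e-9)
    mk_stop("r_cut outside the rdf range", "mk_parameter_error")
  stats::approx(r$r_edges, r$n_of_r, xout = r_cut, rule = 2)$y
}

#' Default per-role water-contact cutoffs
#'
#' 3.5 Angstrom for nitrogen/phosphorus/oxygen sites (the first hydration
#' shell of polar atoms) and 5.0 Angstrom for carbons, whose first
#' water-oxygen RDF minimum lies farther out. Override per role as needed.
#'
#' @return Named numeric vector of cutoffs, Angstrom.
#' @export
default_contact_cutoffs <- function() {
  c(CHOLINE_N = 3.5, PHOSPHATE_P = 3.5, ESTER_O = 3.5, CARBONYL_O = 3.5,
    TAIL_C = 5.0, TERMINAL_C = 5.0, HEAD_OTHER = 3.5)
}

#' Per-atom water-contact table split by monomer/micelle state
#'
#' For each (species, atom role) pair, counts the water oxygens within the
#' role's cutoff of every tagged atom, averaged over frames and molecules,
#' aggregated separately by whether the molecule is part of a micelle or a
#' monomer in that frame (the state may change between frames). Reported
#' counts are rounded half away from zero, with the unrounded means
#' retained.
#'
#' @param cfg An [mk_configuration()].
#' @param assignments Per-frame `mk_clusters` list.
#' @param roles Atom roles to tabulate.
#' @param cutoffs Named per-role cutoffs, Angstrom.
#' @param min_micelle_size Passed to [assign_monomer_state()].
#' @return Data frame (class `mk_hydration_table`) with columns `species`,
#'   `role`, `micelle`, `monomer` (rounded), `micelle_mean`, `monomer_mean`,
#'   `n_micelle_obs`, `n_monomer_obs`.
#' @export
water_contact_table <- function(cfg, assignments,
                                roles = c("CHOLINE_N", "PHOSPHATE_P",
                                          "CARBONYL_O", "ESTER_O", "TERMINAL_C"),
                                cutoffs = default_contact_cutoffs(),
                                min_micelle_size = 5) {
  a <- cfg$atoms
  wat_o <- which(a$role == "WATER_O")
  tagged <- which(a$species != "WATER" & a$role %in% roles)
  if (!length(tagged)) mk_stop("no atoms carry the requested roles", "mk_selection_error")
  acc <- list()
  for (fi in seq_along(assignments)) {
    state <- assign_monomer_state(assignments[[fi]], min_micelle_size)
    box <- cfg$box[fi, ]
    n_contacts <- if (length(wat_o)) {
      d <- pair_dist_pbc(cfg$frames[[fi]][tagged, , drop = FALSE],
                         cfg$frames[[fi]][wat_o, , drop = FALSE], box)
      cut <- cutoffs[a$role[tagged]]
      rowSums(d <= cut)
    } else rep(0, length(tagged))
    acc[[fi]] <- data.frame(species = a$species[tagged], role = a$role[tagged],
                            state = unname(state[as.character(a$molecule_id[tagged])]),
                            n = n_contacts)
  }
  obs <- do.call(rbind, acc)
  key <- unique(obs[, c("species", "role")])
  rows <- lapply(seq_len(nrow(key)), function(i) {
    sub <- obs[obs$species == key$species[i] & obs$role == key$role[i], ]
    mic <- sub$n[sub$state == "MICELLE"]
    mon <- sub$n[sub$state == "MONOMER"]
    data.frame(species = key$species[i], role = key$role[i],
               micelle = if (length(mic)) round_half_away(mean(mic)) else NA_real_,
               monomer = if (length(mon)) round_half_away(mean(mon)) else NA_real_,
               micelle_mean = if (length(mic)) mean(mic) else NA_real_,
               monomer_mean = if (length(mon)) mean(mon) else NA_real_,
               n_micelle_obs = length(mic), n_monomer_obs = length(mon))
  })
  out <- do.call(rbind, rows)
  out <- out[order(match(out$species, mk_species), match(out$role, mk_roles)), ]
  rownames(out) <- NULL
  class(out) <- c("mk_hydration_table", "data.frame")
  out
}
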