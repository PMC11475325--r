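#' Cluster solute molecules by tail-carbon contacts
#'
#' Two molecules belong to the same aggregate when any pair of their linkage
#' atoms (by default tail and terminal carbons, the conventional hydrophobic
#' contact criterion for micelle aggregation) lies within `cutoff` under the
#' minimum-image convention; aggregates are the connected components of this
#' contact graph (single linkage). Water is never clustered.
#'
#' @param cfg An [mk_configuration()].
#' @param frame Frame index.
#' @param cutoff Contact distance, Angstrom (default 4.5).
#' @param linkage_roles Atom roles considered for contacts.
#' @return An object of class `mk_clusters` with `molecule_id`, `cluster_id`
#'   (dense ids from 0, in order of first appearance), `largest_cluster_id`
#'   (maximal member count, ties broken by lowest id) and `sizes`.
#' @export
cluster_molecules <- function(cfg, frame = 1, cutoff = 4.5,
                              linkage_roles = c("TAIL_C", "TERMINAL_C")) {
  if (cutoff <= 0) mk_stop("cutoff must be positive", "mk_parameter_error")
  a <- cfg$atoms
  sol_mols <- solute_molecule_ids(cfg)
  if (!length(sol_mols)) mk_stop("configuration has no solute molecules", "mk_empty_solute")
  sel <- a$species != "WATER" & a$role %in% linkage_roles
  if (!any(sel)) mk_stop("no atoms carry the requested linkage roles", "mk_parameter_error")
  xyz <- cfg$frames[[frame]][sel, , drop = FALSE]
  mol_of_atom <- match(a$molecule_id[sel], sol_mols)
  box <- cfg$box[frame, ]
  nm <- length(sol_mols)
  dm <- pair_dist_pbc(xyz, xyz, box)
  contact <- dm <= cutoff
  # collapse atom-pair contacts to molecule-pair adjacency
  adj <- rowsum(contact + 0, mol_of_atom)
  adj <- t(rowsum(t(adj), mol_of_atom)) > 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  memb <- igraph::components(g)$membership
  # dense ids from 0 in order of first appearance (permutation-stable sets)
  dense <- match(memb, unique(memb)) - 1L
  sizes <- as.integer(table(factor(dense, levels = sort(unique(dense)))))
  largest <- min(which(sizes == max(sizes))) - 1L
  structure(list(frame = frame,
                 molecule_id = sol_mols,
                 cluster_id = dense,
                 sizes = sizes,
                 largest_cluster_id = largest),
            class = "mk_clusters")
}

#' @export
print.mk_clusters <- function(x, ...) {
  cat(sprintf("<mk_clusters> frame %d: %d molecule(s) in %d cluster(s); largest = %d members\n",
              x$frame, length(x$molecule_id), length(x$sizes), max(x$sizes)))
  invisible(x)
}

# molecule ids belonging to the largest cluster of an assignment
largest_cluster_members <- function(cl) {
  cl$molecule_id[cl$cluster_id == cl$largest_cluster_id]
}

#' Aggregation-number time series
#'
#' Applies [cluster_molecules()] to every frame and reports the size and
#' per-species composition of the largest aggregate over time -- the
#' aggregation-number trace used to judge when a stable micelle has formed.
#'
#' @inheritParams cluster_molecules
#' @return Object of class `mk_agg_series`: a data frame with columns
#'   `frame`, `time_ns`, `largest_size` and one count column per species,
#'   plus attributes `totals` (per-species molecule totals) and
#'   `assignments` (the per-frame `mk_clusters` objects).
#' @export
aggregation_timeseries <- function(cfg, cutoff = 4.5,
                                   linkage_roles = c("TAIL_C", "TERMINAL_C")) {
  nf <- n_frames(cfg)
  a <- cfg$atoms
  species_of_mol <- a$species[!duplicated(a$molecule_id)]
  names(species_of_mol) <- a$molecule_id[!duplicated(a$molecule_id)]
  solute_species <- setdiff(mk_species, "WATER")
  assignments <- vector("list", nf)
  rows <- vector("list", nf)
  dt <- cfg$time_per_frame
  for (fi in seq_len(nf)) {
    cl <- cluster_molecules(cfg, frame = fi, cutoff = cutoff,
                            linkage_roles = linkage_roles)
    assignments[[fi]] <- cl
    members <- largest_cluster_members(cl)
    sp <- species_of_mol[as.character(members)]
    counts <- vapply(solute_species, function(s) sum(sp == s), integer(1))
    rows[[fi]] <- data.frame(frame = fi,
                             time_ns = if (is.na(dt)) NA_real_ else (fi - 1) * dt,
                             largest_size = length(members),
                             t(counts))
  }
  out <- do.call(rbind, rows)
  totals <- vapply(solute_species, function(s)
    sum(species_of_mol == s & names(species_of_mol) %in%
          as.character(solute_molecule_ids(cfg))), integer(1))
  structure(out, totals = totals, assignments = assignments,
            class = c("mk_agg_series", "data.frame"))
}

#' Micelle composition summary over an analysis window
#'
#' Mean +/- sample standard deviation of the per-species counts in the
#' largest aggregate over a window of frames, and the percentage of each
#' species resident in the micelle (`round(mean / total * 100)`). The window
#' defaults to the final half of the trajectory. Species absent from the
#' system are reported as `NA` (printed as a dash).
#'
#' @param series An [aggregation_timeseries()] result.
#' @param window Integer vector of frame indices (default: last 50%).
#' @param totals Named per-species totals (default: taken from the series).
#' @return Data frame with columns `species`, `mean_count`, `sd_count`,
#'   `percent`, `total`.
#' @export
micelle_composition <- function(series, window = NULL, totals = NULL) {
  nf <- nrow(series)
  window <- window %||% seq(max(1L, floor(nf / 2) + 1L), nf)
  if (!length(window) || any(window < 1 | window > nf))
    mk_stop("window must be a non-empty set of frame indices within the series",
            "mk_parameter_error")
  if (length(window) == 1L)
    warning("composition window has a single frame; sd reported as 0")
  totals <- totals %||% attr(series, "totals")
  solute_species <- names(totals)
  rows <- lapply(solute_species, function(s) {
    if (totals[[s]] == 0)
      return(data.frame(species = s, mean_count = NA_real_, sd_count = NA_real_,
                        percent = NA_real_, total = 0L))
    x <- series[window, s]
    sdv <- if (length(window) == 1L) 0 else stats::sd(x)
    data.frame(species = s, mean_count = mean(x), sd_count = sdv,
               percent = round(mean(x) / totals[[s]] * 100),
               total = as.integer(totals[[s]]))
  })
  do.call(rbind, rows)
}

#' Classify molecules as micelle members or monomers
#'
#' Molecules in aggregates of at least `min_micelle_size` members are in the
#' `MICELLE` state; smaller aggregates (including dimers and trimers) count
#' as `MONOMER`, matching the binary monomer/micelle bookkeeping used for
#' hydration tables.
#'
#' @param assignment An `mk_clusters` object from [cluster_molecules()].
#' @param min_micelle_size Minimum aggregate size to count as a micelle.
#' @return Named character vector (`MICELLE`/`MONOMER`) keyed by molecule id.
#' @export
assign_monomer_state <- function(assignment, min_micelle_size = 5) {
  size_of <- assignment$sizes[assignment$cluster_id + 1L]
  state <- ifelse(size_of >= min_micelle_size, "MICELLE", "MONOMER")
  names(state) <- assignment$molecule_id
  state
}
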