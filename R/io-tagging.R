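#' Default species/role tagging rules
#'
#' Maps (residue name, atom name) pairs to the (species, role) tags the
#' analytics consume, together with the element symbol and the mass carried
#' by the atom. The package represents lipids with a reduced pseudo-atom set
#' (one atom per tagged role plus four tail-carbon beads per hexanoyl chain),
#' so each bead carries the approximate summed mass of the chemical group it
#' stands for. Atom names follow CHARMM-style glycerophospholipid numbering:
#' the sn-2 chain is `O21/O22/C22..C26`, the sn-1 chain `O31/O32/C32..C36`,
#' so the carbonyl oxygens are `O22`/`O32` and the terminal methyls
#' `C26`/`C36`.
#'
#' @return Data frame with columns `resname`, `atom`, `species`, `role`,
#'   `element`, `mass`.
#' @export
default_tagging <- function() {
  chain <- function(prefix_o, prefix_c, first_c) {
    data.frame(
      atom = c(paste0("O", prefix_o, "1"), paste0("O", prefix_o, "2"),
               paste0("C", prefix_c, (first_c):(first_c + 3)), paste0("C", prefix_c, first_c + 4)),
      role = c("ESTER_O", "CARBONYL_O", rep("TAIL_C", 4), "TERMINAL_C"),
      element = c("O", "O", rep("C", 5)),
      mass = c(16.00, 28.01, rep(14.03, 4), 15.04))
  }
  pc_head <- data.frame(atom = c("N", "P"),
                        role = c("CHOLINE_N", "PHOSPHATE_P"),
                        element = c("N", "P"), mass = c(87.16, 136.08))
  pc <- rbind(pc_head, chain("2", "2", 2), chain("3", "3", 2))
  pc$resname <- "PC6"; pc$species <- "PC2C6"
  lyso <- rbind(pc_head, chain("2", "2", 2))
  lyso$resname <- "LY6"; lyso$species <- "LYSO"
  fa <- data.frame(
    atom = c("O1", "O2", paste0("C", 2:5), "C6"),
    role = c("CARBONYL_O", "ESTER_O", rep("TAIL_C", 4), "TERMINAL_C"),
    element = c("O", "O", rep("C", 5)),
    mass = c(28.01, 17.01, rep(14.03, 4), 15.04))
  fa$resname <- "FA6"; fa$species <- "FA"
  wat <- data.frame(atom = c("OW", "HW1", "HW2"),
                    role = c("WATER_O", "WATER_H", "WATER_H"),
                    element = c("O", "H", "H"),
                    mass = c(18.015, 1.008, 1.008))
  wat$resname <- "SOL"; wat$species <- "WATER"
  out <- rbind(pc, lyso, fa, wat)
  rownames(out) <- NULL
  out[, c("resname", "atom", "species", "role", "element", "mass")]
}

#' Read tagging rules from a YAML file
#'
#' The YAML holds a list of records with fields `resname`, `atom`, `species`,
#' `role`, `element`, `mass`, overriding or extending [default_tagging()].
#'
#' @param path YAML file path.
#' @param base Rules to extend (rows with matching resname+atom are replaced).
#' @return Tagging rules data frame.
#' @export
read_tagging_yaml <- function(path, base = default_tagging()) {
  raw <- yaml::read_yaml(path)
  rows <- do.call(rbind, lapply(raw, function(r) {
    data.frame(resname = r$resname, atom = r$atom, species = r$species,
               role = r$role, element = r$element %||% "X",
               mass = as.numeric(r$mass %||% 0))
  }))
  key <- function(d) paste(d$resname, d$atom)
  base <- base[!(key(base) %in% key(rows)), ]
  out <- rbind(base, rows)
  rownames(out) <- NULL
  out
}

# Apply tagging rules to raw (resname, atom name) pairs; errors listing every
# unknown pair so users can extend their table in one pass.
apply_tagging <- function(resname, atom, tagging) {
  idx <- match(paste(trimws(resname), trimws(atom)),
               paste(tagging$resname, tagging$atom))
  if (anyNA(idx)) {
    bad <- unique(paste0(trimws(resname), "/", trimws(atom))[is.na(idx)])
    mk_stop(paste0("no tagging rule for atom(s): ", paste(bad, collapse = ", ")),
            "mk_tagging_error")
  }
  tagging[idx, c("species", "role", "element", "mass")]
}
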