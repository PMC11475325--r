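#' Read a molecular configuration
#'
#' Reads single- or multi-frame coordinate files in GRO (concatenated
#' frames), PDB (`MODEL`/`ENDMDL` blocks) or extended-XYZ (with a
#' `Lattice="..."` box) format, converts coordinates to Angstrom, groups
#' atoms into molecules and applies species/role tagging rules. Only
#' orthorhombic boxes are supported; triclinic input is rejected. Atom order
#' is preserved exactly as in the file.
#'
#' @param path File to read.
#' @param format One of `"auto"`, `"gro"`, `"pdb"`, `"xyz"`; `"auto"` decides
#'   from the file extension.
#' @param tagging Tagging rules, see [default_tagging()].
#' @param time_per_frame Frame spacing in ns, carried into the result.
#' @return An [mk_configuration()] object.
#' @export
read_configuration <- function(path, format = c("auto", "gro", "pdb", "xyz"),
                               tagging = default_tagging(),
                               time_per_frame = NA_real_) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gro = "gro", pdb = "pdb", xyz = "xyz", extxyz = "xyz",
                     mk_stop(paste("cannot infer format from extension:", ext),
                             "mk_format_error"))
  }
  raw <- switch(format,
                gro = read_gro_raw(path),
                pdb = read_pdb_raw(path),
                xyz = read_xyz_raw(path))
  n <- vapply(raw$frames, nrow, integer(1))
  if (length(unique(n)) != 1L)
    mk_stop("atom count varies across frames", "mk_format_error")
  tags <- apply_tagging(raw$resname, raw$atom, tagging)
  # sequential molecule ids from runs of (residue id, residue name)
  runkey <- paste(raw$resid, raw$resname)
  mol_id <- cumsum(c(TRUE, runkey[-1] != runkey[-length(runkey)]))
  atoms <- data.frame(name = trimws(raw$atom), resname = trimws(raw$resname),
                      element = tags$element, molecule_id = mol_id,
                      species = tags$species, role = tags$role, mass = tags$mass,
                      stringsAsFactors = FALSE)
  cfg <- mk_configuration(raw$frames, raw$box, atoms, time_per_frame)
  check_topology(cfg)
  cfg
}

# --- GRO ---------------------------------------------------------------

read_gro_raw <- function(path) {
  lines <- readLines(path)
  frames <- list(); boxes <- list()
  resid <- resname <- atom <- NULL
  i <- 1L; first <- TRUE
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat)) mk_stop("malformed GRO: bad atom count line", "mk_format_error")
    body <- lines[(i + 2L):(i + 1L + nat)]
    if (first) {
      resid <- as.integer(substr(body, 1, 5))
      resname <- trimws(substr(body, 6, 10))
      atom <- trimws(substr(body, 11, 15))
    }
    xyz <- cbind(as.numeric(substr(body, 21, 28)),
                 as.numeric(substr(body, 29, 36)),
                 as.numeric(substr(body, 37, 44))) * 10  # nm -> Angstrom
    boxline <- as.numeric(strsplit(trimws(lines[i + 2L + nat]), "\\s+")[[1]])
    if (length(boxline) > 3 && any(abs(boxline[4:length(boxline)]) > 1e-9))
      mk_stop("triclinic GRO box not supported", "mk_box_error")
    frames[[length(frames) + 1L]] <- xyz
    boxes[[length(boxes) + 1L]] <- boxline[1:3] * 10
    i <- i + 3L + nat
    first <- FALSE
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  list(frames = frames, box = do.call(rbind, boxes),
       resid = resid, resname = resname, atom = atom)
}

# --- PDB ---------------------------------------------------------------

read_pdb_raw <- function(path) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  cr <- lines[startsWith(rec, "CRYST1")]
  if (!length(cr)) mk_stop("PDB lacks a CRYST1 box record", "mk_box_error")
  cv <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                     substr(cr[1], 25, 33), substr(cr[1], 34, 40),
                     substr(cr[1], 41, 47), substr(cr[1], 48, 54)))
  if (any(abs(cv[4:6] - 90) > 1e-3))
    mk_stop("non-orthorhombic PDB box not supported", "mk_box_error")
  is_atom <- startsWith(rec, "ATOM") | startsWith(rec, "HETATM")
  model_starts <- which(startsWith(rec, "MODEL "))
  if (!length(model_starts)) {
    blocks <- list(which(is_atom))
  } else {
    model_ends <- which(startsWith(rec, "ENDMDL"))
    if (length(model_ends) != length(model_starts))
      mk_stop("unbalanced MODEL/ENDMDL records", "mk_format_error")
    blocks <- Map(function(s, e) {
      idx <- s:e
      idx[is_atom[idx]]
    }, model_starts, model_ends)
  }
  first <- lines[blocks[[1]]]
  frames <- lapply(blocks, function(idx) {
    b <- lines[idx]
    cbind(as.numeric(substr(b, 31, 38)), as.numeric(substr(b, 39, 46)),
          as.numeric(substr(b, 47, 54)))
  })
  list(frames = frames,
       box = matrix(cv[1:3], nrow = length(frames), ncol = 3, byrow = TRUE),
       resid = as.integer(substr(first, 23, 26)),
       resname = trimws(substr(first, 18, 21)),
       atom = trimws(substr(first, 13, 16)))
}

# --- extended XYZ ------------------------------------------------------

parse_lattice <- function(comment) {
  m <- regmatches(comment, regexpr('Lattice="[^"]*"', comment))
  if (!length(m)) mk_stop("extended XYZ frame lacks a Lattice entry", "mk_box_error")
  v <- as.numeric(strsplit(sub('Lattice="([^"]*)"', "\\1", m), "\\s+")[[1]])
  if (length(v) != 9) mk_stop("Lattice must hold 9 numbers", "mk_box_error")
  off <- v[c(2, 3, 4, 6, 7, 8)]
  if (any(abs(off) > 1e-9))
    mk_stop("non-orthorhombic Lattice not supported", "mk_box_error")
  v[c(1, 5, 9)]
}

read_xyz_raw <- function(path) {
  lines <- readLines(path)
  frames <- list(); boxes <- list()
  resid <- resname <- atom <- NULL
  i <- 1L; first <- TRUE
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat)) mk_stop("malformed XYZ: bad atom count line", "mk_format_error")
    box <- parse_lattice(lines[i + 1L])
    body <- lines[(i + 2L):(i + 1L + nat)]
    tok <- strsplit(trimws(body), "\\s+")
    ncol_tok <- lengths(tok)
    if (any(ncol_tok < 7))
      mk_stop("extended XYZ needs columns: element x y z molid resname name",
              "mk_format_error")
    tok <- do.call(rbind, tok)
    xyz <- cbind(as.numeric(tok[, 2]), as.numeric(tok[, 3]), as.numeric(tok[, 4]))
    if (first) {
      resid <- as.integer(tok[, 5])
      resname <- tok[, 6]
      atom <- tok[, 7]
    }
    frames[[length(frames) + 1L]] <- xyz
    boxes[[length(boxes) + 1L]] <- box
    i <- i + 2L + nat
    first <- FALSE
  }
  list(frames = frames, box = do.call(rbind, boxes),
       resid = resid, resname = resname, atom = atom)
}

#' Read a reduced SANS curve from delimited text
#'
#' Accepts whitespace- or comma-delimited text with two columns (q, I) or
#' three (q, I, sigma); `#` comment lines are skipped. Two-column input is
#' assigned `sigma = pmax(0.01 * I, .Machine$double.eps)`. Rows with q <= 0
#' are dropped with a warning.
#'
#' @param path File to read.
#' @param label Curve label (defaults to the file name).
#' @return A [sans_curve()].
#' @export
read_sans_curve <- function(path, label = basename(path)) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  tok <- strsplit(gsub(",", " ", lines), "\\s+")
  nc <- lengths(tok)
  if (!length(nc) || !all(nc %in% c(2L, 3L)) || length(unique(nc)) != 1L)
    mk_stop("SANS curve files need 2 or 3 numeric columns", "mk_format_error")
  m <- suppressWarnings(matrix(as.numeric(unlist(tok)), ncol = nc[1], byrow = TRUE))
  if (anyNA(m)) mk_stop("non-numeric entries in SANS curve file", "mk_format_error")
  sigma <- if (ncol(m) == 3) m[, 3] else pmax(0.01 * m[, 2], .Machine$double.eps)
  sans_curve(m[, 1], m[, 2], sigma, label = label)
}
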