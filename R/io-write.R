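#' Write a configuration to GRO, PDB or extended XYZ
#'
#' Inverse of [read_configuration()]: writes every frame, preserving atom
#' order and molecule grouping. GRO files are written in nm (converted from
#' the internal Angstrom), PDB and XYZ in Angstrom. The extended-XYZ writer
#' emits `element x y z molid resname name` columns plus a `Lattice`
#' comment, which round-trips all tags exactly; GRO and PDB retain tags via
#' the (resname, atom name) pairs and the tagging table.
#'
#' @param cfg An [mk_configuration()] object.
#' @param path Output file.
#' @param format `"gro"`, `"pdb"` or `"xyz"` (default from extension).
#' @return `path`, invisibly.
#' @export
write_configuration <- function(cfg, path, format = c("auto", "gro", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gro = "gro", pdb = "pdb", xyz = "xyz", extxyz = "xyz",
                     mk_stop(paste("cannot infer format from extension:", ext),
                             "mk_format_error"))
  }
  a <- cfg$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (fi in seq_along(cfg$frames)) {
    xyz <- cfg$frames[[fi]]
    box <- cfg$box[fi, ]
    switch(format,
      gro = {
        writeLines(sprintf("micellekit frame %d", fi), con)
        writeLines(sprintf("%5d", nrow(a)), con)
        writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                           a$molecule_id %% 100000L, a$resname, a$name,
                           seq_len(nrow(a)) %% 100000L,
                           xyz[, 1] / 10, xyz[, 2] / 10, xyz[, 3] / 10), con)
        writeLines(sprintf("%10.5f%10.5f%10.5f", box[1] / 10, box[2] / 10, box[3] / 10), con)
      },
      pdb = {
        if (fi == 1L)
          writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                             box[1], box[2], box[3], 90, 90, 90), con)
        writeLines(sprintf("MODEL     %4d", fi), con)
        writeLines(sprintf("ATOM  %5d %-4s %-4s %4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                           seq_len(nrow(a)) %% 100000L, substr(a$name, 1, 4),
                           substr(a$resname, 1, 4), a$molecule_id %% 10000L,
                           xyz[, 1], xyz[, 2], xyz[, 3], substr(a$element, 1, 2)), con)
        writeLines("ENDMDL", con)
      },
      xyz = {
        writeLines(sprintf("%d", nrow(a)), con)
        writeLines(sprintf(
          'Lattice="%.6f 0.0 0.0 0.0 %.6f 0.0 0.0 0.0 %.6f" Properties=species:S:1:pos:R:3:molid:I:1:resname:S:1:name:S:1 Frame=%d',
          box[1], box[2], box[3], fi), con)
        writeLines(sprintf("%-2s %12.6f %12.6f %12.6f %6d %-5s %-5s",
                           a$element, xyz[, 1], xyz[, 2], xyz[, 3],
                           a$molecule_id, a$resname, a$name), con)
      })
  }
  invisible(path)
}

#' Write a SANS curve as 3-column text
#'
#' @param curve A [sans_curve()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sans_curve <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s", curve$label), con)
  writeLines("# q_invA intensity_invcm sigma_invcm", con)
  writeLines(sprintf("%.8g %.10g %.10g", curve$q, curve$intensity, curve$sigma), con)
  invisible(path)
}
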