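#' Read a receptor from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d) into a [receptor()]. Waters
#' (residue names HOH/WAT/DOD) and hydrogens are excluded by default, as is
#' conventional when preparing a rigid receptor for grid construction.
#' Backbone atoms are identified by atom name (N, CA, C, O) in ATOM records.
#'
#' A light line-level scan is performed first so that a malformed
#' ATOM/HETATM record raises an error naming the offending line, rather
#' than being silently skipped.
#'
#' @param path Path to a PDB file.
#' @param keep_waters Keep water residues (default FALSE).
#' @param keep_hydrogens Keep hydrogen atoms (default FALSE).
#' @return A [receptor()].
#' @export
read_pdb <- function(path, keep_waters = FALSE, keep_hydrogens = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(rec)) {
    ln <- lines[i]
    ok <- nchar(ln) >= 54 &&
      !anyNA(suppressWarnings(as.numeric(c(
        substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54)))))
    if (!ok) {
      stop(sprintf("malformed PDB record at line %d: '%s'", i, ln),
           call. = FALSE)
    }
  }
  if (!any(rec)) stop("no ATOM/HETATM records in ", path, call. = FALSE)

  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  elty <- trimws(at$elety)
  elem <- trimws(at$elesy)
  elem[is.na(elem) | elem == ""] <- substr(elty[is.na(elem) | elem == ""], 1, 1)
  elem <- normalize_element(elem)

  keep <- rep(TRUE, nrow(at))
  if (!keep_waters) keep <- keep & !(at$resid %in% c("HOH", "WAT", "DOD"))
  if (!keep_hydrogens) keep <- keep & !is_hydrogen(elem)
  if (!any(keep)) stop("no atoms left after filtering in ", path, call. = FALSE)
  at <- at[keep, , drop = FALSE]
  elem <- elem[keep]
  elty <- elty[keep]

  backbone <- at$type == "ATOM" & elty %in% c("N", "CA", "C", "O")
  receptor(
    elements = elem,
    coords = cbind(at$x, at$y, at$z),
    backbone = backbone,
    atom_names = elty,
    resid = at$resid,
    resno = at$resno,
    chain = at$chain
  )
}

#' Write a receptor to a PDB file
#'
#' Emits standard fixed-width ATOM records. Used mainly to materialise
#' synthetic receptors for external tools; `read_pdb(write_pdb(r))` round
#' trips coordinates at PDB precision (1e-3 A).
#'
#' @param rec A [receptor()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(rec, path) {
  n <- length(rec$elements)
  name4 <- vapply(seq_len(n), function(i) {
    nm <- rec$atom_names[i]
    if (is.na(nm)) nm <- rec$elements[i]
    if (nchar(nm) < 4) sprintf(" %-3s", nm) else substr(nm, 1, 4)
  }, "")
  lines <- sprintf(
    "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(n), name4, substr(rec$resid, 1, 3), substr(rec$chain, 1, 1),
    rec$resno, rec$coords[, 1], rec$coords[, 2], rec$coords[, 3],
    toupper(rec$elements))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
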