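#' Read a ligand (with optional conformer library) from an SD file
#'
#' Parses a V2000 SD file via ChemmineR. A multi-record file is interpreted
#' as a conformer library of a single molecule: record 1 becomes conformer
#' 1 and later records are appended as further conformers. All records must
#' therefore share the same element sequence. Hydrogens are kept as atoms
#' but all scoring, RMSD and grid machinery operates on heavy atoms only.
#'
#' @param path Path to an SD/SDF file.
#' @return A [molecule()] whose `conformers` holds one coordinate set per
#'   record.
#' @export
read_sdf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sdfs <- ChemmineR::read.SDFset(path)
  if (length(sdfs) == 0) stop("no records in ", path, call. = FALSE)

  parse_one <- function(sdf) {
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    elems <- sub("_.*$", "", rownames(ab))
    coords <- unname(ab[, 1:3, drop = FALSE])
    bonds <- if (NROW(bb) > 0) {
      data.frame(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
                 order = as.integer(bb[, 3]))
    } else NULL
    list(elements = elems, coords = coords, bonds = bonds)
  }

  first <- parse_one(sdfs[[1]])
  if (!any(!is_hydrogen(first$elements))) {
    stop("molecule in ", path, " has no heavy atoms", call. = FALSE)
  }
  confs <- NULL
  if (length(sdfs) > 1) {
    confs <- vector("list", length(sdfs) - 1)
    for (k in 2:length(sdfs)) {
      rec <- parse_one(sdfs[[k]])
      if (!identical(normalize_element(rec$elements),
                     normalize_element(first$elements))) {
        stop("record ", k, " in ", path,
             " has a different element sequence; multi-record SD input",
             " must be a conformer library of one molecule", call. = FALSE)
      }
      confs[[k - 1]] <- rec$coords
    }
  }
  nm <- ChemmineR::header(sdfs[[1]])[["Molecule_Name"]]
  if (is.null(nm) || is.na(nm) || nm == "") nm <- "LIG"
  molecule(first$elements, first$coords, first$bonds,
           conformers = confs, name = nm)
}

#' Write poses to an SD file
#'
#' One V2000 record per pose, sharing the molecule's bond table; grid
#' score, full-atom score and RMSD (when available) are written as SD data
#' fields `<grid_score>`, `<fa_score>` and `<rmsd>`. Coordinates are
#' written at 1e-4 A precision, so a read/write round trip preserves them
#' to that tolerance.
#'
#' @param poses A list of [pose()] objects sharing one molecule, or a
#'   single pose.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(poses, path) {
  if (inherits(poses, "pose")) poses <- list(poses)
  if (length(poses) == 0) {
    warning("writing empty SD file: no poses supplied")
    writeLines(character(), path)
    return(invisible(path))
  }
  mol <- poses[[1]]$mol
  for (p in poses) {
    if (!identical(p$mol$elements, mol$elements)) {
      stop("all poses must share one molecule", call. = FALSE)
    }
  }
  out <- character()
  for (p in poses) {
    out <- c(out, sdf_record(mol, p$coords, list(
      grid_score = p$grid_score, fa_score = p$fa_score, rmsd = p$rmsd)))
  }
  writeLines(out, path)
  invisible(path)
}

sdf_record <- function(mol, coords, fields = list()) {
  n <- length(mol$elements)
  nb <- nrow(mol$bonds)
  lines <- c(
    mol$name,
    "  griddock",
    "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            coords[, 1], coords[, 2], coords[, 3], mol$elements))
  if (nb > 0) {
    lines <- c(lines, sprintf("%3d%3d%3d  0", mol$bonds$from, mol$bonds$to,
                              mol$bonds$order))
  }
  lines <- c(lines, "M  END")
  for (nm in names(fields)) {
    v <- fields[[nm]]
    if (!is.null(v) && !is.na(v)) {
      lines <- c(lines, sprintf("> <%s>", nm), format(v, digits = 10), "")
    }
  }
  c(lines, "$$$$")
}
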