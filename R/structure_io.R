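#' Backbone traces
#'
#' A `backbone_trace` holds the ordered backbone-atom records of one
#' structure: residue index, atom name (a subset of N, CA, C, O) and
#' Cartesian coordinates in Angstroms, in file order.  All chains of the
#' entry are concatenated into a single point cloud.
#'
#' @param structure_id Character scalar identifying the structure.
#' @param residue_index Integer vector, non-decreasing along the trace.
#' @param atom_name Character vector of backbone atom names.
#' @param coords Numeric matrix with one row per atom and columns x, y, z
#'   (Angstroms).
#' @return An object of class `backbone_trace`.
#' @seealso [parse_pdb()], [barycenter()]
#' @export
backbone_trace <- function(structure_id, residue_index, atom_name, coords) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (nrow(coords) == 0L)
    stop("empty structure: no backbone atoms for '", structure_id, "'")
  if (nrow(coords) != length(atom_name) || nrow(coords) != length(residue_index))
    stop("residue_index, atom_name and coords must have one entry per atom")
  if (!all(is.finite(coords)))
    stop("non-finite coordinates in '", structure_id, "'")
  colnames(coords) <- c("x", "y", "z")
  structure(
    list(structure_id = as.character(structure_id),
         residue_index = as.integer(residue_index),
         atom_name = as.character(atom_name),
         coords = coords),
    class = "backbone_trace")
}

#' @export
print.backbone_trace <- function(x, ...) {
  cat(sprintf("<backbone_trace> %s: %d atoms, %d residues\n",
              x$structure_id, nrow(x$coords), length(unique(x$residue_index))))
  invisible(x)
}

#' Read backbone atoms from a PDB file
#'
#' Parses a PDB-format file and returns the ordered backbone atoms (by
#' default N, CA, C, O) of its first model.  `HETATM` records are excluded,
#' alternate locations other than blank or `A` are dropped, and all chains
#' are concatenated in file order.  Occupancy and B-factor are ignored.
#'
#' @param path Path to a PDB-format file.
#' @param structure_id Identifier stored in the trace; defaults to the file
#'   name without extension.
#' @param backbone_atoms Character vector of atom names to retain.
#' @return A [backbone_trace()].
#' @examples
#' pdb <- system.file("extdata", "synthetic_helix.pdb", package = "enzyvox")
#' tr <- parse_pdb(pdb)
#' nrow(tr$coords)
#' @export
parse_pdb <- function(path, structure_id = NULL,
                      backbone_atoms = c("N", "CA", "C", "O")) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  if (is.null(structure_id))
    structure_id <- sub("\\.[^.]*$", "", basename(path))
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, verbose = FALSE, rm.alt = FALSE),
    error = function(e) stop("failed to parse PDB '", path, "': ",
                             conditionMessage(e)))
  at <- pdb$atom
  keep <- at$type == "ATOM" &
    at$elety %in% backbone_atoms &
    (is.na(at$alt) | at$alt %in% c("", "A"))
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L)
    stop("empty structure: no backbone atoms found in '", structure_id, "'")
  backbone_trace(structure_id,
                 residue_index = at$resno,
                 atom_name = at$elety,
                 coords = cbind(at$x, at$y, at$z))
}

#' Barycenter of a backbone trace
#'
#' Unweighted mean position of all backbone atoms; the center used for the
#' intrinsic coordinate system of the voxel representation.
#'
#' @param trace A [backbone_trace()].
#' @return Numeric length-3 vector (Angstroms).
#' @export
barycenter <- function(trace) {
  stopifnot(inherits(trace, "backbone_trace"))
  if (nrow(trace$coords) == 0L) stop("empty trace")
  colMeans(trace$coords)
}
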