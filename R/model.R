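# Molecular data model: molecule specs, planar molecules, frames, ensembles.
#
# Coordinates are Angstrom throughout. Frames are 0-indexed internally and
# 1-indexed in printed reports. Boxes are orthorhombic edge lengths; all
# interatomic distances honor the minimum-image convention when a box is
# present.

#' Define the role map of a molecule type
#'
#' A `molecule_spec` names the atoms an analysis needs: the aromatic ring
#' (plane fit), an ordered pair of atoms defining the intramolecular
#' reference vector (orientation angle theta), hydrogen-bond acceptor heavy
#' atoms, and labeled hydrogens.
#'
#' @param name spec name, e.g. `"solute"` or `"modifier"`
#' @param role one of `"solute"`, `"modifier"`
#' @param ring_atoms ordered atom names defining the aromatic plane (>= 3)
#' @param reference_atoms ordered pair of atom names; the in-plane vector
#'   runs from the first to the second
#' @param acceptor_atoms names of hydrogen-bond acceptor heavy atoms
#' @param hydrogen_atoms names of hydrogens with stable labels
#' @return an object of class `molecule_spec`
#' @export
molecule_spec <- function(name, role = c("solute", "modifier"), ring_atoms,
                          reference_atoms, acceptor_atoms = character(),
                          hydrogen_atoms = character()) {
  role <- match.arg(role)
  ring_atoms <- as.character(ring_atoms)
  reference_atoms <- as.character(reference_atoms)
  if (length(ring_atoms) < 3L)
    stop("molecule_spec: ring_atoms needs at least 3 atom names")
  if (length(reference_atoms) != 2L || reference_atoms[1] == reference_atoms[2])
    stop("molecule_spec: reference_atoms must be two distinct atom names")
  structure(list(name = as.character(name), role = role,
                 ring_atoms = ring_atoms, reference_atoms = reference_atoms,
                 acceptor_atoms = as.character(acceptor_atoms),
                 hydrogen_atoms = as.character(hydrogen_atoms)),
            class = "molecule_spec")
}

# Element symbol from an atom label: leading letters, first letter kept
# upper-case ("H13" -> "H", "N3" -> "N", "HR2" -> "H").
element_from_name <- function(name) {
  el <- sub("[0-9].*$", "", name)
  ifelse(substr(el, 1, 1) == "H", "H", substr(el, 1, 1))
}

#' Construct a planar molecule instance
#'
#' @param molecule_id integer id, unique within a frame
#' @param spec a [molecule_spec()]
#' @param xyz n x 3 coordinate matrix (Angstrom) with atom names as rownames
#' @param element optional element symbols (defaults derived from atom names)
#' @return an object of class `planar_molecule`
#' @export
planar_molecule <- function(molecule_id, spec, xyz, element = NULL) {
  if (!inherits(spec, "molecule_spec")) stop("spec must be a molecule_spec")
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stop("xyz must have 3 columns")
  if (is.null(rownames(xyz))) stop("xyz must carry atom names as rownames")
  if (!all(is.finite(xyz))) stop("non-finite coordinates in molecule ",
                                 molecule_id)
  element <- element %||% element_from_name(rownames(xyz))
  needed <- unique(c(spec$ring_atoms, spec$reference_atoms,
                     spec$acceptor_atoms, spec$hydrogen_atoms))
  missing <- setdiff(needed, rownames(xyz))
  if (length(missing))
    stop("molecule ", molecule_id, " (spec '", spec$name,
         "'): unresolvable atom name(s): ", paste(missing, collapse = ", "))
  structure(list(molecule_id = as.integer(molecule_id), spec = spec,
                 xyz = xyz, element = element),
            class = "planar_molecule")
}

#' @export
print.planar_molecule <- function(x, ...) {
  cat(sprintf("<planar_molecule> id=%d spec=%s (%s), %d atoms\n",
              x$molecule_id, x$spec$name, x$spec$role, nrow(x$xyz)))
  invisible(x)
}

# --- accessors --------------------------------------------------------------

#' Coordinates of named atoms of a molecule
#' @param mol a `planar_molecule`
#' @param atoms atom names; all atoms when `NULL`
#' @return m x 3 coordinate matrix
#' @export
atom_xyz <- function(mol, atoms = NULL) {
  if (is.null(atoms)) return(mol$xyz)
  idx <- match(atoms, rownames(mol$xyz))
  if (anyNA(idx))
    stop("atom(s) not found in molecule ", mol$molecule_id, ": ",
         paste(atoms[is.na(idx)], collapse = ", "))
  mol$xyz[idx, , drop = FALSE]
}

ring_xyz <- function(mol) atom_xyz(mol, mol$spec$ring_atoms)

#' Ring centroid of a planar molecule
#' @param mol a `planar_molecule`
#' @return length-3 numeric position (Angstrom)
#' @export
ring_centroid <- function(mol) colMeans(ring_xyz(mol))

#' Heavy-atom (non-hydrogen) coordinates of a molecule
#' @param mol a `planar_molecule`
#' @return m x 3 coordinate matrix
#' @export
heavy_xyz <- function(mol) mol$xyz[mol$element != "H", , drop = FALSE]

#' Unit intramolecular reference vector
#' @param mol a `planar_molecule`
#' @return unit length-3 numeric vector
#' @export
reference_vector <- function(mol) {
  p <- atom_xyz(mol, mol$spec$reference_atoms)
  unitv(p[2, ] - p[1, ])
}

# --- frames and ensembles ---------------------------------------------------

#' Construct a configuration frame
#'
#' @param molecules list of [planar_molecule()] objects
#' @param box orthorhombic edge lengths (Angstrom) or `NULL`
#' @param frame_index 0-based frame index
#' @param time time in ps or `NULL`
#' @return an object of class `md_frame`
#' @export
md_frame <- function(molecules, box = NULL, frame_index = 0L, time = NULL) {
  ids <- vapply(molecules, function(m) m$molecule_id, integer(1))
  if (anyDuplicated(ids))
    stop("duplicate molecule ids in frame ", frame_index)
  nmod <- sum(vapply(molecules, function(m) m$spec$role == "modifier",
                     logical(1)))
  if (nmod > 1L)
    stop("frame ", frame_index, ": at most one modifier per frame")
  if (!is.null(box) && (length(box) != 3L || any(box <= 0)))
    stop("box must be 3 positive edge lengths")
  structure(list(molecules = molecules, box = box,
                 frame_index = as.integer(frame_index), time = time),
            class = "md_frame")
}

frame_roles <- function(fr)
  vapply(fr$molecules, function(m) m$spec$role, character(1))

#' Solute molecules of a frame
#' @param fr an `md_frame`
#' @return list of `planar_molecule`
#' @export
frame_solutes <- function(fr) fr$molecules[frame_roles(fr) == "solute"]

#' The modifier molecule of a frame, or NULL
#' @param fr an `md_frame`
#' @return a `planar_molecule` or `NULL`
#' @export
frame_modifier <- function(fr) {
  i <- which(frame_roles(fr) == "modifier")
  if (!length(i)) NULL else fr$molecules[[i]]
}

#' Construct a configuration ensemble
#'
#' All frames must share the same molecule roster (ids and spec names).
#'
#' @param frames ordered list of [md_frame()] objects
#' @param metadata free-form provenance list (source path, generator seed...)
#' @return an object of class `ensemble`
#' @export
ensemble <- function(frames, metadata = list()) {
  if (!length(frames)) stop("ensemble must contain at least one frame")
  roster <- function(fr)
    paste(vapply(fr$molecules, function(m) m$molecule_id, integer(1)),
          vapply(fr$molecules, function(m) m$spec$name, character(1)),
          sep = ":", collapse = ",")
  r0 <- roster(frames[[1]])
  for (i in seq_along(frames)) {
    if (roster(frames[[i]]) != r0)
      stop("frame ", i - 1, " does not share the molecule roster of frame 0")
  }
  structure(list(frames = frames, metadata = metadata), class = "ensemble")
}

#' Number of frames in an ensemble
#' @param ens an `ensemble`
#' @return integer frame count
#' @export
n_frames <- function(ens) length(ens$frames)

#' @export
print.ensemble <- function(x, ...) {
  fr <- x$frames[[1]]
  cat(sprintf("<ensemble> %d frames, %d molecules/frame (%d solute, %d modifier)%s\n",
              n_frames(x), length(fr$molecules),
              sum(frame_roles(fr) == "solute"),
              sum(frame_roles(fr) == "modifier"),
              if (is.null(fr$box)) "" else
                sprintf(", box %.1f x %.1f x %.1f A",
                        fr$box[1], fr$box[2], fr$box[3])))
  invisible(x)
}

# Apply a rigid transform (rotation R then translation t) to every atom of
# every molecule of a frame.
transform_frame <- function(fr, R, t) {
  fr$molecules <- lapply(fr$molecules, function(m) {
    m$xyz <- sweep(m$xyz %*% t(R), 2, t, "+")
    dimnames(m$xyz) <- list(rownames(m$xyz), NULL)
    m
  })
  fr
}
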