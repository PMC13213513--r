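# Idealized molecule templates used by the synthetic-ensemble generator.
#
# The analysis depends only on planarity, a reference vector, and labeled
# acceptor/hydrogen sites; the templates are geometric idealizations that
# preserve exactly those features. Shared constants tie the generator's
# hydrogen-bond construction to the classifier cutoff and to the idealized
# crystal lattice spacing so the two definitions cannot drift apart.

# Geometry constants (Angstrom / radians)
SOLUTE_RING_RADIUS <- 1.6   # circumradius of the 9-gon aromatic ring
SOLUTE_SUB_RADIUS  <- 2.4   # radial distance of substituent sites
HBOND_CUTOFF       <- 2.5   # hydrogen...acceptor heavy atom contact cutoff
HBOND_TARGET       <- 1.9   # generated H-bond contact distance (< cutoff)
MODIFIER_RING_RADIUS <- 1.4 # hexagon circumradius of the modifier core
MODIFIER_RING_STEP <- 2.42  # fused-hexagon center spacing
ADSORPTION_GAP     <- 3.3   # face-normal offset of adsorbed solutes

# Substituent site azimuths (degrees) on the solute template.
.SOLUTE_SITES <- list(
  N3 = 0, O2 = 90, O6 = 135, O8 = 225,  # acceptors
  H1 = 180, H2 = 270                    # donor hydrogens
)

#' Idealized planar solute template
#'
#' Nine ring atoms `C1..C9` on a regular polygon (circumradius 1.6 A) with
#' four acceptor sites (`N3`, `O2`, `O6`, `O8`) and two donor hydrogens
#' (`H1`, `H2`) at 2.4 A in-plane radius. All atoms lie exactly in the
#' z = 0 plane; the construction is deterministic and seed-free.
#'
#' @return list with `spec` ([molecule_spec()]), `xyz` (atoms x 3 matrix)
#' @export
solute_template <- function() {
  ring_names <- paste0("C", 1:9)
  ang <- (0:8) * (2 * pi / 9)
  ring <- cbind(SOLUTE_RING_RADIUS * cos(ang),
                SOLUTE_RING_RADIUS * sin(ang), 0)
  sub_ang <- unlist(.SOLUTE_SITES) * pi / 180
  subs <- cbind(SOLUTE_SUB_RADIUS * cos(sub_ang),
                SOLUTE_SUB_RADIUS * sin(sub_ang), 0)
  xyz <- rbind(ring, subs)
  rownames(xyz) <- c(ring_names, names(.SOLUTE_SITES))
  spec <- molecule_spec(
    name = "solute", role = "solute",
    ring_atoms = ring_names, reference_atoms = c("C1", "C5"),
    acceptor_atoms = c("N3", "O2", "O6", "O8"),
    hydrogen_atoms = c("H1", "H2"))
  list(spec = spec, xyz = xyz)
}

#' Idealized planar modifier template
#'
#' A row of `size` fused hexagonal rings (circumradius 1.4 A, center
#' spacing 2.42 A) with rim hydrogens, and optionally a short side chain
#' carrying the labeled hydrogen `H13` (plus its carrier atom `C13`) near
#' one end of the row, slightly out of plane. The in-plane ring extent is
#' strictly increasing in `size`.
#'
#' @param size number of fused-ring units (>= 1)
#' @param with_side_chain include the `C13`/`H13` side-chain site?
#' @return list with `spec`, `xyz`, `size`, `with_side_chain`,
#'   `anchors` (in-plane adsorption anchor points used by the generator),
#'   `extent` (in-plane ring extent, A)
#' @export
modifier_template <- function(size = 3L, with_side_chain = TRUE) {
  size <- as.integer(size)
  if (size < 1L) stop("modifier size must be >= 1")
  centers <- (seq_len(size) - (size + 1) / 2) * MODIFIER_RING_STEP
  pts <- NULL
  for (cx in centers) {
    a <- pi / 6 + (0:5) * pi / 3   # pointy-side hexagon, shares fused edges
    pts <- rbind(pts, cbind(cx + MODIFIER_RING_RADIUS * cos(a),
                            MODIFIER_RING_RADIUS * sin(a), 0))
  }
  # deduplicate fused-edge atoms
  keep <- rep(TRUE, nrow(pts))
  for (i in seq_len(nrow(pts))[-1]) {
    d <- sqrt(rowSums((pts[seq_len(i - 1), , drop = FALSE] -
                         matrix(pts[i, ], i - 1, 3, byrow = TRUE))^2))
    if (any(d[keep[seq_len(i - 1)]] < 0.2)) keep[i] <- FALSE
  }
  ring <- pts[keep, , drop = FALSE]
  ring_names <- paste0("M", seq_len(nrow(ring)))
  rownames(ring) <- ring_names
  # rim hydrogens above/below the row axis at each ring center
  hr <- NULL
  for (i in seq_along(centers)) {
    hr <- rbind(hr, c(centers[i], SOLUTE_SUB_RADIUS, 0),
                c(centers[i], -SOLUTE_SUB_RADIUS, 0))
  }
  rownames(hr) <- paste0("HR", seq_len(nrow(hr)))
  xyz <- rbind(ring, hr)
  hyd <- rownames(hr)
  if (with_side_chain) {
    x13 <- centers[length(centers)] + 1.2
    side <- rbind(C13 = c(x13, 0, 1.0), H13 = c(x13, 0, 1.8))
    xyz <- rbind(xyz, side)
    hyd <- c(hyd, "H13")
  }
  spec <- molecule_spec(
    name = sprintf("modifier%d%s", size, if (with_side_chain) "s" else ""),
    role = "modifier",
    ring_atoms = ring_names,
    reference_atoms = c(ring_names[1], ring_names[2]),
    hydrogen_atoms = hyd)
  anchors <- if (size == 1L) centers else range(centers)
  extent <- max(stats::dist(ring[, 1:2]))
  list(spec = spec, xyz = xyz, size = size,
       with_side_chain = with_side_chain,
       anchors = anchors, extent = extent)
}

# In-plane heavy-atom diameter of the solute template ("footprint").
solute_footprint <- function() {
  tpl <- solute_template()
  heavy <- tpl$xyz[element_from_name(rownames(tpl$xyz)) != "H", , drop = FALSE]
  max(stats::dist(heavy[, 1:2]))
}

# Centroid spacing of the head-on hydrogen-bonded coplanar construction;
# also the in-plane spacing of the idealized crystal lattice.
coplanar_spacing <- function() 2 * SOLUTE_SUB_RADIUS + HBOND_TARGET

# Instantiate a template as a planar_molecule after rigid placement.
instantiate <- function(tpl, molecule_id, R = diag(3), t = c(0, 0, 0)) {
  xyz <- sweep(tpl$xyz %*% t(R), 2, t, "+")
  rownames(xyz) <- rownames(tpl$xyz)
  planar_molecule(molecule_id, tpl$spec, xyz)
}
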