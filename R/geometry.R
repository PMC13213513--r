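# Dimer order parameters (r, theta, psi), conformer classification, stacking
# polarity, and hydrogen-bond contact testing.
#
# Conventions:
#  * psi is the angle between the a -> b ring-centroid unit vector and the
#    plane normal of molecule a, where a is the member with the lower
#    molecule_id; psi spans [0, pi], so stacked pairs sit near 0 or pi and
#    coplanar pairs near pi/2. A symmetrized variant (mean of both normals'
#    angles) is available via `reference = "symmetric"`.
#  * theta is the angle between the two intramolecular reference vectors,
#    in [0, pi] (undirected orientation angle).

#' Unit normal of the least-squares ring plane
#'
#' The normal is the smallest-singular-value direction of the centered ring
#' coordinates. Its sign is fixed deterministically: positive component
#' along (reference vector) x (first ring bond).
#'
#' @param mol a [planar_molecule()]
#' @return unit length-3 normal vector
#' @export
plane_normal <- function(mol) {
  rx <- ring_xyz(mol)
  cen <- sweep(rx, 2, colMeans(rx))
  sv <- svd(cen)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-300))
    stop("degenerate geometry: ring atoms of molecule ", mol$molecule_id,
         " are (near-)collinear")
  n <- sv$v[, 3]
  b1 <- rx[2, ] - rx[1, ]
  s <- cross3(reference_vector(mol), b1)
  if (sum(n * s) < 0) n <- -n
  unitv(n)
}

#' Dimer conformational parameters (r, theta, psi)
#'
#' @param a,b two solute [planar_molecule()]s; internally ordered so the
#'   lower molecule_id provides the reference normal (unless
#'   `reference = "first"`)
#' @param box orthorhombic box edge lengths or `NULL`
#' @param reference `"lower_id"` (default), `"first"` (use `a` as given), or
#'   `"symmetric"` (psi averaged over both members' normals after folding
#'   b's angle through pi)
#' @param frame_index frame index carried into the result
#' @return object of class `dimer_geometry`: list with `r` (A), `theta`,
#'   `psi` (radians in \[0, pi\]), `polarity` (`"undefined"` until the pair is
#'   classified stacked), `pair_ids`, `frame_index`
#' @export
dimer_params <- function(a, b, box = NULL,
                         reference = c("lower_id", "first", "symmetric"),
                         frame_index = NA_integer_) {
  reference <- match.arg(reference)
  if (reference != "first" && b$molecule_id < a$molecule_id) {
    tmp <- a; a <- b; b <- tmp
  }
  d <- min_image(ring_centroid(b) - ring_centroid(a), box)
  r <- vnorm(d)
  if (r < 1e-9)
    stop("coincident ring centroids (r < 1e-9 A): psi is undefined for pair ",
         a$molecule_id, "-", b$molecule_id)
  u <- d / r
  psi <- vec_angle(u, plane_normal(a))
  if (reference == "symmetric") {
    psi <- (psi + vec_angle(-u, plane_normal(b))) / 2
  }
  theta <- vec_angle(reference_vector(a), reference_vector(b))
  structure(list(r = r, theta = theta, psi = psi, polarity = "undefined",
                 pair_ids = c(a$molecule_id, b$molecule_id),
                 frame_index = as.integer(frame_index)),
            class = "dimer_geometry")
}

#' Classifier thresholds for stacked/coplanar conformers
#'
#' Defaults: stacked band halfwidth pi/6 (30 deg) around psi = 0 and pi with
#' r inside 3.0-5.5 A (around the ~4 A stacking spacing); coplanar band
#' halfwidth pi/9 (20 deg) around psi = pi/2 with a hydrogen-bond contact
#' below 2.5 A.
#'
#' @param psi_stack_halfwidth radians
#' @param psi_coplanar_halfwidth radians
#' @param r_stack_window length-2 numeric interval (A)
#' @param hbond_contact_max hydrogen...acceptor contact cutoff (A)
#' @return object of class `classifier_thresholds`
#' @export
classifier_thresholds <- function(psi_stack_halfwidth = pi / 6,
                                  psi_coplanar_halfwidth = pi / 9,
                                  r_stack_window = c(3.0, 5.5),
                                  hbond_contact_max = HBOND_CUTOFF) {
  if (psi_stack_halfwidth <= 0 || psi_coplanar_halfwidth <= 0)
    stop("band halfwidths must be positive")
  if (psi_stack_halfwidth + psi_coplanar_halfwidth >= pi / 2)
    stop("psi bands overlap: stack + coplanar halfwidths must be < pi/2")
  if (length(r_stack_window) != 2L || diff(r_stack_window) <= 0)
    stop("r_stack_window must be an increasing interval")
  structure(list(psi_stack_halfwidth = psi_stack_halfwidth,
                 psi_coplanar_halfwidth = psi_coplanar_halfwidth,
                 r_stack_window = r_stack_window,
                 hbond_contact_max = hbond_contact_max),
            class = "classifier_thresholds")
}

#' Classify a dimer as stacked, coplanar, or other
#'
#' Stacked: psi within the stack band of 0 or pi and r inside the stacking
#' window. Coplanar: psi within the coplanar band of pi/2 and a satisfied
#' hydrogen-bond contact. Everything else: other.
#'
#' @param g a [dimer_params()] result
#' @param t a [classifier_thresholds()]
#' @param hbond_ok logical, result of [hbond_contact()]
#' @return `"stacked"`, `"coplanar"`, or `"other"`
#' @export
classify_conformer <- function(g, t = classifier_thresholds(), hbond_ok) {
  stacked_psi <- g$psi <= t$psi_stack_halfwidth ||
    g$psi >= pi - t$psi_stack_halfwidth
  if (stacked_psi && g$r >= t$r_stack_window[1] && g$r <= t$r_stack_window[2])
    return("stacked")
  if (abs(g$psi - pi / 2) <= t$psi_coplanar_halfwidth && isTRUE(hbond_ok))
    return("coplanar")
  "other"
}

#' Stacking polarity of a stacked pair
#'
#' Parallel if the two intramolecular reference vectors have positive dot
#' product, antiparallel otherwise. An exactly zero dot product is broken
#' to antiparallel with a warning.
#'
#' @param a,b the two stacked molecules
#' @return `"parallel"` or `"antiparallel"`
#' @export
stacking_polarity <- function(a, b) {
  d <- sum(reference_vector(a) * reference_vector(b))
  if (d == 0) {
    warning("reference vectors exactly orthogonal; tie broken to antiparallel")
    return("antiparallel")
  }
  if (d > 0) "parallel" else "antiparallel"
}

#' Hydrogen-bond contact between two molecules
#'
#' TRUE iff any labeled hydrogen of one molecule lies within `cutoff` of any
#' acceptor heavy atom of the other, checked in both directions under the
#' minimum-image convention.
#'
#' @param a,b two [planar_molecule()]s exposing hydrogen/acceptor roles
#' @param cutoff contact cutoff (A), default 2.5
#' @param box orthorhombic box or `NULL`
#' @return logical
#' @export
hbond_contact <- function(a, b, cutoff = HBOND_CUTOFF, box = NULL) {
  one_way <- function(don, acc) {
    if (!length(don$spec$hydrogen_atoms) || !length(acc$spec$acceptor_atoms))
      return(Inf)
    min_cross_dist(atom_xyz(don, don$spec$hydrogen_atoms),
                   atom_xyz(acc, acc$spec$acceptor_atoms), box)
  }
  min(one_way(a, b), one_way(b, a)) <= cutoff
}
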