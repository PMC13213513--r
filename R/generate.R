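# Seeded synthetic ensemble generator.
#
# Emulates the statistical structure the dimer analysis assumes: bulk solute
# dimers dominated by ~4 A stacking (psi near 0/pi, mostly antiparallel),
# a minority coplanar hydrogen-bonded population (psi near pi/2, contact
# < 2.5 A), and - in templated ensembles - a modifier-proximal population
# whose coplanar fraction is a logistic function of templating strength,
# capped by the modifier's in-plane ring extent.
#
# Randomness: one integer master seed; each frame draws from a sub-stream
# seeded by a fixed offset of the master seed (see frame_seed()), so
# identical spec + seed reproduce ensembles exactly.

PAIR_EXCLUSION <- 17   # min distance between dimer placement centers (A)
BOX_MARGIN     <- 8    # placement margin from box faces (A)
OVERLAP_CUTOFF <- 1.5  # hard-sphere heavy-atom overlap cutoff (A)
FACE_Y_OFFSET  <- 2.5  # lateral offset of the two adsorption faces (A),
                       # keeps cross-face solute pairs outside the dimer
                       # enumeration radius

#' Specification of a synthetic ensemble
#'
#' @param n_frames number of frames
#' @param n_solutes solute molecules per frame (2 per dimer)
#' @param box orthorhombic edge lengths (A); scalar is recycled
#' @param coplanar_fraction_bulk probability a bulk dimer is coplanar
#' @param coplanar_fraction_near near-modifier coplanar probability; when
#'   `NULL` it is derived from `templating_strength` and the modifier extent
#' @param templating_strength dimensionless >= 0; mapped to
#'   `coplanar_fraction_near` via f_near = f_bulk + (f_max - f_bulk) s/(1+s)
#' @param stack_distance_mean,stack_distance_sd stacking distance (A)
#' @param hbond_contact_max hydrogen-bond contact cutoff shared with the
#'   classifier (A)
#' @param angular_noise_sd angular jitter sd (radians)
#' @param antiparallel_fraction probability a stacked pair is antiparallel
#' @param n_near_dimers templated dimers per frame (default 1 on the +z
#'   face; 2 uses both modifier faces)
#' @param seed integer master seed
#' @return object of class `ensemble_spec`
#' @export
ensemble_spec <- function(n_frames = 100L, n_solutes = 40L, box = 80,
                          coplanar_fraction_bulk = 0.3,
                          coplanar_fraction_near = NULL,
                          templating_strength = 0,
                          stack_distance_mean = 4.0,
                          stack_distance_sd = 0.3,
                          hbond_contact_max = HBOND_CUTOFF,
                          angular_noise_sd = 0.08,
                          antiparallel_fraction = 0.8,
                          n_near_dimers = 1L, seed = 1L) {
  if (length(box) == 1L) box <- rep(box, 3)
  fr <- c(coplanar_fraction_bulk, antiparallel_fraction,
          coplanar_fraction_near %||% 0)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (stack_distance_mean <= 0) stop("stack_distance_mean must be positive")
  if (stack_distance_sd < 0 || angular_noise_sd < 0)
    stop("noise standard deviations must be non-negative")
  if (templating_strength < 0) stop("templating_strength must be >= 0")
  if (!n_near_dimers %in% 1:2)
    stop("n_near_dimers must be 1 (default) or 2 (one per modifier face)")
  structure(list(n_frames = as.integer(n_frames),
                 n_solutes = as.integer(n_solutes), box = box,
                 coplanar_fraction_bulk = coplanar_fraction_bulk,
                 coplanar_fraction_near = coplanar_fraction_near,
                 templating_strength = templating_strength,
                 stack_distance_mean = stack_distance_mean,
                 stack_distance_sd = stack_distance_sd,
                 hbond_contact_max = hbond_contact_max,
                 angular_noise_sd = angular_noise_sd,
                 antiparallel_fraction = antiparallel_fraction,
                 n_near_dimers = as.integer(n_near_dimers),
                 seed = as.integer(seed)),
            class = "ensemble_spec")
}

# random small rotation of xyz about a fixed point (angle ~ N(0, sd), random
# axis); draws nothing when sd == 0 so noise-free limits are exact.
jitter_about <- function(xyz, point, sd) {
  if (sd <= 0) return(xyz)
  ang <- stats::rnorm(1, 0, sd)
  axis <- stats::rnorm(3)
  R <- rot_axis(axis, ang)
  out <- sweep(sweep(xyz, 2, point) %*% t(R), 2, point, "+")
  rownames(out) <- rownames(xyz)
  out
}

# Stacked pair in the local frame: member a is the unrotated template at the
# origin; member b is displaced along +/- z (tilted by the angular noise) at
# distance r, antiparallel (180 deg in-plane rotation) or parallel.
build_stacked_pair <- function(tpl, r, antiparallel, sign_up, noise_sd) {
  xa <- tpl$xyz
  xb <- if (antiparallel) tpl$xyz %*% t(rot_z(pi)) else tpl$xyz
  rownames(xb) <- rownames(tpl$xyz)
  w <- c(0, 0, sign_up)
  if (noise_sd > 0) {
    tilt <- stats::rnorm(1, 0, noise_sd)
    axis <- c(stats::rnorm(2), 0)
    w <- as.vector(rot_axis(axis, tilt) %*% w)
  }
  xb <- sweep(xb, 2, r * w, "+")
  xb <- jitter_about(xb, colMeans(xb[tpl$spec$ring_atoms, , drop = FALSE]),
                     noise_sd)
  list(a = xa, b = xb)
}

# Coplanar hydrogen-bonded pair in the local frame: head-on construction in
# which the chosen acceptor of a, the contact hydrogen of b, and both ring
# centroids are colinear, with H...acceptor distance exactly HBOND_TARGET.
# Angular jitter rotates a about its acceptor and b about its contact
# hydrogen, so the generated contact distance is preserved exactly and can
# never drift past the classifier cutoff.
build_coplanar_pair <- function(tpl, noise_sd, acceptor = NULL,
                                donor = NULL) {
  acc <- acceptor %||% sample(tpl$spec$acceptor_atoms, 1)
  don <- donor %||% sample(tpl$spec$hydrogen_atoms, 1)
  qa <- tpl$xyz[acc, ]
  qh <- tpl$xyz[don, ]
  az_a <- atan2(qa[2], qa[1])
  az_h <- atan2(qh[2], qh[1])
  rho <- az_a + pi - az_h
  u <- c(cos(az_a), sin(az_a), 0)
  t_len <- vnorm(qa[1:2]) + HBOND_TARGET + vnorm(qh[1:2])
  xb <- tpl$xyz %*% t(rot_z(rho))
  rownames(xb) <- rownames(tpl$xyz)
  xb <- sweep(xb, 2, t_len * u, "+")
  xa <- jitter_about(tpl$xyz, qa, noise_sd)
  xb <- jitter_about(xb, xb[don, ], noise_sd)
  list(a = xa, b = xb, acceptor = acc, donor = don)
}

# Rejection-sample n placement centers with mutual exclusion, inside the
# box margins, away from optional fixed exclusion points.
place_centers <- function(n, box, fixed = NULL, min_sep = PAIR_EXCLUSION,
                          margin = BOX_MARGIN, max_attempts = 20000L) {
  if (n == 0L) return(matrix(numeric(0), 0, 3))
  lo <- rep(margin, 3); hi <- box - margin
  if (any(hi <= lo))
    stop("placement error: box too small for the requested margin")
  centers <- matrix(NA_real_, n, 3)
  placed <- 0L
  for (attempt in seq_len(max_attempts)) {
    cand <- lo + stats::runif(3) * (hi - lo)
    ok <- TRUE
    if (placed > 0L) {
      d <- sqrt(colSums((t(centers[seq_len(placed), , drop = FALSE]) - cand)^2))
      if (any(d < min_sep)) ok <- FALSE
    }
    if (ok && !is.null(fixed) && nrow(fixed) > 0L) {
      d <- sqrt(colSums((t(fixed) - cand)^2))
      if (any(d < min_sep)) ok <- FALSE
    }
    if (ok) {
      placed <- placed + 1L
      centers[placed, ] <- cand
      if (placed == n) return(centers)
    }
  }
  stop("placement error: box too small to place ", n,
       " dimers without overlap")
}

# Bulk-style dimer: build in the local frame, apply a uniform random
# rotation to the whole pair (joint rigid motion leaves r/theta/psi
# untouched), translate the pair midpoint to `center`.
make_bulk_pair <- function(tpl, spec, center) {
  coplanar <- stats::runif(1) < spec$coplanar_fraction_bulk
  if (coplanar) {
    pr <- build_coplanar_pair(tpl, spec$angular_noise_sd)
  } else {
    r <- stats::rnorm(1, spec$stack_distance_mean, spec$stack_distance_sd)
    r <- max(r, 2.5)  # guard against unphysical negative draws
    pr <- build_stacked_pair(
      tpl, r, antiparallel = stats::runif(1) < spec$antiparallel_fraction,
      sign_up = if (stats::runif(1) < 0.5) 1 else -1,
      noise_sd = spec$angular_noise_sd)
  }
  R <- random_rotation()
  xa <- pr$a %*% t(R); xb <- pr$b %*% t(R)
  rownames(xa) <- rownames(pr$a); rownames(xb) <- rownames(pr$b)
  mid <- (colMeans(xa) + colMeans(xb)) / 2
  xa <- sweep(xa, 2, center - mid, "+")
  xb <- sweep(xb, 2, center - mid, "+")
  list(a = xa, b = xb, coplanar = coplanar)
}

#' Generate a bulk (modifier-free) synthetic ensemble
#'
#' Dimer pairs are stacked with probability `1 - coplanar_fraction_bulk`
#' (member separation along the plane normal, antiparallel with probability
#' `antiparallel_fraction`) and coplanar hydrogen-bonded otherwise; pairs
#' are placed non-overlapping with a wide mutual exclusion so enumerated
#' dimers coincide with generated dimers. An odd leftover solute is placed
#' uniformly, away from every pair.
#'
#' @param spec an [ensemble_spec()]
#' @return an [ensemble()]
#' @export
make_bulk_ensemble <- function(spec) {
  tpl <- solute_template()
  frames <- with_seed(spec$seed, lapply(seq_len(spec$n_frames), function(f) {
    set.seed(frame_seed(spec$seed, f - 1L))
    n_dim <- spec$n_solutes %/% 2L
    n_single <- spec$n_solutes %% 2L
    centers <- place_centers(n_dim + n_single, spec$box)
    mols <- vector("list", spec$n_solutes)
    for (i in seq_len(n_dim)) {
      pr <- make_bulk_pair(tpl, spec, centers[i, ])
      mols[[2L * i - 1L]] <- planar_molecule(2L * i - 1L, tpl$spec, pr$a)
      mols[[2L * i]] <- planar_molecule(2L * i, tpl$spec, pr$b)
    }
    if (n_single) {
      R <- random_rotation()
      xs <- tpl$xyz %*% t(R)
      rownames(xs) <- rownames(tpl$xyz)
      xs <- sweep(xs, 2, centers[n_dim + 1L, ], "+")
      mols[[spec$n_solutes]] <- planar_molecule(spec$n_solutes, tpl$spec, xs)
    }
    md_frame(mols, box = spec$box, frame_index = f - 1L)
  }))
  ensemble(frames, metadata = list(generator = "make_bulk_ensemble",
                                   spec = unclass(spec)))
}

#' Achievable near-modifier coplanar fraction
#'
#' Logistic map of templating strength, saturating at the extent cap
#' f_max = modifier in-plane ring extent / (2 x solute footprint), clamped
#' to \[0, 1\]: a modifier too small to host two solute footprints side by
#' side cannot template coplanar pairs at full efficiency.
#'
#' @param spec an [ensemble_spec()]
#' @param modifier a [modifier_template()]
#' @return probability in \[0, 1\]
#' @export
near_coplanar_fraction <- function(spec, modifier) {
  if (!is.null(spec$coplanar_fraction_near))
    return(spec$coplanar_fraction_near)
  f_max <- min(1, max(0, modifier$extent / (2 * solute_footprint())))
  s <- spec$templating_strength
  f <- spec$coplanar_fraction_bulk +
    (f_max - spec$coplanar_fraction_bulk) * s / (1 + s)
  min(1, max(0, f))
}

#' Generate a modifier-templated synthetic ensemble
#'
#' One modifier sits at the box center in the z = 0 plane and hosts one
#' near dimer per occupied face (default: the +z face): an adsorbed member
#' at |z| ~ 3.3 A over an adsorption anchor (anchors cycle
#' deterministically over the extreme ring centers of the row), with its
#' partner coplanar hydrogen-bonded in the adsorption plane with
#' probability [near_coplanar_fraction()] or stacked outward along the
#' face normal otherwise. Far dimers follow the bulk construction,
#' excluded from the modifier neighborhood.
#'
#' @param spec an [ensemble_spec()]
#' @param modifier a [modifier_template()]
#' @return an [ensemble()]; metadata records the achieved
#'   `coplanar_fraction_near`
#' @export
make_templated_ensemble <- function(spec, modifier = modifier_template()) {
  tpl <- solute_template()
  f_near <- near_coplanar_fraction(spec, modifier)
  center <- spec$box / 2
  n_near <- spec$n_near_dimers
  n_far <- (spec$n_solutes - 2L * n_near) %/% 2L
  if (n_far < 0L) stop("n_solutes too small for n_near_dimers")
  anchors <- modifier$anchors
  faces <- c(1, -1)[seq_len(n_near)]
  frames <- with_seed(spec$seed, lapply(seq_len(spec$n_frames), function(f) {
    set.seed(frame_seed(spec$seed, f - 1L))
    mols <- list(instantiate(modifier, 1L, t = center))
    next_id <- 2L
    for (j in seq_along(faces)) {
      face <- faces[j]
      anchor <- anchors[((f - 1L + j - 1L) %% length(anchors)) + 1L]
      y_off <- if (length(faces) > 1L) face * FACE_Y_OFFSET else 0
      a_pos <- center + c(anchor, y_off, face * ADSORPTION_GAP)
      coplanar <- stats::runif(1) < f_near
      if (coplanar) {
        pr <- build_coplanar_pair(tpl, spec$angular_noise_sd)
        xa <- sweep(pr$a, 2, a_pos, "+")
        xb <- sweep(pr$b, 2, a_pos, "+")
      } else {
        r <- max(stats::rnorm(1, spec$stack_distance_mean,
                              spec$stack_distance_sd), 2.5)
        pr <- build_stacked_pair(
          tpl, r, antiparallel = stats::runif(1) < spec$antiparallel_fraction,
          sign_up = face, noise_sd = spec$angular_noise_sd)
        xa <- sweep(pr$a, 2, a_pos, "+")
        xb <- sweep(pr$b, 2, a_pos, "+")
      }
      # random id order: the psi convention references the lower-id member,
      # so this balances near stacked pairs between psi ~ 0 and psi ~ pi,
      # mirroring the random stacking sign of bulk pairs
      if (stats::runif(1) < 0.5) { tmp <- xa; xa <- xb; xb <- tmp }
      mols[[length(mols) + 1L]] <- planar_molecule(next_id, tpl$spec, xa)
      mols[[length(mols) + 1L]] <- planar_molecule(next_id + 1L, tpl$spec, xb)
      next_id <- next_id + 2L
    }
    if (n_far > 0L) {
      centers <- place_centers(n_far, spec$box,
                               fixed = matrix(center, 1, 3),
                               min_sep = PAIR_EXCLUSION)
      for (i in seq_len(n_far)) {
        pr <- make_bulk_pair(tpl, spec, centers[i, ])
        mols[[length(mols) + 1L]] <- planar_molecule(next_id, tpl$spec, pr$a)
        mols[[length(mols) + 1L]] <- planar_molecule(next_id + 1L, tpl$spec,
                                                     pr$b)
        next_id <- next_id + 2L
      }
    }
    md_frame(mols, box = spec$box, frame_index = f - 1L)
  }))
  ensemble(frames, metadata = list(
    generator = "make_templated_ensemble", spec = unclass(spec),
    modifier_size = modifier$size, modifier_extent = modifier$extent,
    coplanar_fraction_near = f_near))
}

#' Default idealized crystal lattice motif
#'
#' Parallel stacking along z at `stack_spacing` and head-on hydrogen-bonded
#' coplanar neighbors along x and y at the shared generator spacing
#' ([coplanar_spacing()]), so lattice fingerprints and generated coplanar
#' dimers live at identical geometry by construction.
#'
#' @param stack_spacing stacking distance (A)
#' @return motif list (`stack_spacing`, `coplanar_offsets`)
#' @export
crystal_motif <- function(stack_spacing = 4.0) {
  s <- coplanar_spacing()
  list(stack_spacing = stack_spacing,
       coplanar_offsets = list(list(offset = c(s, 0), rotation = 0),
                               list(offset = c(0, s), rotation = 0)))
}

#' Build an idealized crystal lattice frame
#'
#' A periodic arrangement of solute template copies: parallel stacking
#' (aligned reference vectors) along z and coplanar hydrogen-bonded
#' neighbors within each plane at the motif offsets. Molecule ids run
#' fastest along the stacking axis.
#'
#' @param n_cells integer vector (nx, ny, nz), each >= 1
#' @param motif a [crystal_motif()]-style list; each coplanar offset may
#'   carry a `rotation` (radians) applied cumulatively along that axis
#' @return an [md_frame()] (non-periodic cluster)
#' @export
make_crystal_lattice <- function(n_cells = c(2, 2, 2),
                                 motif = crystal_motif()) {
  n_cells <- as.integer(n_cells)
  if (length(n_cells) != 3L || any(n_cells < 1L))
    stop("n_cells must be 3 integers >= 1")
  tpl <- solute_template()
  off <- motif$coplanar_offsets
  if (length(off) != 2L) stop("motif needs two in-plane coplanar offsets")
  a1 <- c(off[[1]]$offset, 0); a2 <- c(off[[2]]$offset, 0)
  a3 <- c(0, 0, motif$stack_spacing)
  mols <- list(); id <- 0L
  for (i in seq_len(n_cells[1]) - 1L)
    for (j in seq_len(n_cells[2]) - 1L)
      for (k in seq_len(n_cells[3]) - 1L) {
        id <- id + 1L
        rot <- i * (off[[1]]$rotation %||% 0) + j * (off[[2]]$rotation %||% 0)
        xyz <- tpl$xyz %*% t(rot_z(rot))
        rownames(xyz) <- rownames(tpl$xyz)
        xyz <- sweep(xyz, 2, i * a1 + j * a2 + k * a3, "+")
        mols[[id]] <- planar_molecule(id, tpl$spec, xyz)
      }
  # overlap check between distinct molecules
  if (length(mols) > 1L) {
    cents <- t(vapply(mols, ring_centroid, numeric(3)))
    for (p in seq_len(length(mols) - 1L))
      for (q in (p + 1L):length(mols)) {
        if (vnorm(cents[p, ] - cents[q, ]) > 12) next
        if (min_cross_dist(heavy_xyz(mols[[p]]), heavy_xyz(mols[[q]])) <
              OVERLAP_CUTOFF)
          stop("construction error: motif offsets place molecules ", p,
               " and ", q, " in overlap")
      }
  }
  md_frame(mols, box = NULL, frame_index = 0L)
}
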