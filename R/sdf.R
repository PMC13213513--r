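# Modifier-aligned spatial distribution function (SDF) occupancy grids and
# isosurface component analysis.

#' Rigidly align every frame onto the first frame's modifier
#'
#' Each frame is transformed with the proper-rotation least-squares
#' (Kabsch) fit of its modifier ring atoms onto those of frame 0; the fit
#' never uses reflections. Per-frame post-alignment ring RMSDs are attached
#' as attribute `"rmsd"`. Alignment is a joint rigid motion per frame, so
#' all intra-frame distances are preserved; the box is dropped from aligned
#' frames (a rotated orthorhombic box is no longer axis-aligned).
#'
#' @param ens an [ensemble()] with one modifier per frame
#' @return aligned [ensemble()] with attribute `rmsd`
#' @export
align_frames <- function(ens) {
  ref_mod <- frame_modifier(ens$frames[[1]])
  if (is.null(ref_mod)) stop("alignment requires a modifier in every frame")
  ref <- ring_xyz(ref_mod)
  ref_cen <- colMeans(ref)
  ref0 <- sweep(ref, 2, ref_cen)
  rmsd <- numeric(n_frames(ens))
  frames <- lapply(seq_len(n_frames(ens)), function(fi) {
    fr <- ens$frames[[fi]]
    mod <- frame_modifier(fr)
    if (is.null(mod)) stop("frame ", fr$frame_index, " has no modifier")
    mob <- ring_xyz(mod)
    mob_cen <- colMeans(mob)
    mob0 <- sweep(mob, 2, mob_cen)
    sv <- svd(t(mob0) %*% ref0)
    d <- sign(det(sv$v %*% t(sv$u)))
    D <- diag(c(1, 1, d))
    R <- sv$v %*% D %*% t(sv$u)   # optimal proper rotation, mob -> ref
    t_vec <- ref_cen - as.vector(R %*% mob_cen)
    fr2 <- transform_frame(fr, R, t_vec)
    fr2$box <- NULL
    fit <- sweep(mob0 %*% t(R), 2, ref_cen, "+")
    rmsd[fi] <<- sqrt(mean(rowSums((fit - ref)^2)))
    fr2
  })
  out <- ensemble(frames, metadata = c(ens$metadata, list(aligned = TRUE)))
  attr(out, "rmsd") <- rmsd
  out
}

#' Construct an SDF occupancy grid container
#'
#' @param origin corner of voxel (1,1,1) (A)
#' @param spacing voxel edge length (A)
#' @param dims integer voxel counts (nx, ny, nz)
#' @param occupancy numeric array `dims` of per-voxel values in \[0, 1\]
#' @param reference optional aligned modifier coordinates
#' @return object of class `sdf_grid`
#' @export
sdf_grid <- function(origin, spacing, dims, occupancy, reference = NULL) {
  dims <- as.integer(dims)
  if (spacing <= 0) stop("spacing must be positive")
  if (length(occupancy) != prod(dims))
    stop("occupancy length does not match grid dims")
  occupancy <- array(occupancy, dims)
  if (any(occupancy < -1e-9 | occupancy > 1 + 1e-9))
    stop("occupancy values must lie in [0, 1]")
  structure(list(origin = origin, spacing = spacing, dims = dims,
                 occupancy = occupancy, reference = reference),
            class = "sdf_grid")
}

#' Spatial distribution function of solute heavy atoms around the modifier
#'
#' Voxel occupancy = fraction of frames in which at least one solute heavy
#' atom falls inside the voxel. The cubic grid is centered on the (aligned)
#' modifier ring centroid of the first frame with half-width `radius`.
#'
#' @param aligned an aligned [ensemble()] (see [align_frames()])
#' @param spacing voxel edge (A), default 0.5
#' @param radius grid half-width (A), default 12
#' @return an [sdf_grid()]
#' @export
sdf <- function(aligned, spacing = 0.5, radius = 12) {
  if (spacing <= 0) stop("spacing must be positive")
  mod <- frame_modifier(aligned$frames[[1]])
  if (is.null(mod)) stop("SDF requires a modifier")
  center <- ring_centroid(mod)
  n_side <- as.integer(2L * ceiling(radius / spacing))
  dims <- rep(n_side, 3L)
  origin <- center - n_side / 2 * spacing
  counts <- array(0L, dims)
  nf <- n_frames(aligned)
  for (fi in seq_len(nf)) {
    fr <- aligned$frames[[fi]]
    at <- do.call(rbind, lapply(frame_solutes(fr), heavy_xyz))
    if (is.null(at) || !nrow(at)) next
    idx <- floor(sweep(at, 2, origin) / spacing) + 1L
    keep <- idx[, 1] >= 1L & idx[, 1] <= dims[1] &
      idx[, 2] >= 1L & idx[, 2] <= dims[2] &
      idx[, 3] >= 1L & idx[, 3] <= dims[3]
    if (!any(keep)) next
    idx <- idx[keep, , drop = FALSE]
    lin <- unique((idx[, 3] - 1L) * dims[1] * dims[2] +
                    (idx[, 2] - 1L) * dims[1] + idx[, 1])
    counts[lin] <- counts[lin] + 1L
  }
  sdf_grid(origin, spacing, dims, counts / nf,
           reference = mod$xyz)
}

# voxel centers for a set of linear indices
.voxel_centers <- function(grid, lin) {
  d <- grid$dims
  k <- (lin - 1L) %/% (d[1] * d[2])
  rem <- (lin - 1L) %% (d[1] * d[2])
  j <- rem %/% d[1]
  i <- rem %% d[1]
  cbind(grid$origin[1] + (i + 0.5) * grid$spacing,
        grid$origin[2] + (j + 0.5) * grid$spacing,
        grid$origin[3] + (k + 0.5) * grid$spacing)
}

#' Connected components of an occupancy isosurface
#'
#' 26-connected components of voxels with occupancy >= `level`. The
#' in-plane extent of each component (and of the union of all components,
#' attribute `"union_extent_inplane"`) is the largest bounding spread of
#' voxel centers projected onto the modifier ring plane - the quantity that
#' makes "can host two solute footprints side by side" checkable.
#'
#' @param grid an [sdf_grid()]
#' @param level occupancy threshold in (0, 1)
#' @return data.frame (possibly empty) with one row per component:
#'   `voxels`, `volume` (A^3), `extent` (3D bounding diagonal, A),
#'   `extent_inplane` (A); sorted by size, descending
#' @export
isosurface_components <- function(grid, level = 0.4) {
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  lin <- which(grid$occupancy >= level)
  empty <- data.frame(voxels = integer(), volume = numeric(),
                      extent = numeric(), extent_inplane = numeric())
  attr(empty, "union_extent_inplane") <- 0
  if (!length(lin)) return(empty)
  d <- grid$dims
  k <- (lin - 1L) %/% (d[1] * d[2])
  rem <- (lin - 1L) %% (d[1] * d[2])
  j <- rem %/% d[1]
  i <- rem %% d[1]
  key <- function(ii, jj, kk) kk * d[1] * d[2] + jj * d[1] + ii
  keys <- key(i, j, k)
  edges <- NULL
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    if (di < 0 || (di == 0 && dj < 0) || (di == 0 && dj == 0 && dk < 0))
      next  # each unordered neighbor pair once
    ni <- i + di; nj <- j + dj; nk <- k + dk
    ok <- ni >= 0L & ni < d[1] & nj >= 0L & nj < d[2] & nk >= 0L & nk < d[3]
    m <- match(key(ni, nj, nk)[ok], keys)
    src <- which(ok)[!is.na(m)]
    if (length(src))
      edges <- rbind(edges, cbind(src, m[!is.na(m)]))
  }
  g <- igraph::make_empty_graph(n = length(lin), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  # in-plane basis from the modifier reference plane (z plane fallback)
  if (!is.null(grid$reference)) {
    ref <- grid$reference[element_from_name(rownames(grid$reference)) != "H",
                          , drop = FALSE]
    cen <- sweep(ref, 2, colMeans(ref))
    sv <- svd(cen)
    e1 <- sv$v[, 1]; e2 <- sv$v[, 2]
  } else {
    e1 <- c(1, 0, 0); e2 <- c(0, 1, 0)
  }
  pos <- .voxel_centers(grid, lin)
  p1 <- pos %*% e1; p2 <- pos %*% e2
  stats_one <- function(sel) {
    ext3 <- sqrt(sum((apply(pos[sel, , drop = FALSE], 2, function(x)
      diff(range(x)) + grid$spacing))^2))
    extp <- sqrt((diff(range(p1[sel])) + grid$spacing)^2 +
                   (diff(range(p2[sel])) + grid$spacing)^2)
    c(ext3, extp)
  }
  ids <- sort(unique(comp))
  res <- t(vapply(ids, function(cid) {
    sel <- comp == cid
    c(sum(sel), stats_one(sel))
  }, numeric(3)))
  out <- data.frame(voxels = as.integer(res[, 1]),
                    volume = res[, 1] * grid$spacing^3,
                    extent = res[, 2], extent_inplane = res[, 3])
  out <- out[order(-out$voxels), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "union_extent_inplane") <- stats_one(rep(TRUE, length(lin)))[2]
  out
}
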