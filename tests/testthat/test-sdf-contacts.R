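# Alignment, SDF occupancy grids, isosurface components, contact analysis.

test_that("alignment exactly undoes rigid motions and preserves distances", {
  ens <- sdf_fixture(2)
  sub <- ensemble(ens$frames[1:10], metadata = ens$metadata)
  # apply a distinct random rigid motion to every frame except the first,
  # so realignment must recover the original coordinates exactly
  set.seed(123)
  moved <- ensemble(lapply(seq_along(sub$frames), function(i) {
    if (i == 1) return(sub$frames[[i]])
    preorg:::transform_frame(sub$frames[[i]], random_rot_test(),
                             stats::runif(3, -30, 30))
  }))
  al <- align_frames(moved)
  expect_lt(max(attr(al, "rmsd")), 1e-9)
  # modifier-solute distances are invariant under alignment
  d_orig <- preorg:::min_cross_dist(
    heavy_xyz(frame_modifier(sub$frames[[7]])),
    heavy_xyz(frame_solutes(sub$frames[[7]])[[1]]))
  d_al <- preorg:::min_cross_dist(
    heavy_xyz(frame_modifier(al$frames[[7]])),
    heavy_xyz(frame_solutes(al$frames[[7]])[[1]]))
  expect_lt(abs(d_orig - d_al), 1e-9)
  # aligned coordinates coincide with the originals (box-free)
  expect_lt(max(abs(al$frames[[7]]$molecules[[2]]$xyz -
                      sub$frames[[7]]$molecules[[2]]$xyz)), 1e-9)
  # self-alignment of frame 0 is the identity
  al0 <- align_frames(sub)
  expect_lt(max(abs(al0$frames[[1]]$molecules[[1]]$xyz -
                      sub$frames[[1]]$molecules[[1]]$xyz)), 1e-12)
})

test_that("a solute fixed inside one voxel gives a single occupancy-1 voxel", {
  mod <- preorg:::instantiate(modifier_template(1), 1L)
  # coarse grid (6 A voxels) so the whole fixed solute sits in one voxel,
  # centered at a voxel center of the grid around the modifier
  frames <- lapply(0:9, function(f)
    md_frame(list(mod, make_solute(2, t = c(9, 9, 9))), frame_index = f))
  g <- sdf(ensemble(frames), spacing = 6, radius = 12)
  expect_equal(sum(g$occupancy == 1), 1L)
  expect_equal(sum(g$occupancy > 0), 1L)
})

test_that("SDF occupancy equals the brute-force per-frame membership count", {
  ens <- sdf_fixture(2)
  sub <- ensemble(ens$frames[1:20], metadata = ens$metadata)
  g <- sdf(sub, spacing = 1.5, radius = 6)
  brute <- array(0, g$dims)
  for (fr in sub$frames) {
    at <- do.call(rbind, lapply(frame_solutes(fr), heavy_xyz))
    seen <- array(FALSE, g$dims)
    for (row in seq_len(nrow(at))) {
      p <- at[row, ]
      idx <- integer(3)
      inside <- TRUE
      for (k in 1:3) {
        lo <- g$origin[k]
        # independent interval search over voxel boundaries
        hit <- which(p[k] >= lo + (0:(g$dims[k] - 1)) * g$spacing &
                       p[k] < lo + (1:g$dims[k]) * g$spacing)
        if (!length(hit)) { inside <- FALSE; break }
        idx[k] <- hit
      }
      if (inside) seen[idx[1], idx[2], idx[3]] <- TRUE
    }
    brute <- brute + seen
  }
  expect_equal(g$occupancy, brute / 20, tolerance = 1e-12)
  expect_true(all(g$occupancy >= 0 & g$occupancy <= 1))
})

test_that("an empty neighborhood gives an all-zero grid", {
  mod <- preorg:::instantiate(modifier_template(1), 1L)
  far <- make_solute(2, t = c(40, 0, 0))
  ens <- ensemble(list(md_frame(list(mod, far))))
  g <- sdf(ens, spacing = 1, radius = 8)
  expect_true(all(g$occupancy == 0))
  expect_error(sdf(ens, spacing = 0), "positive")
})

test_that("isosurface components follow 26-connectivity", {
  occ <- array(0, c(6, 6, 6))
  occ[2, 2, 2] <- 0.9
  g <- sdf_grid(c(0, 0, 0), 0.5, c(6, 6, 6), occ)
  comps <- isosurface_components(g, 0.4)
  expect_equal(nrow(comps), 1)
  expect_equal(comps$voxels, 1L)
  expect_equal(comps$volume, 0.5^3)
  # corner-sharing voxels merge under 26-connectivity
  occ[3, 3, 3] <- 0.9
  comps2 <- isosurface_components(sdf_grid(c(0, 0, 0), 0.5, c(6, 6, 6), occ),
                                  0.4)
  expect_equal(nrow(comps2), 1)
  expect_equal(comps2$voxels, 2L)
  # separated voxels stay distinct components
  occ[6, 6, 6] <- 0.9
  comps3 <- isosurface_components(sdf_grid(c(0, 0, 0), 0.5, c(6, 6, 6), occ),
                                  0.4)
  expect_equal(nrow(comps3), 2)
  expect_error(isosurface_components(g, 0), "level")
})

test_that("the larger modifier templates a wider isosurface region", {
  ext <- vapply(c(1, 3), function(size) {
    g <- sdf(align_frames(sdf_fixture(size)), spacing = 1.0, radius = 12)
    comps <- isosurface_components(g, 0.4)
    expect_gt(nrow(comps), 0)
    attr(comps, "union_extent_inplane")
  }, numeric(1))
  expect_gt(ext[2], ext[1])
})

test_that("contact frequencies match a brute-force distance scan", {
  ens <- sdf_fixture(2)
  sub <- ensemble(ens$frames[1:20], metadata = ens$metadata)
  tab <- contact_frequency(sub, r_cut = 2.5)
  mod <- frame_modifier(sub$frames[[1]])
  hyd <- mod$spec$hydrogen_atoms
  acc <- frame_solutes(sub$frames[[1]])[[1]]$spec$acceptor_atoms
  brute <- matrix(0, length(hyd), length(acc), dimnames = list(hyd, acc))
  for (fr in sub$frames) {
    m <- frame_modifier(fr)
    for (h in hyd) for (a in acc) {
      dmin <- Inf
      for (s in frame_solutes(fr)) {
        hx <- atom_xyz(m, h); ax <- atom_xyz(s, a)
        dmin <- min(dmin, sqrt(sum((hx - ax)^2)))
      }
      if (dmin <= 2.5) brute[h, a] <- brute[h, a] + 1
    }
  }
  expect_equal(tab, brute / 20, tolerance = 1e-12)
  expect_true(all(tab >= 0 & tab <= 1))
  # monotone in r_cut
  tab_wide <- contact_frequency(sub, r_cut = 4.0)
  expect_true(all(tab_wide >= tab))
})

test_that("constructed contacts give frequency 1 and distant solutes 0", {
  mod <- preorg:::instantiate(modifier_template(2), 1L)
  h13 <- atom_xyz(mod, "H13")[1, ]
  # put a solute with its O2 exactly 2.4 A from H13 in every frame
  tpl <- solute_template()
  shift <- h13 + c(0, 0, 2.4) - tpl$xyz["O2", ]
  frames <- lapply(0:4, function(f)
    md_frame(list(mod, make_solute(2, t = shift)), frame_index = f))
  tab <- contact_frequency(ensemble(frames))
  expect_equal(unname(tab["H13", "O2"]), 1.0)
  far <- lapply(0:4, function(f)
    md_frame(list(mod, make_solute(2, t = c(25, 0, 0))), frame_index = f))
  expect_true(all(contact_frequency(ensemble(far)) == 0))
})

test_that("conditional H13 split partitions the near dimers", {
  ens <- sdf_fixture(3)
  pops <- select_populations(ens)
  spl <- conditional_dimer_split(ens, pops$near, "H13", r_cut = 2.5)
  expect_equal(nrow(spl$contacting) + nrow(spl$noncontacting),
               nrow(pops$near))
  expect_gt(nrow(spl$contacting), 0)
  expect_gt(nrow(spl$noncontacting), 0)
  # contacting dimers really do touch H13
  fr <- ens$frames[[spl$contacting$frame[1] + 1]]
  h13 <- atom_xyz(frame_modifier(fr), "H13")
  ids <- c(spl$contacting$id_a[1], spl$contacting$id_b[1])
  dmin <- min(vapply(ids, function(id) {
    mol <- Find(function(m) m$molecule_id == id, fr$molecules)
    preorg:::min_cross_dist(h13, atom_xyz(mol, mol$spec$acceptor_atoms))
  }, numeric(1)))
  expect_lte(dmin, 2.5)
  expect_error(conditional_dimer_split(ens, pops$near, "H99"),
               "unknown modifier hydrogen")
})

test_that("hydrogen-bond mode timelines count transitions exactly", {
  mod <- preorg:::instantiate(modifier_template(1), 1L)
  a_fix <- make_solute(2, t = c(0, 0, 20))
  near_b <- make_solute(3, t = c(0, 0, 20) + c(6.7, 0, 0))
  far_b <- make_solute(3, t = c(0, 0, 20) + c(0, 0, 30))
  mk <- function(b, f) md_frame(list(mod, a_fix, b), frame_index = f,
                                box = c(90, 90, 90))
  # static geometry: zero transitions
  static <- ensemble(lapply(0:9, function(f) mk(near_b, f)))
  tl <- hbond_mode_timeline(static, c(2, 3))
  expect_equal(tl$transitions, 0)
  expect_equal(length(unique(tl$labels)), 1)
  # alternating A/B geometry over 10 frames: 9 transitions
  alt <- ensemble(lapply(0:9, function(f)
    mk(if (f %% 2 == 0) near_b else far_b, f)))
  tl2 <- hbond_mode_timeline(alt, c(2, 3))
  expect_equal(tl2$transitions, 9)
  expect_true("none" %in% tl2$labels)
  # switch every k frames: floor((n-1)/k) boundary crossings
  k <- 3; n <- 12
  sched <- ensemble(lapply(0:(n - 1), function(f)
    mk(if ((f %/% k) %% 2 == 0) near_b else far_b, f)))
  expect_equal(hbond_mode_timeline(sched, c(2, 3))$transitions,
               floor((n - 1) / k))
  expect_error(hbond_mode_timeline(static, c(2, 9)), "absent")
})
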