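# Dimer order parameters: exact constructions, oracles, invariances.

test_that("plane normal is exact for flat rings and robust to small noise", {
  m <- make_solute(1)
  n <- plane_normal(m)
  expect_equal(abs(sum(n * c(0, 0, 1))), 1, tolerance = 1e-12)
  # out-of-plane Gaussian noise, sd 0.01 A: compare against an independent
  # edge-cross-product estimate of the ring normal
  set.seed(42)
  tpl <- solute_template()
  xyz <- tpl$xyz
  xyz[, 3] <- xyz[, 3] + stats::rnorm(nrow(xyz), 0, 0.01)
  noisy <- planar_molecule(1, tpl$spec, xyz)
  n2 <- plane_normal(noisy)
  expect_gt(abs(sum(n2 * c(0, 0, 1))), 0.999)
  ring <- xyz[tpl$spec$ring_atoms, ]
  cen <- sweep(ring, 2, colMeans(ring))
  acc <- c(0, 0, 0)
  for (i in seq_len(nrow(cen))) {
    j <- if (i == nrow(cen)) 1L else i + 1L
    cr <- c(cen[i, 2] * cen[j, 3] - cen[i, 3] * cen[j, 2],
            cen[i, 3] * cen[j, 1] - cen[i, 1] * cen[j, 3],
            cen[i, 1] * cen[j, 2] - cen[i, 2] * cen[j, 1])
    acc <- acc + cr
  }
  acc <- acc / sqrt(sum(acc^2))
  expect_gt(abs(sum(n2 * acc)), 0.9999)
  # collinear ring atoms are a degenerate geometry
  line <- cbind(1:4, 0, 0)
  rownames(line) <- c("A", "B", "C", "D")
  spec_line <- molecule_spec("line", "solute", c("A", "B", "C"), c("A", "D"))
  expect_error(plane_normal(planar_molecule(9, spec_line, line)),
               "collinear")
})

test_that("pure constructions give exact (r, theta, psi)", {
  a <- make_solute(1)
  n <- plane_normal(a)
  # pure stack along the normal
  b <- make_solute(2, t = 4 * n)
  g <- dimer_params(a, b)
  expect_equal(g$r, 4, tolerance = 1e-12)
  expect_true(min(g$psi, pi - g$psi) < 1e-9)
  expect_lt(g$theta, 1e-6)
  # pure in-plane translation
  b2 <- make_solute(2, t = c(6, 0, 0))
  g2 <- dimer_params(a, b2)
  expect_equal(g2$psi, pi / 2, tolerance = 1e-9)
  expect_equal(g2$r, 6, tolerance = 1e-12)
  # 180 degree in-plane rotation then in-plane translation: antiparallel
  b3 <- make_solute(2, R = rot_z_test(pi), t = c(0, 6.5, 0))
  g3 <- dimer_params(a, b3)
  expect_equal(g3$theta, pi, tolerance = 1e-6)
  expect_equal(g3$psi, pi / 2, tolerance = 1e-9)
  # coincident centroids are rejected
  expect_error(dimer_params(a, make_solute(2)), "coincident")
})

test_that("dimer parameters agree with direct vector arithmetic", {
  # oracle: molecules are rigid template copies, so the reference vector and
  # plane normal are known analytically from the placement rotation
  tpl <- solute_template()
  u0 <- (tpl$xyz["C5", ] - tpl$xyz["C1", ])
  u0 <- u0 / sqrt(sum(u0^2))
  n0 <- c(0, 0, -1)  # template normal under the package sign convention
  set.seed(31)
  for (k in 1:100) {
    Ra <- random_rot_test(); Rb <- random_rot_test()
    ta <- stats::runif(3, -10, 10); tb <- ta + stats::runif(3, -6, 6)
    a <- make_solute(1, Ra, ta); b <- make_solute(2, Rb, tb)
    g <- dimer_params(a, b)
    d <- tb - ta
    r_o <- sqrt(sum(d^2))
    psi_o <- acos(max(-1, min(1, sum(d / r_o * (Ra %*% n0)))))
    theta_o <- acos(max(-1, min(1, sum((Ra %*% u0) * (Rb %*% u0)))))
    expect_equal(g$r, r_o, tolerance = 1e-10)
    expect_equal(g$psi, psi_o, tolerance = 1e-10)
    expect_equal(g$theta, theta_o, tolerance = 1e-10)
  }
})

test_that("joint rigid motions leave (r, theta, psi) unchanged", {
  set.seed(13)
  a <- make_solute(1, random_rot_test(), c(1, 2, 3))
  b <- make_solute(2, random_rot_test(), c(4, 1, 2))
  g0 <- dimer_params(a, b)
  for (k in 1:20) {
    R <- random_rot_test(); t <- stats::runif(3, -20, 20)
    move <- function(m) {
      xyz <- sweep(m$xyz %*% t(R), 2, t, "+")
      rownames(xyz) <- rownames(m$xyz)
      planar_molecule(m$molecule_id, m$spec, xyz)
    }
    g <- dimer_params(move(a), move(b))
    expect_lt(abs(g$r - g0$r), 1e-9)
    expect_lt(abs(g$theta - g0$theta), 1e-9)
    expect_lt(abs(g$psi - g0$psi), 1e-9)
  }
})

test_that("swap consistency: r and theta symmetric, psi follows the normal", {
  set.seed(5)
  a <- make_solute(1, random_rot_test(), c(0, 0, 0))
  b <- make_solute(2, random_rot_test(), c(3, 2, 4))
  g_ab <- dimer_params(a, b, reference = "first")
  g_ba <- dimer_params(b, a, reference = "first")
  expect_equal(g_ab$r, g_ba$r, tolerance = 1e-12)
  expect_equal(g_ab$theta, g_ba$theta, tolerance = 1e-12)
  # lower-id convention is invariant under argument order
  expect_equal(dimer_params(a, b)$psi, dimer_params(b, a)$psi)
  # the swapped psi equals the angle computed from b's normal and the b->a
  # separation
  d <- ring_centroid(a) - ring_centroid(b)
  u <- d / sqrt(sum(d^2))
  psi_b <- acos(max(-1, min(1, sum(u * plane_normal(b)))))
  expect_equal(g_ba$psi, psi_b, tolerance = 1e-12)
})

test_that("conformer classification follows the band definitions", {
  t <- classifier_thresholds()
  g <- function(psi, r) structure(list(r = r, theta = 0, psi = psi),
                                  class = "dimer_geometry")
  expect_equal(classify_conformer(g(0.05, 4.0), t, FALSE), "stacked")
  expect_equal(classify_conformer(g(pi - 0.05, 4.0), t, FALSE), "stacked")
  expect_equal(classify_conformer(g(pi / 2, 6.7), t, TRUE), "coplanar")
  expect_equal(classify_conformer(g(pi / 2, 6.7), t, FALSE), "other")
  expect_equal(classify_conformer(g(pi / 4, 4.0), t, TRUE), "other")
  expect_equal(classify_conformer(g(0.05, 7.5), t, FALSE), "other")
  # non-overlapping bands are enforced
  expect_error(classifier_thresholds(psi_stack_halfwidth = 1.2,
                                     psi_coplanar_halfwidth = 0.5),
               "overlap")
})

test_that("stacking polarity distinguishes parallel from antiparallel", {
  a <- make_solute(1)
  expect_equal(stacking_polarity(a, make_solute(2, t = c(0, 0, 4))),
               "parallel")
  expect_equal(stacking_polarity(a, make_solute(2, R = rot_z_test(pi),
                                                t = c(0, 0, 4))),
               "antiparallel")
  # exactly orthogonal reference vectors: tie broken to antiparallel
  sq <- molecule_spec("sq", "solute", c("A", "B", "C", "D"), c("A", "B"))
  xy1 <- rbind(A = c(0, 0, 0), B = c(1, 0, 0), C = c(1, 1, 0),
               D = c(0, 1, 0))
  xy2 <- xy1[c("A", "D", "B", "C"), ]  # reference vector along +y
  rownames(xy2) <- c("A", "B", "C", "D")
  m1 <- planar_molecule(1, sq, xy1)
  m2 <- planar_molecule(2, sq, sweep(xy2, 2, c(0, 0, 4), "+"))
  expect_warning(pol <- stacking_polarity(m1, m2), "tie")
  expect_equal(pol, "antiparallel")
})

test_that("generator recovery: antiparallel fraction within 3 binomial SE", {
  fix <- bulk_fixture()
  st <- fix$dimers[fix$dimers$class == "stacked", ]
  expect_gt(nrow(st), 2000)
  frac <- mean(st$polarity == "antiparallel")
  se <- sqrt(0.8 * 0.2 / nrow(st))
  expect_lt(abs(frac - 0.8), 3 * se)
})

test_that("hydrogen-bond contact honors the 2.5 A boundary", {
  a <- make_solute(1)
  # unrotated copy at (d + 4.8, 0, 0): its H1 (at -2.4 x) sits exactly d
  # from a's N3 (at +2.4 x), and every other H/acceptor pair is farther
  place_b <- function(d) make_solute(2, t = c(d + 4.8, 0, 0))
  expect_true(hbond_contact(a, place_b(2.4)))
  expect_false(hbond_contact(a, place_b(2.6)))
  expect_false(hbond_contact(a, make_solute(2, t = c(20, 0, 0))))
  # minimum-image: neighbors across the periodic boundary still contact
  box <- c(20, 20, 20)
  expect_true(hbond_contact(a, make_solute(2, t = c(-20 + 7.2, 0, 0)),
                            box = box))
})
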