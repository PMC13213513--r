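# Population selection, histograms, differential and free-energy maps.

# tiny hand-built ensemble: modifier at origin, one dimer adjacent, one far
local_selection_ensemble <- function(second_near = TRUE) {
  mod <- preorg:::instantiate(modifier_template(2), 1L)
  a <- make_solute(2, t = c(0, 0, 3.3))
  b_t <- if (second_near) c(0, 0, 3.3 + 4) else c(6.7, 0, 3.3)
  b <- make_solute(3, t = b_t)
  c1 <- make_solute(4, t = c(30, 30, 30))
  c2 <- make_solute(5, t = c(30, 30, 34))
  ensemble(list(md_frame(list(mod, a, b, c1, c2), box = c(80, 80, 80))))
}

test_that("near/bulk selection follows the membership rule", {
  ens <- local_selection_ensemble()
  pops <- select_populations(ens)
  expect_equal(nrow(pops$near), 1)
  expect_equal(nrow(pops$bulk), 1)
  expect_equal(nrow(pops$excluded), 0)
  expect_setequal(pops$near$id_a, 2)
  expect_setequal(pops$bulk$id_a, 4)
  # stacked partner is > 4 A from the modifier: under both_members the
  # straddling dimer is excluded from both populations
  both <- select_populations(
    ens, population_selection(membership = "both_members"))
  expect_equal(nrow(both$near), 0)
  expect_equal(nrow(both$excluded), 1)
  expect_equal(nrow(both$bulk), 1)
  # conservation: near + bulk + excluded = all enumerated
  expect_equal(nrow(both$near) + nrow(both$bulk) + nrow(both$excluded),
               nrow(both$all))
  # a dimer with both members within the cutoff is near under both rules
  ens2 <- local_selection_ensemble(second_near = FALSE)
  both2 <- select_populations(
    ens2, population_selection(membership = "both_members"))
  expect_equal(nrow(both2$near), 1)
})

test_that("requesting a near population without a modifier errors", {
  bulk <- make_bulk_ensemble(ensemble_spec(n_frames = 1, n_solutes = 4,
                                           seed = 1))
  expect_error(select_populations(bulk), "no modifier")
  pops <- select_populations(bulk, require_near = FALSE)
  expect_equal(nrow(pops$near), 0)
  expect_equal(nrow(pops$bulk), nrow(pops$all))
})

test_that("histogram3d bins exactly, half-open with closed last bin", {
  ax <- conformer_axes()
  one_bin <- data.frame(r = rep(4.05, 4), theta = rep(0.1, 4),
                        psi = rep(1.5, 4))
  h <- histogram3d(one_bin, ax)
  expect_equal(max(h$probability), 1.0)
  expect_equal(sum(h$counts), 4)
  # interior edge values land in the upper bin
  ax2 <- conformer_axes(r_edges = c(0, 1, 2), theta_edges = c(0, 1, 2),
                        psi_edges = c(0, 1, 2))
  h2 <- histogram3d(data.frame(r = 1, theta = 0.5, psi = 0.5), ax2)
  expect_equal(h2$counts[2, 1, 1], 1L)
  # the terminal edge closes the last bin
  h3 <- histogram3d(data.frame(r = 2, theta = 2, psi = 2), ax2)
  expect_equal(h3$counts[2, 2, 2], 1L)
  expect_error(histogram3d(one_bin[0, ], ax), "empty")
})

test_that("histogram3d equals brute-force per-observation counting", {
  set.seed(99)
  n <- 10000
  d <- data.frame(r = stats::runif(n, 2, 8),
                  theta = stats::runif(n, 0, pi),
                  psi = stats::runif(n, 0, pi))
  ax <- conformer_axes()
  h <- histogram3d(d, ax)
  brute <- array(0L, dim(h$counts))
  for (k in seq_len(n)) {
    i <- max(which(ax$r <= d$r[k] + 1e-15)); i <- min(i, length(ax$r) - 1)
    j <- max(which(ax$theta <= d$theta[k] + 1e-15))
    j <- min(j, length(ax$theta) - 1)
    l <- max(which(ax$psi <= d$psi[k] + 1e-15))
    l <- min(l, length(ax$psi) - 1)
    brute[i, j, l] <- brute[i, j, l] + 1L
  }
  expect_identical(unname(h$counts), brute)
  expect_equal(sum(h$counts), n)
  expect_equal(sum(h$probability), 1, tolerance = 1e-12)
})

test_that("differential maps are antisymmetric and sum to zero", {
  fix <- templated_fixture(3, 4)
  hn <- histogram3d(fix$pops$near)
  hb <- histogram3d(fix$pops$bulk)
  m <- differential_map(hn, hb, c("r", "psi"))
  expect_lt(abs(sum(m$values)), 1e-9)
  m_rev <- differential_map(hb, hn, c("r", "psi"))
  expect_equal(m$values, -m_rev$values)
  # identity: near = bulk gives an all-zero map
  m0 <- differential_map(hb, hb, c("r", "psi"))
  expect_true(all(m0$values == 0))
  # mismatched bin edges are a contract error
  hb2 <- histogram3d(fix$pops$bulk,
                     conformer_axes(r_edges = seq(2, 8, by = 0.5)))
  expect_error(differential_map(hn, hb2), "contract error")
})

test_that("templated differential map enhances the coplanar band", {
  fix <- templated_fixture(3, 4)
  m <- differential_map(histogram3d(fix$pops$near),
                        histogram3d(fix$pops$bulk), c("r", "psi"))
  expect_gt(differential_band_mass(m, pi / 2, pi / 9), 0)
  expect_lt(differential_band_mass(m, 0, pi / 6), 0)
})

test_that("psi marginal: peaks, band masses, uniform sampling limit", {
  # noise-free bulk: mass only in the terminal stacking bins
  sp <- ensemble_spec(n_frames = 5, n_solutes = 8,
                      coplanar_fraction_bulk = 0, angular_noise_sd = 0,
                      stack_distance_sd = 0, seed = 2)
  pm <- psi_marginal(histogram3d(enumerate_dimers(make_bulk_ensemble(sp))))
  occupied <- which(pm$probability > 0)
  expect_true(all(occupied %in% c(1L, length(pm$probability))))
  expect_equal(sum(pm$probability), 1, tolerance = 1e-12)
  # strongly templated near population peaks at pi/2
  fix <- templated_fixture(3, 4)
  pm2 <- psi_marginal(histogram3d(fix$pops$near))
  expect_lt(abs(pm2$peak - pi / 2), pi / 36)
  # uniform psi: bin probabilities approach uniformity at large n
  set.seed(77)
  d <- data.frame(r = stats::runif(50000, 2, 8), theta = 0.1,
                  psi = stats::runif(50000, 0, pi))
  pm3 <- psi_marginal(histogram3d(d))
  expect_lt(max(pm3$probability) / min(pm3$probability), 1.3)
})

test_that("free-energy maps: closed forms, masking, monotonicity", {
  m2 <- list(axes_names = c("r", "theta"),
             edges = list(r = c(0, 1, 2), theta = c(0, 1)),
             probability = matrix(c(0.5, 0.5), 2, 1))
  fe <- free_energy_map(m2)
  expect_equal(as.vector(fe$values), c(0, 0))
  p1 <- exp(-1) / (1 + exp(-1)); p2 <- 1 / (1 + exp(-1))
  fe2 <- free_energy_map(list(axes_names = c("r", "theta"),
                              edges = list(r = c(0, 1, 2), theta = c(0, 1)),
                              probability = matrix(c(p1, p2), 2, 1)))
  expect_equal(as.vector(fe2$values), c(1, 0), tolerance = 1e-12)
  # empty bins are masked, argmin matches argmax of probability
  fix <- templated_fixture(3, 4)
  h <- histogram3d(fix$pops$near)
  fe3 <- free_energy_map(h, c("r", "theta"))
  marg <- preorg:::marginalize_histogram(h, c("r", "theta"))
  expect_true(all(is.na(fe3$values[marg$probability == 0])))
  expect_equal(which.min(fe3$values), which.max(marg$probability))
  expect_error(free_energy_map(list(axes_names = "r",
                                    edges = list(r = c(0, 1)),
                                    probability = matrix(0, 1, 1))),
               "all-empty")
})
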