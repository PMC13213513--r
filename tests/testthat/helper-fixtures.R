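# Shared fixtures and small builders. Larger ensembles are generated once
# per session and memoized, so several test files can reuse them.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) assign(key, expr, .fixture_env)
  get(key, envir = .fixture_env)
}

# a solute molecule placed by rotation R and translation t
make_solute <- function(id, R = diag(3), t = c(0, 0, 0)) {
  tpl <- solute_template()
  xyz <- sweep(tpl$xyz %*% t(R), 2, t, "+")
  rownames(xyz) <- rownames(tpl$xyz)
  planar_molecule(id, tpl$spec, xyz)
}

rot_z_test <- function(a) {
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

# deterministic random rotation matrix (uniform, via QR of a normal matrix)
random_rot_test <- function() {
  qr_d <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# moderately large bulk ensemble at the stated study conditions
bulk_fixture <- function() fixture("bulk5000", {
  spec <- ensemble_spec(n_frames = 250, n_solutes = 40,
                        coplanar_fraction_bulk = 0.3, seed = 7)
  ens <- make_bulk_ensemble(spec)
  list(spec = spec, ens = ens, dimers = enumerate_dimers(ens))
})

# templated ensembles by (modifier size, templating strength)
templated_fixture <- function(size, strength, n_frames = 400, seed = 11,
                              noise = 0.08) {
  key <- sprintf("tmpl_%d_%g_%d_%d_%g", size, strength, n_frames, seed, noise)
  fixture(key, {
    spec <- ensemble_spec(n_frames = n_frames, n_solutes = 10,
                          templating_strength = strength,
                          angular_noise_sd = noise, seed = seed)
    ens <- make_templated_ensemble(spec, modifier_template(size))
    pops <- select_populations(ens)
    list(spec = spec, ens = ens, pops = pops)
  })
}

lattice_fixture <- function() fixture("lattice222", {
  lat <- make_crystal_lattice(c(2, 2, 2))
  list(lattice = lat, fingerprints = extract_fingerprints(lat))
})

# small templated ensemble for SDF / contact work
sdf_fixture <- function(size) {
  key <- sprintf("sdf_%d", size)
  fixture(key, {
    spec <- ensemble_spec(n_frames = 60, n_solutes = 10,
                          templating_strength = 4,
                          angular_noise_sd = 0.02, seed = 3)
    make_templated_ensemble(spec, modifier_template(size))
  })
}
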