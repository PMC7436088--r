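test_that("instantaneous SCD matches the closed form at reference angles", {
  expect_equal(instantaneous_scd(c(0, 0, 1)), 1)
  expect_equal(instantaneous_scd(c(0, 0, -3)), 1)          # sign-invariant
  expect_equal(instantaneous_scd(c(1, 0, 0)), -0.5)
  expect_equal(instantaneous_scd(c(0, 2.5, 0)), -0.5)      # magnitude-invariant
  magic <- c(sqrt(2 / 3), 0, sqrt(1 / 3))                  # cos^2 = 1/3
  expect_equal(instantaneous_scd(magic), 0, tolerance = 1e-12)
  expect_equal(instantaneous_scd(c(1, 1, 1), c(0, 0, 5)),
               instantaneous_scd(c(1, 1, 1)))
  expect_error(instantaneous_scd(c(0, 0, 0)), "invalid geometry")
})

test_that("an isotropic bond ensemble averages to zero order", {
  set.seed(12)
  n <- 20000
  v <- matrix(rnorm(3 * n), ncol = 3)
  s <- apply(v, 1, instantaneous_scd)
  # Var(P2(cos theta)) = 1/5 for isotropic orientations
  expect_lt(abs(mean(s)), 3 * sqrt(0.2 / n))
})

test_that("reconstruction geometry is exact on an all-trans chain", {
  chain <- cbind(0, 0, -(0:9) * 1.27)
  for (j in 2:9) {
    u <- reconstruct_ch_vectors(chain, j)
    expect_equal(nrow(u), 2)
    expect_equal(rowSums(u^2), c(1, 1), tolerance = 1e-12)
    expect_equal(u[, 3], c(0, 0), tolerance = 1e-12)   # perpendicular to z
    # H-C-H angle is tetrahedral: cos(acos(-1/3)) exactly
    expect_equal(sum(u[1, ] * u[2, ]), -1 / 3, tolerance = 1e-9)
  }
  # |S| = 0.5 for every reconstructed bond of the straight chain
  u <- reconstruct_ch_vectors(chain, 5)
  expect_equal((3 * u[, 3]^2 - 1) / 2, c(-0.5, -0.5), tolerance = 1e-12)

  # terminal methyl: three unit vectors at mutual tetrahedral angles
  um <- reconstruct_ch_vectors(chain, 10)
  expect_equal(nrow(um), 3)
  for (a in 1:2) for (b in (a + 1):3)
    expect_equal(sum(um[a, ] * um[b, ]), -1 / 3, tolerance = 1e-9)

  expect_error(reconstruct_ch_vectors(chain[1:2, ], 1), "reconstruction error")
  expect_error(reconstruct_ch_vectors(chain, 11), "reconstruction error")
})

test_that("sp2 reconstruction returns the in-plane vinyl vector", {
  # a kinked planar chain: the vinyl H bisects the C-C=C exterior angle
  chain <- rbind(c(0, 0, 0), c(1, 0, -1), c(2, 0, 0), c(3, 0, -1))
  u <- reconstruct_ch_vectors(chain, 2, sp2 = TRUE)
  expect_equal(nrow(u), 1)
  expect_equal(u[1, 2], 0, tolerance = 1e-12)       # stays in the xz plane
  expect_equal(unname(u[1, ]), c(0, 0, -1), tolerance = 1e-12)
})

test_that("explicit-H and reconstruction profiles agree on the same conformers", {
  sim <- gen_bilayer(bilayer_preset("popc", n_lipids_per_leaflet = 400,
                                    seed = 21), n_frames = 1, sigma_z = 0)
  pe <- scd_profile(sim$trajectory, sim$topology, "sn1")
  pr <- scd_profile(sim$trajectory, sim$topology, "sn1",
                    hydrogens = "reconstruct")
  expect_identical(pe$hydrogens, "explicit")
  expect_identical(pr$hydrogens, "reconstructed")
  # saturated mid-chain carbons; terminal geometry is approximate by design
  mid <- 2:15
  expect_lt(max(abs(pe$scd[mid] - pr$scd[mid])), 0.02)
})

test_that("generator-prescribed profiles are recovered from explicit hydrogens", {
  sim <- gen_bilayer(bilayer_preset("popc", n_lipids_per_leaflet = 1250,
                                    seed = 8), n_frames = 1)
  for (ch in c("sn1", "sn2")) {
    prof <- scd_profile(sim$trajectory, sim$topology, ch)
    expect_lt(max(abs(prof$scd - sim$ground_truth$scd[[ch]])), 0.01)
  }
})

test_that("near-probe profiles reselect per frame and error when empty", {
  sim <- gen_bilayer(bilayer_preset("popc", n_lipids_per_leaflet = 16,
                                    probe = "T*", seed = 2), n_frames = 2)
  rid <- sim$ground_truth$probe_residue
  prof <- scd_profile(sim$trajectory, sim$topology, "sn1",
                      probe_residue = rid, cutoff = 5)
  expect_gte(prof$n_lipids_used, 1)
  expect_match(prof$selection, "within 5")
  expect_error(
    scd_profile(sim$trajectory, sim$topology, "sn1",
                probe_residue = rid, cutoff = 1e-6),
    "empty selection")
})

test_that("the disordered tail decays toward zero on the fluid preset", {
  sim <- gen_bilayer(bilayer_preset("popc", n_lipids_per_leaflet = 200,
                                    seed = 4), n_frames = 1)
  prof <- scd_profile(sim$trajectory, sim$topology, "sn1")
  expect_lt(prof$scd[16], 0.08)
  expect_gt(prof$scd[4], 0.15)
  expect_lt(prof$scd[16], prof$scd[10])
})
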