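test_that("generation is bit-reproducible for a fixed seed", {
  spec <- bilayer_preset("popc", n_lipids_per_leaflet = 8, seed = 13)
  a <- gen_bilayer(spec, n_frames = 2)
  b <- gen_bilayer(spec, n_frames = 2)
  expect_identical(a$trajectory$frames[[1]]$xyz, b$trajectory$frames[[1]]$xyz)
  expect_identical(a$trajectory$frames[[2]]$xyz, b$trajectory$frames[[2]]$xyz)
  # a different seed moves the coordinates
  spec2 <- bilayer_preset("popc", n_lipids_per_leaflet = 8, seed = 14)
  c <- gen_bilayer(spec2, n_frames = 2)
  expect_false(identical(a$trajectory$frames[[1]]$xyz,
                         c$trajectory$frames[[1]]$xyz))
})

test_that("constructed geometry equals the spec exactly when unjittered", {
  spec <- bilayer_preset("popc", n_lipids_per_leaflet = 16, seed = 1)
  sim <- gen_bilayer(spec, n_frames = 1, sigma_z = 0)
  fr <- sim$trajectory$frames[[1]]
  expect_equal(bilayer_thickness(fr, sim$topology), 37.3, tolerance = 1e-6)
  expect_equal(area_per_lipid(fr, sim$topology)$apl,
               sim$ground_truth$area_per_lipid, tolerance = 1e-9)
  expect_equal(sim$ground_truth$thickness, 37.3)
})

test_that("probe systems carry the probe residue in one leaflet", {
  sim <- gen_bilayer(bilayer_preset("dppc-chol", probe = "N*",
                                    n_lipids_per_leaflet = 8, seed = 6),
                     n_frames = 1)
  rid <- sim$ground_truth$probe_residue
  fr <- sim$trajectory$frames[[1]]
  expect_true(!is.null(rid))
  expect_true(any(fr$residue_ids == rid))
  expect_identical(sim$trajectory$label$probe_state, "N*")
  # head anchored beneath the upper P plane
  head_z <- fr$xyz[fr$residue_ids == rid & fr$atom_names == "N1", 3]
  expect_lt(head_z, 45.9 / 2)
  expect_gt(head_z, 0)
})

test_that("infeasible order targets are rejected", {
  expect_error(
    bilayer_spec(8, 37.3, 20,
                 list(sn1 = list(targets = c(0.3, 0.6, 0.3)))),
    "configuration error")
})

test_that("written PDB re-reads to the same coordinates within format precision", {
  sim <- gen_bilayer(bilayer_preset("popc", n_lipids_per_leaflet = 6,
                                    seed = 3), n_frames = 2)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(sim$trajectory, path)
  back <- read_structure(path, sim$topology)
  expect_length(back$frames, 2)
  for (i in 1:2) {
    expect_lt(max(abs(back$frames[[i]]$xyz - sim$trajectory$frames[[i]]$xyz)),
              1e-3)
    expect_equal(back$frames[[i]]$time, sim$trajectory$frames[[i]]$time)
  }
  expect_equal(back$frames[[1]]$box, sim$trajectory$frames[[1]]$box,
               tolerance = 1e-3)
})

test_that("topology files round-trip through JSON and YAML", {
  sim <- gen_bilayer(bilayer_preset("popc", n_lipids_per_leaflet = 4,
                                    seed = 1), n_frames = 1)
  for (ext in c(".json", ".yaml")) {
    path <- withr::local_tempfile(fileext = ext)
    write_topology(sim$topology, path)
    back <- read_topology(path)
    expect_identical(back$name, sim$topology$name)
    expect_identical(back$chains$sn1$carbons, sim$topology$chains$sn1$carbons)
    expect_identical(back$chains$sn2$double_bonds,
                     sim$topology$chains$sn2$double_bonds)
    expect_identical(back$chains$sn2$hydrogens[[9]],
                     sim$topology$chains$sn2$hydrogens[[9]])
  }
})

test_that("target profile helper produces the plateau-decay-dip shape", {
  v <- target_scd_profile(18, 0.2, 7, 0.03, dip = c("9" = 0.1, "10" = 0.1))
  expect_equal(v[2:7], rep(0.2, 6))
  expect_equal(v[c(9, 10)], c(0.1, 0.1))
  expect_equal(v[18], 0.03)
  expect_lt(v[17], v[12])  # monotone decay along the tail
})

test_that("spectrum and image generators honour their ground truth", {
  sp <- gen_spectrum(list(c(470, 1, 12)))
  expect_equal(sp$wavelength[which.max(sp$intensity)], 470)
  expect_error(gen_spectrum(list(c(470, -1, 12))), "positive")

  a <- gen_guv_images(seed = 21)
  b <- gen_guv_images(seed = 21)
  expect_identical(a$ch_N, b$ch_N)
  flat <- gen_guv_images(true_ratio = 1, noise_sd = 0, seed = 1)
  expect_equal(flat$ch_N, flat$ch_T)
  expect_error(gen_guv_images(radius_px = 3, ring_width_px = 5), "radius")
})
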