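test_that("multi-model PDB reading preserves counts, box and coordinates", {
  top <- tiny_topology(2, "POPC")
  path <- withr::local_tempfile(fileext = ".pdb")
  mk_atom <- function(serial, name, resno, x, y, z)
    sprintf("ATOM  %5d %-4s %-4s%5d    %8.3f%8.3f%8.3f  1.00  0.00",
            serial, name, "POPC", resno, x, y, z)
  model <- function(shift) {
    lines <- character()
    for (r in 1:4) {
      z <- if (r <= 2) 18 else -18
      lines <- c(lines,
        mk_atom(3 * r - 2, "P", r, 5 * r, 5, z + shift),
        mk_atom(3 * r - 1, "C1", r, 5 * r, 5, z - 2 + shift),
        mk_atom(3 * r,     "C2", r, 5 * r, 5, z - 4 + shift))
    }
    c("MODEL", lines, "ENDMDL")
  }
  writeLines(c(
    "CRYST1   64.000   64.000   80.000  90.00  90.00  90.00 P 1           1",
    model(0), model(0.25), "END"), path)

  traj <- read_structure(path, top)
  expect_length(traj$frames, 2)
  f1 <- traj$frames[[1]]
  expect_equal(length(unique(f1$residue_ids)), 4)
  expect_equal(f1$box, c(64, 64, 80))
  expect_equal(f1$xyz[1, ], c(5, 5, 18))
  expect_equal(traj$frames[[2]]$xyz[1, 3], 18.25)
})

test_that("missing CRYST1 falls back to the bounding box", {
  top <- tiny_topology(1, "POPC")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL",
    sprintf("ATOM  %5d %-4s %-4s%5d    %8.3f%8.3f%8.3f  1.00  0.00",
            1:2, c("P", "C1"), "POPC", 1L, c(1, 11), c(2, 22), c(3, 43)),
    "ENDMDL", "END"), path)
  traj <- read_structure(path, top)
  expect_equal(traj$frames[[1]]$box, c(10, 20, 40))
})

test_that("topology mismatches and unreadable files are reported", {
  top <- tiny_topology(1, "POPC")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL",
    sprintf("ATOM  %5d %-4s %-4s%5d    %8.3f%8.3f%8.3f  1.00  0.00",
            1L, "C1", "POPC", 7L, 1, 2, 3),  # no P atom
    "ENDMDL", "END"), path)
  expect_error(read_structure(path, top), "topology mismatch.*7.*P")
  expect_error(read_structure(file.path(tempdir(), "nope.pdb"), top),
               "cannot read")
})

test_that("leaflet assignment splits by the P midplane with a lower tie rule", {
  top <- tiny_topology(1)
  fr <- p_only_frame(c(18, 19, -18, -19))
  leaf <- assign_leaflets(fr, top)
  expect_equal(unname(leaf[c("1", "2", "3", "4")]),
               c("upper", "upper", "lower", "lower"))

  # all P coplanar: everything ties to "lower", with a warning
  fr2 <- p_only_frame(rep(5, 4))
  expect_warning(leaf2 <- assign_leaflets(fr2, top), "degenerate")
  expect_true(all(leaf2 == "lower"))

  # no phosphorus at all
  fr3 <- membrane_frame(matrix(1:3, 1), "C1", 1L, "LIP", c(10, 10, 10))
  expect_error(assign_leaflets(fr3, top), "reference atom")
})

test_that("leaflet assignment is translation invariant and recovers the generated split", {
  top <- tiny_topology(1)
  set.seed(31)
  z <- c(18 + rnorm(50), -18 + rnorm(50))
  fr <- p_only_frame(z)
  leaf <- assign_leaflets(fr, top)
  shifted <- fr
  shifted$xyz <- fr$xyz + matrix(rep(c(3, -2, 7), each = 100), ncol = 3)
  expect_identical(assign_leaflets(shifted, top), leaf)

  sim <- gen_bilayer(bilayer_preset("popc", n_lipids_per_leaflet = 50,
                                    seed = 3), n_frames = 1)
  got <- assign_leaflets(sim$trajectory$frames[[1]], sim$topology)
  truth <- sim$ground_truth$leaflets
  expect_identical(unname(got[names(truth)]), unname(truth))
})

test_that("near-probe selection applies the cutoff with xy minimum image", {
  top <- tiny_topology(1)
  # probe atom at origin; lipid 1 nearest at 4.9 A, lipid 2 at 5.1 A,
  # lipid 3 across the periodic x boundary at distance 1.0
  xyz <- rbind(c(0, 0, 0),          # probe
               c(4.9, 0, 0), c(0, 0, 30),
               c(5.1, 0, 0),
               c(39, 0, 0))
  fr <- membrane_frame(xyz, c("X1", "P", "C9", "P", "P"),
                       c(9L, 1L, 1L, 2L, 3L),
                       c("PRB", rep("LIP", 4)), box = c(40, 40, 60))
  expect_equal(select_near_probe(fr, top, 9, 5), c(1L, 3L))
  expect_error(select_near_probe(fr, top, 77, 5), "missing probe")
  # coincident atoms selected at an arbitrarily small cutoff
  fr2 <- membrane_frame(rbind(c(1, 1, 1), c(1, 1, 1)), c("X1", "P"),
                        c(9L, 1L), c("PRB", "LIP"), c(40, 40, 60))
  expect_equal(select_near_probe(fr2, top, 9, 1e-9), 1L)
})

test_that("near-probe selection equals a brute-force periodic scan", {
  top <- tiny_topology(1)
  set.seed(77)
  box <- c(30, 30, 60)
  n_lip <- 50
  lip_xyz <- do.call(rbind, lapply(seq_len(n_lip), function(i)
    cbind(runif(3, 0, box[1]), runif(3, 0, box[2]), runif(3, -20, 20))))
  probe_xyz <- cbind(runif(4, 0, box[1]), runif(4, 0, box[2]),
                     runif(4, -20, 20))
  fr <- membrane_frame(
    rbind(lip_xyz, probe_xyz),
    c(rep(c("P", "C1", "C2"), n_lip), paste0("X", 1:4)),
    c(rep(seq_len(n_lip), each = 3), rep(99L, 4)),
    c(rep("LIP", 3 * n_lip), rep("PRB", 4)), box)

  # oracle: explicit loop over all atom pairs and all 9 xy images
  mind <- rep(Inf, n_lip)
  for (i in seq_len(nrow(lip_xyz))) for (j in seq_len(4)) {
    for (sx in -1:1) for (sy in -1:1) {
      d <- sqrt(sum((lip_xyz[i, ] - probe_xyz[j, ] -
                       c(sx * box[1], sy * box[2], 0))^2))
      r <- (i - 1) %/% 3 + 1
      mind[r] <- min(mind[r], d)
    }
  }
  expected <- which(mind <= 5)
  expect_equal(select_near_probe(fr, top, 99, 5), as.integer(expected))
})

test_that("analysis frames land on the even grid over the last window", {
  tr <- dummy_traj(seq(0, 15, by = 0.5))
  sel <- analysis_frames(tr)
  expect_length(sel$frames, 11)
  expect_equal(vapply(sel$frames, `[[`, numeric(1), "time"),
               seq(10, 15, by = 0.5))

  # finer cadence still snaps onto the same grid
  tr2 <- dummy_traj(seq(0, 15, by = 0.1))
  sel2 <- analysis_frames(tr2)
  expect_equal(vapply(sel2$frames, `[[`, numeric(1), "time"),
               seq(10, 15, by = 0.5))

  # window equal to the full span with matching count is the identity
  tr3 <- dummy_traj(seq(0, 15, by = 0.5))
  sel3 <- analysis_frames(tr3, window_ns = 15, n_frames = 31)
  expect_equal(vapply(sel3$frames, `[[`, numeric(1), "time"),
               seq(0, 15, by = 0.5))

  expect_error(analysis_frames(dummy_traj(c(0, 1, 2))), "insufficient span")
})
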