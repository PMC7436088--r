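#' Piecewise target SCD profile
#'
#' Helper to build per-carbon `|S_CD|` targets: a plateau over the upper
#' chain, a linear decay to the terminal value (the disordered-tail shape
#' seen in NMR and simulation), and optional local dips such as the drop at
#' the double-bond carbons of an oleoyl chain.
#'
#' @param n chain length (carbons).
#' @param plateau plateau value.
#' @param plateau_end last carbon of the plateau.
#' @param tail_value value at the terminal carbon.
#' @param dip named numeric vector, e.g. `c("9" = 0.10, "10" = 0.10)`.
#' @return numeric vector of length `n`.
#' @export
target_scd_profile <- function(n, plateau, plateau_end, tail_value,
                               dip = NULL) {
  stopifnot(n >= 3, plateau_end >= 1, plateau_end < n)
  v <- numeric(n)
  v[1:plateau_end] <- plateau
  v[plateau_end:n] <- seq(plateau, tail_value,
                          length.out = n - plateau_end + 1)
  if (!is.null(dip)) v[as.integer(names(dip))] <- dip
  v
}

#' Specification of a synthetic bilayer
#'
#' Defines the ground truth a generated bilayer must realise: P-P thickness,
#' box size (hence area per lipid), per-carbon `|S_CD|` targets per chain,
#' cholesterol fraction (metadata driving the area-per-lipid correction and
#' an ordered profile; no sterol atoms are placed), and an optional
#' single-leaflet probe anchored below the membrane surface.
#'
#' @param n_lipids_per_leaflet lipids per leaflet.
#' @param target_thickness P-P thickness in Angstrom.
#' @param box_xy lateral box edge in Angstrom.
#' @param profiles named list of chains (e.g. `sn1`, `sn2`); each a list
#'   with `targets` (per-carbon `|S_CD|` in `[0, 0.5]`) and optional
#'   `double_bonds` (sp2 carbon indices).
#' @param chol_fraction cholesterol mole fraction in `[0, 1]`.
#' @param probe `"none"`, `"N"`, `"N*"` or `"T*"`; non-`"none"` places a
#'   zwitterionic-head placeholder with an 18-carbon tail in the upper
#'   leaflet.
#' @param probe_depth anchoring depth of the chromophore head below the P
#'   plane, Angstrom.
#' @param membrane membrane label for the system.
#' @param seed RNG seed; generation is bit-reproducible per seed.
#' @return an `mp_bilayer_spec`.
#' @export
bilayer_spec <- function(n_lipids_per_leaflet, target_thickness, box_xy,
                         profiles, chol_fraction = 0, probe = "none",
                         probe_depth = 2, membrane = "POPC", seed = 1) {
  stopifnot(is_count(n_lipids_per_leaflet), target_thickness > 0, box_xy > 0,
            chol_fraction >= 0, chol_fraction <= 1)
  if (!is.list(profiles) || is.null(names(profiles)))
    stopf("'profiles' must be a named list of chains")
  for (id in names(profiles)) {
    t <- profiles[[id]]$targets
    if (is.null(t) || length(t) < 3) stopf("chain '%s': need >= 3 targets", id)
    if (any(t < 0) || any(t > 0.5))
      stopf("configuration error: chain '%s' SCD target outside [0, 0.5]", id)
  }
  probe <- match.arg(probe, c("none", "N", "N*", "T*"))
  structure(list(
    n_lipids_per_leaflet = as.integer(n_lipids_per_leaflet),
    target_thickness = target_thickness, box_xy = box_xy,
    profiles = profiles, chol_fraction = chol_fraction,
    probe = probe, probe_depth = probe_depth, membrane = membrane,
    seed = as.integer(seed)), class = "mp_bilayer_spec")
}

#' Preset bilayer specifications
#'
#' `"popc"` emulates a fluid (Ld-like) POPC bilayer: P-P thickness 37.3 A,
#' area per lipid 64.4 A^2, a 16-carbon saturated sn-1 chain and an
#' 18-carbon sn-2 chain with an sp2 dip at carbons 9-10. `"dppc-chol"`
#' emulates an ordered (Lo-like) DPPC/cholesterol bilayer: thickness
#' 45.9 A, tighter packing, two 16-carbon chains with a high plateau, and
#' cholesterol fraction 0.32 (above the 20% threshold that triggers the
#' area-per-lipid correction). A probe tautomer perturbs the target
#' profiles slightly, most visibly the ordering effect of `"T*"` in POPC.
#'
#' @param preset `"popc"` or `"dppc-chol"`.
#' @param probe probe state, as in [bilayer_spec()].
#' @param n_lipids_per_leaflet lipids per leaflet (default 64, a standard membrane-patch size).
#' @param seed RNG seed.
#' @return an `mp_bilayer_spec`.
#' @export
bilayer_preset <- function(preset = c("popc", "dppc-chol"), probe = "none",
                           n_lipids_per_leaflet = 64, seed = 1) {
  preset <- match.arg(preset)
  probe <- match.arg(probe, c("none", "N", "N*", "T*"))
  if (preset == "popc") {
    delta <- switch(probe, none = 0, N = 0.005, "N*" = 0.01, "T*" = 0.03)
    profiles <- list(
      sn1 = list(targets = target_scd_profile(16, 0.21, 8, 0.05) + delta),
      sn2 = list(targets = target_scd_profile(18, 0.20, 7, 0.03,
                                              dip = c("9" = 0.10, "10" = 0.10))
                 + delta,
                 double_bonds = c(9L, 10L)))
    bilayer_spec(n_lipids_per_leaflet, 37.3,
                 sqrt(n_lipids_per_leaflet * 64.4), profiles,
                 chol_fraction = 0, probe = probe, membrane = "POPC",
                 seed = seed)
  } else {
    delta <- if (probe == "none") 0 else 0.005
    prof <- list(targets = target_scd_profile(16, 0.35, 10, 0.08) + delta)
    bilayer_spec(n_lipids_per_leaflet, 45.9,
                 sqrt(n_lipids_per_leaflet * 49.6),
                 list(sn1 = prof, sn2 = prof),
                 chol_fraction = 0.32, probe = probe, membrane = "DPPC-Chol",
                 seed = seed)
  }
}

# Solve the mean tilt beta0 such that E[P2(cos(beta0 + eps))] = target with
# eps ~ N(0, sigma). Gauss-quadrature over eps + uniroot over beta0.
solve_tilt <- function(target, sigma) {
  if (sigma == 0) return(acos(sqrt((2 * target + 1) / 3)))
  z <- seq(-4, 4, length.out = 81)
  w <- stats::dnorm(z); w <- w / sum(w)
  ev <- function(b0) sum(w * p2(cos(b0 + z * sigma)))
  if (ev(0) < target)
    stopf("configuration error: SCD target %.3g infeasible at tilt sd %.3g rad",
          target / 2, sigma)
  stats::uniroot(function(b0) ev(b0) - target, c(0, pi / 2),
                 tol = 1e-10)$root
}

# chain-local atom name tables; one-letter prefixes keep every name within
# the 4-character PDB atom-name field for chains up to 49 carbons
chain_prefixes <- c("C", "D", "E", "F")
h_prefixes <- c("G", "J", "L", "M")

build_chain_names <- function(profiles) {
  out <- list()
  for (ci in seq_along(profiles)) {
    id <- names(profiles)[ci]
    m <- length(profiles[[ci]]$targets)
    db <- as.integer(profiles[[ci]]$double_bonds %||% integer())
    carbons <- paste0(chain_prefixes[ci], seq_len(m))
    hydrogens <- lapply(seq_len(m), function(j) {
      if (j %in% db) paste0(h_prefixes[ci], 2 * j - 1)   # one vinyl H
      else paste0(h_prefixes[ci], c(2 * j - 1, 2 * j))
    })
    out[[id]] <- list(carbons = carbons, hydrogens = hydrogens,
                      double_bonds = db)
  }
  out
}

#' Generate a synthetic bilayer trajectory with known ground truth
#'
#' Builds a kinematic stick-model bilayer, not a physical conformer set:
#' lipids sit on a jittered xy grid, leaflet phosphorus atoms at plus/minus
#' half the target thickness (z jitter `sigma_z`), and each acyl chain is
#' grown through per-carbon local direction vectors whose tilt distribution
#' is solved numerically so that the expected `|S_CD|` of the C-H bonds
#' (placed perpendicular to the local direction, as the reconstruction
#' geometry assumes) equals the per-carbon target. Bond orientation states
#' persist across frames and are resampled with probability
#' `bond_resample_rate` per frame, emulating the slow, temporally coherent
#' order fluctuations of real trajectories. Everything is bit-reproducible
#' for a fixed `spec$seed`.
#'
#' @param spec an [bilayer_spec()] / [bilayer_preset()].
#' @param n_frames number of frames.
#' @param frame_spacing_ns frame cadence in ns.
#' @param start_time_ns time of the first frame (default 10, so the default
#'   11 frames at 0.5 ns span 10-15 ns).
#' @param sigma_z z jitter of the phosphorus planes, Angstrom.
#' @param tilt_sd_deg Gaussian wobble of the chain tilt, degrees.
#' @param bond_resample_rate per-frame probability that a carbon's
#'   orientation state is redrawn.
#' @return list with `trajectory` (`mp_trajectory`), `topology`
#'   (`mp_topology` with explicit hydrogens), `ground_truth` (thickness,
#'   area per lipid, per-chain SCD targets, leaflet labels, probe residue)
#'   and `spec`.
#' @export
gen_bilayer <- function(spec, n_frames = 11, frame_spacing_ns = 0.5,
                        start_time_ns = 10, sigma_z = 0.5, tilt_sd_deg = 5,
                        bond_resample_rate = 0.02) {
  stopifnot(inherits(spec, "mp_bilayer_spec"), is_count(n_frames))
  set.seed(spec$seed)
  sigma_b <- tilt_sd_deg * pi / 180
  n_leaf <- spec$n_lipids_per_leaflet
  n_lip <- 2L * n_leaf
  box <- c(spec$box_xy, spec$box_xy, spec$target_thickness + 30)
  s_leaf <- rep(c(1, -1), each = n_leaf)  # +1 upper, -1 lower
  thk2 <- spec$target_thickness / 2

  # static jittered xy grid per leaflet
  k <- ceiling(sqrt(n_leaf))
  g <- (seq_len(k) - 0.5) * spec$box_xy / k
  grid <- as.matrix(expand.grid(x = g, y = g))[seq_len(n_leaf), ]
  xy <- rbind(grid, grid) + matrix(stats::rnorm(2 * n_lip, 0, 0.6), ncol = 2)

  chains <- build_chain_names(spec$profiles)
  chain_ids <- names(chains)
  n_chain <- length(chain_ids)
  m_c <- vapply(spec$profiles, function(p) length(p$targets), integer(1))
  beta0 <- lapply(spec$profiles, function(p)
    vapply(p$targets, function(t) solve_tilt(2 * t, sigma_b), numeric(1)))

  # atom layout within one lipid: P, then per chain carbons then hydrogens
  nm <- "P"
  for (id in chain_ids)
    nm <- c(nm, chains[[id]]$carbons, unlist(chains[[id]]$hydrogens))
  apl_atoms <- length(nm)
  off_P <- 1L
  off_C <- list(); off_H <- list()
  cur <- 1L
  for (id in chain_ids) {
    m <- length(chains[[id]]$carbons)
    off_C[[id]] <- cur + seq_len(m)
    cur <- cur + m
    off_H[[id]] <- vector("list", m)
    for (j in seq_len(m)) {
      nh <- length(chains[[id]]$hydrogens[[j]])
      off_H[[id]][[j]] <- cur + seq_len(nh)
      cur <- cur + nh
    }
  }
  base <- (seq_len(n_lip) - 1L) * apl_atoms
  probe_on <- spec$probe != "none"
  n_probe_atoms <- if (probe_on) 21L else 0L
  n_atoms <- n_lip * apl_atoms + n_probe_atoms

  resname <- if (spec$membrane == "POPC") "POPC" else "DPPC"
  atom_names <- c(rep(nm, n_lip),
                  if (probe_on) c("N1", "O1", "S1", paste0("T", 1:18)))
  residue_ids <- c(rep(seq_len(n_lip), each = apl_atoms),
                   rep(n_lip + 1L, n_probe_atoms))
  residue_names <- c(rep(resname, n_lip * apl_atoms),
                     rep("PRB", n_probe_atoms))

  # probe geometry: chromophore head below the upper P plane, tail spanning
  # the leaflet; static across frames
  if (probe_on) {
    cx <- spec$box_xy / 2; cy <- spec$box_xy / 2
    zh <- thk2 - spec$probe_depth
    probe_xyz <- rbind(
      c(cx, cy, zh + 1.0), c(cx + 1.2, cy, zh), c(cx - 1.2, cy, zh + 0.5),
      cbind(cx + stats::rnorm(18, 0, 0.3), cy + stats::rnorm(18, 0, 0.3),
            zh - 1.25 * (1:18)))
  }

  # orientation state: per chain, n_lip x m matrices of tilt, azimuth and
  # H-pair phase; persists across frames with partial resampling
  draw <- function(id) {
    m <- m_c[[id]]
    list(beta = matrix(rep(beta0[[id]], each = n_lip), n_lip, m) +
           matrix(stats::rnorm(n_lip * m, 0, sigma_b), n_lip, m),
         phi = matrix(stats::runif(n_lip * m, 0, 2 * pi), n_lip, m),
         hphi = matrix(stats::runif(n_lip * m, 0, 2 * pi), n_lip, m))
  }
  state <- lapply(stats::setNames(chain_ids, chain_ids), draw)

  frames <- vector("list", n_frames)
  for (fi in seq_len(n_frames)) {
    if (fi > 1) {
      for (id in chain_ids) {
        m <- m_c[[id]]
        new <- draw(id)
        keep <- matrix(stats::runif(n_lip * m) >= bond_resample_rate,
                       n_lip, m)
        for (fld in c("beta", "phi", "hphi"))
          state[[id]][[fld]] <- ifelse(keep, state[[id]][[fld]],
                                       new[[fld]])
      }
    }
    X <- matrix(0, n_atoms, 3)
    zP <- s_leaf * thk2 + stats::rnorm(n_lip, 0, sigma_z)
    X[base + off_P, ] <- cbind(xy, zP)
    for (ci in seq_along(chain_ids)) {
      id <- chain_ids[ci]
      m <- m_c[[id]]
      st <- state[[id]]
      sb <- sin(st$beta); cb <- cos(st$beta)
      D <- list()  # local direction per carbon: n_lip x 3
      for (j in seq_len(m))
        D[[j]] <- cbind(sb[, j] * cos(st$phi[, j]),
                        sb[, j] * sin(st$phi[, j]),
                        -s_leaf * cb[, j])
      C <- vector("list", m)
      start <- cbind(xy[, 1] + 0.9 * (ci - 1.5) * 2,
                     xy[, 2],
                     s_leaf * (thk2 - 2.2))
      C[[1]] <- start
      C[[2]] <- C[[1]] + 1.25 * D[[1]]
      if (m > 2) for (j in 2:(m - 1)) C[[j + 1]] <- C[[j - 1]] + 2.5 * D[[j]]
      sp2 <- seq_len(m) %in% chains[[id]]$double_bonds
      for (j in seq_len(m)) {
        X[base + off_C[[id]][j], ] <- C[[j]]
        b <- perp_basis(D[[j]])
        ph <- st$hphi[, j]
        if (sp2[j]) {
          u <- cos(ph) * b$e1 + sin(ph) * b$e2
          X[base + off_H[[id]][[j]][1], ] <- C[[j]] + 1.09 * u
        } else {
          u1 <- cos(ph + half_tetra) * b$e1 + sin(ph + half_tetra) * b$e2
          u2 <- cos(ph - half_tetra) * b$e1 + sin(ph - half_tetra) * b$e2
          X[base + off_H[[id]][[j]][1], ] <- C[[j]] + 1.09 * u1
          X[base + off_H[[id]][[j]][2], ] <- C[[j]] + 1.09 * u2
        }
      }
    }
    if (probe_on) X[n_lip * apl_atoms + seq_len(n_probe_atoms), ] <- probe_xyz
    frames[[fi]] <- membrane_frame(
      X, atom_names, residue_ids, residue_names, box,
      start_time_ns + (fi - 1) * frame_spacing_ns)
  }

  topology <- lipid_topology(resname, "P", chains)
  label <- system_label(spec$membrane, spec$probe)
  list(
    trajectory = membrane_trajectory(frames, label),
    topology = topology,
    ground_truth = list(
      thickness = spec$target_thickness,
      area_per_lipid = spec$box_xy^2 / n_leaf,
      scd = lapply(spec$profiles, `[[`, "targets"),
      chol_fraction = spec$chol_fraction,
      leaflets = stats::setNames(ifelse(s_leaf > 0, "upper", "lower"),
                                 seq_len(n_lip)),
      probe_residue = if (probe_on) n_lip + 1L else NULL),
    spec = spec)
}

#' Generate a Gaussian binding-energy series
#'
#' Stand-in for per-frame probe-membrane binding energies, which in
#' production come from the MD engine.
#'
#' @param mean,sd Gaussian parameters (kcal/mol), `sd >= 0`.
#' @param n series length, `>= 2`.
#' @param seed RNG seed.
#' @param label optional label.
#' @return an `mp_energy_series` with times 10, 10.5, ... ns.
#' @export
gen_energy_series <- function(mean, sd, n, seed = 1, label = NULL) {
  stopifnot(sd >= 0, is_count(n), n >= 2)
  set.seed(seed)
  energy_series(stats::rnorm(n, mean, sd), times = 10 + 0.5 * (seq_len(n) - 1),
                label = label)
}

#' Generate a sum-of-Gaussians emission spectrum
#'
#' @param peaks list of `c(center_nm, amplitude, width_nm)` triples (or a
#'   3-column matrix, one row per band).
#' @param grid wavelength grid in nm.
#' @return an `mp_spectrum`.
#' @export
gen_spectrum <- function(peaks, grid = seq(400, 700, by = 1)) {
  if (is.list(peaks)) peaks <- do.call(rbind, peaks)
  peaks <- matrix(as.numeric(peaks), ncol = 3)
  if (any(peaks[, 2] <= 0) || any(peaks[, 3] <= 0))
    stopf("amplitudes and widths must be positive")
  I <- rep(0, length(grid))
  for (r in seq_len(nrow(peaks)))
    I <- I + peaks[r, 2] * exp(-(grid - peaks[r, 1])^2 / (2 * peaks[r, 3]^2))
  emission_spectrum(grid, I)
}

#' Generate a two-channel ring (vesicle cross-section) image pair
#'
#' The membrane of a vesicle imaged at its equator is a bright annulus.
#' Both channels share a Gaussian ring profile; the N* channel is the T*
#' channel scaled by `true_ratio` before independent Gaussian noise
#' (relative to the ring peak) is added and negatives are clipped.
#'
#' @param size image edge in pixels.
#' @param radius_px ring radius; must exceed `ring_width_px`.
#' @param ring_width_px Gaussian ring width (sd) in pixels.
#' @param true_ratio ground-truth N*/T* intensity ratio on the ring.
#' @param noise_sd relative noise level (fraction of the ring peak).
#' @param seed RNG seed.
#' @param peak T* channel peak intensity.
#' @return list with matrices `ch_N`, `ch_T` and the `true_ratio`.
#' @export
gen_guv_images <- function(size = 128, radius_px = 40, ring_width_px = 5,
                           true_ratio = 1.5, noise_sd = 0.01, seed = 1,
                           peak = 1) {
  stopifnot(radius_px > ring_width_px, true_ratio > 0, noise_sd >= 0)
  set.seed(seed)
  cx <- (size + 1) / 2
  r <- sqrt(outer((seq_len(size) - cx)^2, (seq_len(size) - cx)^2, "+"))
  ring <- peak * exp(-(r - radius_px)^2 / (2 * ring_width_px^2))
  ch_T <- ring + matrix(stats::rnorm(size^2, 0, noise_sd * peak), size)
  ch_N <- true_ratio * ring +
    matrix(stats::rnorm(size^2, 0, noise_sd * peak * true_ratio), size)
  list(ch_N = pmax(ch_N, 0), ch_T = pmax(ch_T, 0), true_ratio = true_ratio)
}
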