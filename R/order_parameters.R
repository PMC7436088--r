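#' Instantaneous deuterium order parameter of one bond
#'
#' `(3*cos^2(theta) - 1) / 2` for the angle `theta` between a C-D (C-H) bond
#' vector and the bilayer normal. Invariant to the magnitude and sign of
#' either vector; range `[-0.5, 1]`.
#'
#' @param cd_vector numeric length-3 bond vector.
#' @param normal bilayer normal (default z).
#' @return unitless order parameter.
#' @examples
#' instantaneous_scd(c(0, 0, 1))   #  1.0
#' instantaneous_scd(c(1, 0, 0))   # -0.5
#' @export
instantaneous_scd <- function(cd_vector, normal = c(0, 0, 1)) {
  if (length(cd_vector) != 3 || length(normal) != 3)
    stopf("vectors must have length 3")
  nb <- vec_norm(cd_vector); nn <- vec_norm(normal)
  if (nb == 0 || nn == 0)
    stopf("invalid geometry: zero-length vector")
  p2(sum(cd_vector * normal) / (nb * nn))
}

# vectorised: order parameter of each row of V against the z axis
scd_rows <- function(V) {
  p2(V[, 3] / sqrt(rowSums(V^2)))
}

tetra <- acos(-1 / 3)      # exact tetrahedral angle
half_tetra <- tetra / 2    # half the H-C-H angle

# orthonormal basis perpendicular to each row of unit matrix D (n x 3).
# Reference axis z, falling back to x where D is (anti)parallel to z.
perp_basis <- function(D) {
  ref <- matrix(rep(c(0, 0, 1), each = nrow(D)), ncol = 3)
  par <- abs(D[, 3]) > 0.999
  if (any(par)) ref[par, ] <- matrix(rep(c(1, 0, 0), each = sum(par)), ncol = 3)
  e1 <- cbind(ref[, 2] * D[, 3] - ref[, 3] * D[, 2],
              ref[, 3] * D[, 1] - ref[, 1] * D[, 3],
              ref[, 1] * D[, 2] - ref[, 2] * D[, 1])
  e1 <- unit_rows(e1)
  e2 <- cbind(D[, 2] * e1[, 3] - D[, 3] * e1[, 2],
              D[, 3] * e1[, 1] - D[, 1] * e1[, 3],
              D[, 1] * e1[, 2] - D[, 2] * e1[, 1])
  list(e1 = e1, e2 = unit_rows(e2))
}

# methylene H pair: perpendicular to D, split by the tetrahedral angle.
# phase rotates the pair in the perpendicular plane. The default 45 degrees
# straddles the diagonal of the (e1, e2) frame, which makes the pair-averaged
# order parameter equal to the azimuthal average for any chain tilt, so the
# reconstruction carries no orientation bias for saturated mid-chain carbons.
ch_pair <- function(D, phase = pi / 4) {
  b <- perp_basis(D)
  u1 <- cos(phase + half_tetra) * b$e1 + sin(phase + half_tetra) * b$e2
  u2 <- cos(phase - half_tetra) * b$e1 + sin(phase - half_tetra) * b$e2
  list(u1, u2)
}

# terminal methyl: three H at the tetrahedral angle from the chain end
ch_methyl <- function(D) {
  b <- perp_basis(D)
  lapply(c(0, 2 * pi / 3, 4 * pi / 3), function(phi)
    cos(tetra) * D + sin(tetra) * (cos(phi) * b$e1 + sin(phi) * b$e2))
}

#' Reconstruct C-H unit vectors from a carbon skeleton
#'
#' For hydrogen-free structures. A saturated methylene carbon gets two unit
#' vectors perpendicular to the local chain direction `C(i-1) -> C(i+1)`,
#' split symmetrically by the tetrahedral angle; an sp2 (double-bond) carbon
#' gets the single in-plane vinyl vector; a terminal methyl gets three
#' vectors at tetrahedral angles from the last bond; the first carbon uses
#' its only neighbour as the local direction.
#'
#' @param carbons_xyz m x 3 matrix of one chain's carbon coordinates, in
#'   acyl order.
#' @param index carbon position (1-based) to reconstruct.
#' @param sp2 is this carbon part of a double bond?
#' @return k x 3 matrix of unit C-H vectors (k = 1, 2 or 3).
#' @export
reconstruct_ch_vectors <- function(carbons_xyz, index, sp2 = FALSE) {
  m <- nrow(carbons_xyz)
  if (m < 3)
    stopf("reconstruction error: chain has %d carbons, need at least 3", m)
  if (index < 1 || index > m)
    stopf("reconstruction error: carbon %d outside chain of length %d",
          index, m)
  C <- carbons_xyz
  if (sp2) {
    if (index == 1 || index == m)
      stopf("reconstruction error: sp2 carbon %d needs both neighbours", index)
    u <- -(unit(C[index - 1, ] - C[index, ]) + unit(C[index + 1, ] - C[index, ]))
    return(matrix(unit(u), ncol = 3))
  }
  if (index == 1) {
    D <- matrix(unit(C[2, ] - C[1, ]), ncol = 3)
    return(do.call(rbind, ch_pair(D)))
  }
  if (index == m) {
    D <- matrix(unit(C[m - 1, ] - C[m, ]), ncol = 3)  # pointing back up-chain
    return(do.call(rbind, ch_methyl(D)))
  }
  D <- matrix(unit(C[index + 1, ] - C[index - 1, ]), ncol = 3)
  do.call(rbind, ch_pair(D))
}

# reconstruction across many lipids at once: Cm1/Cc/Cp1 are n x 3 matrices
# (neighbour may be NA-free by construction). kind: "mid", "first", "last",
# "sp2". Returns list of n x 3 unit-vector matrices.
reconstruct_rows <- function(Cm1, Cc, Cp1, kind) {
  switch(kind,
    mid   = ch_pair(unit_rows(Cp1 - Cm1)),
    first = ch_pair(unit_rows(Cp1 - Cc)),
    last  = ch_methyl(unit_rows(Cm1 - Cc)),
    sp2   = list(-unit_rows(unit_rows(Cm1 - Cc) + unit_rows(Cp1 - Cc))))
}

#' Per-carbon SCD profile of an acyl chain
#'
#' Averages the instantaneous order parameter of every C-H (C-D) bond of a
#' chain over the selected lipids and frames. With explicit hydrogens in the
#' topology the measured bonds are used; otherwise C-H directions are
#' reconstructed from the carbon skeleton (see [reconstruct_ch_vectors()]).
#' Values are reported as `|S_CD|` (the usual plotting convention under
#' which ordered plateaus sit near 0.2-0.4 and the disordered tail
#' approaches 0); the signed mean is retained in `scd_signed`.
#'
#' @param trajectory an `mp_trajectory`.
#' @param topology the lipid topology.
#' @param chain chain id, e.g. `"sn1"` or `"sn2"`.
#' @param probe_residue if non-`NULL`, restrict to lipids within `cutoff`
#'   Angstrom of this residue, re-selected in every frame.
#' @param cutoff near-probe cutoff in Angstrom.
#' @param frames `"averaged"` for one profile over all frames, or
#'   `"per_frame"` for a list with one profile per frame.
#' @param hydrogens `"auto"` uses explicit hydrogens when the topology
#'   declares them, `"explicit"` requires them, `"reconstruct"` forces
#'   skeleton reconstruction.
#' @return an `mp_order_profile`, or a list of them when
#'   `frames = "per_frame"`.
#' @export
scd_profile <- function(trajectory, topology, chain = "sn1",
                        probe_residue = NULL, cutoff = 5,
                        frames = c("averaged", "per_frame"),
                        hydrogens = c("auto", "explicit", "reconstruct")) {
  stopifnot(inherits(trajectory, "mp_trajectory"),
            inherits(topology, "mp_topology"))
  frames <- match.arg(frames)
  hydrogens <- match.arg(hydrogens)
  if (!chain %in% names(topology$chains))
    stopf("chain '%s' not in topology (has: %s)", chain,
          paste(names(topology$chains), collapse = ", "))
  ch <- topology$chains[[chain]]
  m <- length(ch$carbons)
  f1 <- trajectory$frames[[1]]
  lip_rid <- sort(unique(f1$residue_ids[f1$residue_names == topology$name]))
  if (length(lip_rid) == 0) stopf("no '%s' residues in frame", topology$name)

  use_h <- switch(hydrogens,
    auto = !is.null(ch$hydrogens),
    explicit = if (is.null(ch$hydrogens))
      stopf("topology declares no hydrogens for chain '%s'", chain) else TRUE,
    reconstruct = FALSE)

  # atom row indices, constant across frames by trajectory invariant
  key <- paste(f1$residue_ids, f1$atom_names)
  cidx <- sapply(ch$carbons, function(a) match(paste(lip_rid, a), key))
  if (is.null(dim(cidx))) cidx <- matrix(cidx, nrow = length(lip_rid))
  if (any(is.na(cidx)))
    stopf("topology mismatch: chain '%s' carbons missing from some lipid",
          chain)
  hidx <- NULL
  if (use_h) {
    hidx <- lapply(seq_len(m), function(j) {
      hs <- ch$hydrogens[[j]]
      if (length(hs) == 0) return(NULL)
      ix <- sapply(hs, function(a) match(paste(lip_rid, a), key))
      if (is.null(dim(ix))) ix <- matrix(ix, nrow = length(lip_rid))
      if (any(is.na(ix)))
        stopf("explicit hydrogens of carbon %d absent from structure", j)
      ix
    })
  }
  sp2 <- seq_len(m) %in% ch$double_bonds

  profile_of <- function(fr_set, scope) {
    s_sum <- numeric(m); s_n <- numeric(m); n_sel <- numeric(0)
    for (fi in seq_along(fr_set)) {
      fr <- fr_set[[fi]]
      if (is.null(probe_residue)) {
        rows <- seq_along(lip_rid)
      } else {
        sel <- select_near_probe(fr, topology, probe_residue, cutoff)
        rows <- which(lip_rid %in% sel)
      }
      if (length(rows) == 0)
        stopf("empty selection: no lipids within %.3g A of residue %s at t = %g ns",
              cutoff, probe_residue, fr$time)
      n_sel <- c(n_sel, length(rows))
      X <- fr$xyz
      for (j in seq_len(m)) {
        Cc <- X[cidx[rows, j], , drop = FALSE]
        if (use_h && !is.null(hidx[[j]])) {
          for (k in seq_len(ncol(hidx[[j]]))) {
            V <- X[hidx[[j]][rows, k], , drop = FALSE] - Cc
            s <- scd_rows(V)
            s_sum[j] <- s_sum[j] + sum(s); s_n[j] <- s_n[j] + length(s)
          }
        } else {
          if (m < 3)
            stopf("reconstruction error: chain has %d carbons, need at least 3", m)
          kind <- if (sp2[j]) "sp2" else if (j == 1) "first"
                  else if (j == m) "last" else "mid"
          Cm1 <- if (j > 1) X[cidx[rows, j - 1], , drop = FALSE] else Cc
          Cp1 <- if (j < m) X[cidx[rows, j + 1], , drop = FALSE] else Cc
          for (U in reconstruct_rows(Cm1, Cc, Cp1, kind)) {
            s <- p2(U[, 3])
            s_sum[j] <- s_sum[j] + sum(s); s_n[j] <- s_n[j] + length(s)
          }
        }
      }
    }
    signed <- s_sum / s_n
    structure(list(
      chain = chain, carbon = seq_len(m),
      scd = abs(signed), scd_signed = signed, sp2 = sp2,
      n_bonds = s_n, n_lipids_used = mean(n_sel),
      selection = if (is.null(probe_residue)) "all"
                  else sprintf("within %.3g A of residue %s", cutoff,
                               probe_residue),
      frame_scope = scope,
      hydrogens = if (use_h) "explicit" else "reconstructed"),
      class = "mp_order_profile")
  }

  if (frames == "averaged") {
    profile_of(trajectory$frames, "averaged")
  } else {
    lapply(trajectory$frames, function(fr)
      profile_of(list(fr), sprintf("single frame t = %g ns", fr$time)))
  }
}

#' @export
print.mp_order_profile <- function(x, ...) {
  cat(sprintf("SCD profile, chain %s (%s H, %s, %s)\n", x$chain, x$hydrogens,
              x$selection, x$frame_scope))
  print(round(stats::setNames(x$scd, paste0("C", x$carbon)), 3))
  invisible(x)
}

#' @export
as.data.frame.mp_order_profile <- function(x, ...) {
  data.frame(chain = x$chain, carbon = x$carbon, scd = x$scd,
             scd_signed = x$scd_signed, sp2 = x$sp2, n_bonds = x$n_bonds)
}
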