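#' Construct a single membrane snapshot
#'
#' A frame holds per-atom coordinates (Angstrom), atom and residue labels,
#' the orthorhombic box edges and a time stamp. The bilayer normal is the
#' z axis by convention throughout the package.
#'
#' @param xyz numeric n x 3 matrix of coordinates in Angstrom.
#' @param atom_names character vector of atom names, length n.
#' @param residue_ids integer vector of residue numbers, length n.
#' @param residue_names character vector of residue names, length n.
#' @param box numeric length-3 vector `(Lx, Ly, Lz)` in Angstrom.
#' @param time frame time in ns.
#' @return an object of class `mp_frame`.
#' @export
membrane_frame <- function(xyz, atom_names, residue_ids, residue_names,
                           box, time = 0) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3) stopf("'xyz' must have 3 columns")
  n <- nrow(xyz)
  if (n == 0) stopf("a frame needs at least one atom")
  if (!all(is.finite(xyz))) stopf("non-finite coordinates in frame")
  if (length(atom_names) != n || length(residue_ids) != n ||
      length(residue_names) != n)
    stopf("atom_names, residue_ids, residue_names must match nrow(xyz)")
  box <- as.numeric(box)
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
    stopf("'box' must be 3 positive finite edge lengths")
  structure(
    list(xyz = xyz, atom_names = as.character(atom_names),
         residue_ids = as.integer(residue_ids),
         residue_names = as.character(residue_names),
         box = box, time = as.numeric(time)),
    class = "mp_frame")
}

#' @export
print.mp_frame <- function(x, ...) {
  cat(sprintf("Membrane frame: %d atoms, %d residues, box %.1f x %.1f x %.1f A, t = %g ns\n",
              nrow(x$xyz), length(unique(x$residue_ids)),
              x$box[1], x$box[2], x$box[3], x$time))
  invisible(x)
}

#' Construct a trajectory from a list of frames
#'
#' @param frames list of [membrane_frame()] objects with strictly increasing
#'   times and a shared atom count/ordering.
#' @param label optional [system_label()].
#' @return an object of class `mp_trajectory`.
#' @export
membrane_trajectory <- function(frames, label = NULL) {
  if (length(frames) == 0) stopf("empty trajectory")
  if (!all(vapply(frames, inherits, logical(1), "mp_frame")))
    stopf("all elements must be mp_frame objects")
  times <- vapply(frames, `[[`, numeric(1), "time")
  if (length(times) > 1 && any(diff(times) <= 0))
    stopf("frame times must be strictly increasing")
  n <- vapply(frames, function(f) nrow(f$xyz), integer(1))
  if (length(unique(n)) != 1)
    stopf("all frames must share the same atom count")
  nm <- frames[[1]]$atom_names
  ok <- vapply(frames, function(f) identical(f$atom_names, nm), logical(1))
  if (!all(ok)) stopf("all frames must share the same atom ordering")
  structure(list(frames = frames, label = label), class = "mp_trajectory")
}

#' @export
print.mp_trajectory <- function(x, ...) {
  t1 <- x$frames[[1]]$time; t2 <- x$frames[[length(x$frames)]]$time
  cat(sprintf("Membrane trajectory: %d frames, %g-%g ns, %d atoms/frame\n",
              length(x$frames), t1, t2, nrow(x$frames[[1]]$xyz)))
  if (!is.null(x$label))
    cat(sprintf("  system: %s / probe %s\n", x$label$membrane,
                x$label$probe_state))
  invisible(x)
}

#' @export
length.mp_trajectory <- function(x) length(x$frames)

frame_times <- function(trajectory)
  vapply(trajectory$frames, `[[`, numeric(1), "time")

#' Label a membrane system
#'
#' @param membrane one of `"POPC"`, `"DPPC-Chol"`.
#' @param probe_state one of `"none"`, `"N"`, `"N*"`, `"T*"` — the
#'   3-hydroxyflavone probe tautomer present, if any.
#' @return a `system_label` list.
#' @export
system_label <- function(membrane = c("POPC", "DPPC-Chol"),
                         probe_state = c("none", "N", "N*", "T*")) {
  list(membrane = match.arg(membrane), probe_state = match.arg(probe_state))
}

# ---- structure file I/O ----------------------------------------------------

#' Read a multi-model PDB trajectory
#'
#' One `MODEL`/`ENDMDL` block per frame. The box is taken from the `CRYST1`
#' record when present and otherwise falls back to the axis-aligned bounding
#' box of each frame. Frame times come from `REMARK 250 TIME_NS` records
#' (written by [write_structure()]), from the `times` argument, or default to
#' a 0.5 ns cadence starting at 0.
#'
#' @param path multi-model PDB file.
#' @param topology [lipid_topology()] of the lipid species; every residue
#'   with that name must contain the phosphorus and all chain carbon atoms.
#' @param times optional numeric vector of frame times (ns).
#' @return an `mp_trajectory`.
#' @export
read_structure <- function(path, topology, times = NULL) {
  stopifnot(inherits(topology, "mp_topology"))
  if (!file.exists(path)) stopf("cannot read structure file: %s", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) stopf("not a readable PDB file (%s): %s",
                              conditionMessage(e), path))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_models <- nrow(xyz)
  if (n_models == 0 || ncol(xyz) == 0) stopf("no models in %s", path)

  atom_names <- pdb$atom$elety
  residue_ids <- pdb$atom$resno
  residue_names <- pdb$atom$resid

  # CRYST1 / time remarks: bio3d drops them, grep the raw lines
  hdr <- readLines(path, warn = FALSE)
  cr <- grep("^CRYST1", hdr, value = TRUE)
  box <- NULL
  if (length(cr) >= 1) {
    flds <- suppressWarnings(as.numeric(c(
      substr(cr[1], 7, 15), substr(cr[1], 16, 24), substr(cr[1], 25, 33))))
    if (all(is.finite(flds)) && all(flds > 0)) box <- flds
  }
  if (is.null(times)) {
    tm <- grep("^REMARK 250 TIME_NS", hdr, value = TRUE)
    if (length(tm) == n_models)
      times <- as.numeric(sub("^REMARK 250 TIME_NS *", "", tm))
  }
  if (is.null(times)) times <- (seq_len(n_models) - 1) * 0.5
  if (length(times) != n_models)
    stopf("'times' has length %d but the file has %d models",
          length(times), n_models)

  # topology check on every lipid residue
  lip <- residue_names == topology$name
  if (any(lip)) {
    need <- c(topology$phosphorus_atom,
              unlist(lapply(topology$chains, `[[`, "carbons")))
    for (rid in unique(residue_ids[lip])) {
      have <- atom_names[lip & residue_ids == rid]
      miss <- setdiff(need, have)
      if (length(miss))
        stopf("topology mismatch: residue %s %d lacks atom(s) %s",
              topology$name, rid, paste(miss, collapse = ", "))
    }
  }

  frames <- lapply(seq_len(n_models), function(i) {
    m <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
    b <- box %||% (apply(m, 2, max) - apply(m, 2, min))
    membrane_frame(m, atom_names, residue_ids, residue_names, b, times[i])
  })
  membrane_trajectory(frames)
}

#' Write a trajectory as a multi-model PDB
#'
#' Emits a `CRYST1` record from the first frame's box and one
#' `REMARK 250 TIME_NS` record per model so that [read_structure()]
#' round-trips times. Coordinates use the standard `%8.3f` PDB precision.
#'
#' @param trajectory an `mp_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "mp_trajectory"))
  f1 <- trajectory$frames[[1]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
    f1$box[1], f1$box[2], f1$box[3]), con)
  nm <- f1$atom_names
  el <- substr(gsub("[0-9]", "", nm), 1, 1)
  # atom name column: left-aligned in cols 14-16 for short names
  nm_fmt <- ifelse(nchar(nm) < 4, sprintf(" %-3s", nm), nm)
  for (i in seq_along(trajectory$frames)) {
    fr <- trajectory$frames[[i]]
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(sprintf("REMARK 250 TIME_NS %.6f", fr$time), con)
    lines <- sprintf(
      "ATOM  %5d %s %-4s%5d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      (seq_along(nm) - 1L) %% 99999L + 1L, nm_fmt,
      substr(fr$residue_names, 1, 4), fr$residue_ids %% 10000L,
      fr$xyz[, 1], fr$xyz[, 2], fr$xyz[, 3], el)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---- leaflets, probe proximity, frame cadence ------------------------------

#' Assign lipids to bilayer leaflets
#'
#' The midplane is the mean z of all lipid phosphorus atoms; a lipid whose
#' phosphorus sits strictly above it is `"upper"`, otherwise `"lower"`
#' (ties go to `"lower"`). A warning is raised when either leaflet ends up
#' empty (degenerate bilayer).
#'
#' @param frame an `mp_frame`.
#' @param topology the lipid topology.
#' @return named character vector (`"upper"`/`"lower"`), one entry per lipid
#'   residue, names are residue ids.
#' @export
assign_leaflets <- function(frame, topology) {
  stopifnot(inherits(frame, "mp_frame"), inherits(topology, "mp_topology"))
  sel <- frame$residue_names == topology$name &
    frame$atom_names == topology$phosphorus_atom
  if (!any(sel))
    stopf("missing reference atom: no '%s' atoms in residue '%s'",
          topology$phosphorus_atom, topology$name)
  rid <- frame$residue_ids[sel]
  z <- frame$xyz[sel, 3]
  mid <- mean(z)
  lab <- ifelse(z > mid, "upper", "lower")
  names(lab) <- rid
  if (!all(c("upper", "lower") %in% lab))
    warnf("degenerate bilayer: one leaflet is empty (all P at z = midplane?)")
  lab
}

#' Select lipids within a cutoff of the probe
#'
#' A lipid is selected iff the minimum atom-atom distance between any of its
#' atoms and any probe atom is at most `cutoff`. The minimum-image convention
#' is applied in x and y (the membrane plane); z is non-periodic.
#'
#' @param frame an `mp_frame`.
#' @param topology the lipid topology (defines which residues are lipids).
#' @param probe_residue residue id of the probe.
#' @param cutoff distance cutoff in Angstrom (default 5, the near-probe
#'   shell used for the SCD fluidity analysis).
#' @return integer vector of selected lipid residue ids.
#' @export
select_near_probe <- function(frame, topology, probe_residue, cutoff = 5) {
  stopifnot(inherits(frame, "mp_frame"), cutoff > 0)
  pr <- frame$residue_ids == probe_residue
  if (!any(pr)) stopf("missing probe: residue %d not in frame", probe_residue)
  lip <- frame$residue_names == topology$name & !pr
  if (!any(lip)) return(integer())
  P <- frame$xyz[pr, , drop = FALSE]
  L <- frame$xyz[lip, , drop = FALSE]
  rid <- frame$residue_ids[lip]
  bx <- frame$box[1]; by <- frame$box[2]
  # n_lipid_atoms x n_probe_atoms squared distances, min image in x,y
  dx <- outer(L[, 1], P[, 1], "-"); dx <- dx - bx * round(dx / bx)
  dy <- outer(L[, 2], P[, 2], "-"); dy <- dy - by * round(dy / by)
  dz <- outer(L[, 3], P[, 3], "-")
  d2min <- apply(dx^2 + dy^2 + dz^2, 1, min)
  mind2 <- tapply(d2min, rid, min)
  sort(as.integer(names(mind2)[mind2 <= cutoff^2]))
}

#' Pick analysis frames on an even time grid
#'
#' Returns the frames whose times are nearest to an even grid of `n_frames`
#' points spanning the last `window_ns` of the trajectory, endpoints
#' included. Defaults mirror the production cadence of the analyses: the
#' last 5 ns as 11 frames.
#'
#' @param trajectory an `mp_trajectory` spanning at least `window_ns`.
#' @param window_ns analysis window length in ns.
#' @param n_frames number of frames to select.
#' @return an `mp_trajectory` of `n_frames` frames.
#' @export
analysis_frames <- function(trajectory, window_ns = 5, n_frames = 11) {
  stopifnot(inherits(trajectory, "mp_trajectory"), is_count(n_frames))
  times <- frame_times(trajectory)
  span <- times[length(times)] - times[1]
  if (span < window_ns)
    stopf("insufficient span: trajectory covers %.3g ns < window of %.3g ns",
          span, window_ns)
  grid <- seq(times[length(times)] - window_ns, times[length(times)],
              length.out = n_frames)
  idx <- vapply(grid, function(g) which.min(abs(times - g)), integer(1))
  membrane_trajectory(trajectory$frames[idx], trajectory$label)
}
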