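# Small builders used across test files.

# topology of a minimal one-chain lipid without hydrogens
tiny_topology <- function(n_carbons = 3, name = "LIP") {
  lipid_topology(name, "P",
                 list(sn1 = list(carbons = paste0("C", seq_len(n_carbons)))))
}

# frame of P-only lipids at given z positions (one lipid per z)
p_only_frame <- function(z, box = c(64, 64, 80), xy = NULL, name = "LIP") {
  n <- length(z)
  xy <- xy %||% cbind(runif(n, 0, box[1]), runif(n, 0, box[2]))
  membrane_frame(cbind(xy, z), rep("P", n), seq_len(n), rep(name, n), box)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# trajectory of 1-atom dummy frames at the given times
dummy_traj <- function(times) {
  membrane_trajectory(lapply(times, function(t)
    membrane_frame(matrix(c(0, 0, 0), 1), "P", 1L, "LIP", c(10, 10, 10), t)))
}

# brute-force k-mer enumeration, independent of kmer_set()
brute_kmers <- function(s, k_min, k_max) {
  out <- character()
  for (k in k_min:k_max) {
    if (nchar(s) < k) next
    for (i in 1:(nchar(s) - k + 1)) out <- c(out, substr(s, i, i + k - 1))
  }
  unique(out)
}

# encoded strings of the two chains of a generated system, one per frame
frame_strings <- function(sim, enc = encoding_config()) {
  pf <- lapply(names(sim$topology$chains), function(ch)
    scd_profile(sim$trajectory, sim$topology, ch, frames = "per_frame"))
  vapply(seq_along(pf[[1]]), function(i)
    encode_profile(lapply(pf, `[[`, i), enc), character(1))
}
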