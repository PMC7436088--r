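#' Describe the atoms of a lipid species
#'
#' A lipid topology maps a residue name to the atoms the analyses need: the
#' phosphorus atom used for leaflet assignment and thickness, and, per acyl
#' chain, the ordered carbon atom names (1-based acyl numbering starting at
#' the carbonyl carbon), optional explicit hydrogen names per carbon, and the
#' positions of double-bonded (sp2) carbons.
#'
#' @param name residue name of the species as it appears in the structure
#'   file (e.g. `"POPC"`).
#' @param phosphorus_atom atom name of the headgroup phosphorus.
#' @param chains named list with elements `sn1` and (optionally) `sn2`. Each
#'   chain is a list with `carbons` (character vector, ordered from the
#'   carbonyl carbon), optional `hydrogens` (list of character vectors, one
#'   per carbon; may contain zero-length entries), and optional
#'   `double_bonds` (integer carbon indices that are sp2).
#'
#' @return an object of class `mp_topology`.
#' @examples
#' top <- lipid_topology("DLPC",
#'   chains = list(
#'     sn1 = list(carbons = paste0("C", 1:12)),
#'     sn2 = list(carbons = paste0("D", 1:12))))
#' top
#' @export
lipid_topology <- function(name, phosphorus_atom = "P", chains) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name))
    stopf("'name' must be a single non-empty residue name")
  if (!is.list(chains) || length(chains) == 0)
    stopf("'chains' must be a non-empty list")
  if (is.null(names(chains)) || any(!nzchar(names(chains))))
    stopf("'chains' must be a named list (e.g. sn1, sn2)")
  chain_ids <- names(chains)
  chains <- lapply(chain_ids, function(id) {
    ch <- chains[[id]]
    if (is.null(ch$carbons) || length(ch$carbons) == 0)
      stopf("chain '%s' has an empty carbon list", id)
    ch$carbons <- as.character(ch$carbons)
    ch$double_bonds <- as.integer(ch$double_bonds %||% integer())
    if (any(ch$double_bonds < 1 | ch$double_bonds > length(ch$carbons)))
      stopf("chain '%s': double-bond index outside the chain", id)
    if (!is.null(ch$hydrogens)) {
      if (length(ch$hydrogens) != length(ch$carbons))
        stopf("chain '%s': 'hydrogens' must have one entry per carbon", id)
      ch$hydrogens <- lapply(ch$hydrogens, as.character)
    }
    ch
  })
  names(chains) <- chain_ids
  structure(
    list(name = name, phosphorus_atom = phosphorus_atom, chains = chains),
    class = "mp_topology")
}

#' @export
print.mp_topology <- function(x, ...) {
  cat("Lipid topology:", x$name, "\n")
  cat("  phosphorus atom:", x$phosphorus_atom, "\n")
  for (id in names(x$chains)) {
    ch <- x$chains[[id]]
    cat(sprintf("  chain %s: %d carbons%s%s\n", id, length(ch$carbons),
                if (length(ch$double_bonds))
                  paste0(", sp2 at ", paste(ch$double_bonds, collapse = ","))
                else "",
                if (!is.null(ch$hydrogens)) ", explicit H" else ""))
  }
  invisible(x)
}

#' Read or write a lipid topology configuration
#'
#' Topologies are stored as JSON or YAML (chosen from the file extension)
#' with the same fields as [lipid_topology()].
#'
#' @param path file ending in `.json`, `.yaml` or `.yml`.
#' @return `read_topology()` returns an `mp_topology`;
#'   `write_topology()` returns `path` invisibly.
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) stopf("topology file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyVector = FALSE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stopf("unsupported topology format '.%s' (use JSON or YAML)", ext))
  chains <- lapply(raw$chains, function(ch) {
    ch$carbons <- unlist(ch$carbons)
    ch$double_bonds <- unlist(ch$double_bonds)
    if (!is.null(ch$hydrogens)) ch$hydrogens <- lapply(ch$hydrogens, unlist)
    ch
  })
  lipid_topology(unlist(raw$name), unlist(raw$phosphorus_atom) %||% "P",
                 chains)
}

#' @rdname read_topology
#' @param topology an `mp_topology` object.
#' @export
write_topology <- function(topology, path) {
  stopifnot(inherits(topology, "mp_topology"))
  ext <- tolower(tools::file_ext(path))
  x <- unclass(topology)
  switch(ext,
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA),
    yaml = ,
    yml  = yaml::write_yaml(x, path),
    stopf("unsupported topology format '.%s' (use JSON or YAML)", ext))
  invisible(path)
}

# names of all chain atoms (carbons + any hydrogens) of a topology
topology_atom_names <- function(topology) {
  unlist(lapply(topology$chains, function(ch)
    c(ch$carbons, unlist(ch$hydrogens %||% list()))), use.names = FALSE)
}
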