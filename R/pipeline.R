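#' Configuration for a multi-system membrane comparison
#'
#' @param systems list of system entries. Each entry is a list with either
#'   `preset` (`"popc"` / `"dppc-chol"`) plus `probe` (`"none"`, `"N"`,
#'   `"N*"`, `"T*"`), or `path` (multi-model PDB) plus `topology`
#'   (`mp_topology` or topology file), optional `probe_residue`,
#'   `chol_fraction`, `membrane` and `name`.
#' @param cutoff near-probe selection cutoff, Angstrom.
#' @param window_ns,n_frames analysis-frame cadence (defaults: last 5 ns as
#'   11 frames).
#' @param n_lipids_per_leaflet leaflet size for generated presets.
#' @param encoding an [encoding_config()].
#' @param k_min,k_max k-mer lengths for the string distances.
#' @param perplexity t-SNE perplexity.
#' @param seed master seed; per-system generator seeds derive from it.
#' @param energies optional path to a binding-energy CSV (columns `system`,
#'   `time_ns`, `energy_kcal_mol`) or a named list of
#'   [energy_series()] objects; all pairs are Welch-tested.
#' @param confidence_threshold significance threshold for the energy tests.
#' @return an `mp_pipeline_config`.
#' @export
pipeline_config <- function(systems, cutoff = 5, window_ns = 5, n_frames = 11,
                            n_lipids_per_leaflet = 64,
                            encoding = encoding_config(), k_min = 2,
                            k_max = 8, perplexity = 10, seed = 42,
                            energies = NULL, confidence_threshold = 0.98) {
  if (length(systems) < 1) stopf("need at least one system")
  structure(list(systems = systems, cutoff = cutoff, window_ns = window_ns,
                 n_frames = n_frames,
                 n_lipids_per_leaflet = n_lipids_per_leaflet,
                 encoding = encoding, k_min = k_min, k_max = k_max,
                 perplexity = perplexity, seed = seed, energies = energies,
                 confidence_threshold = confidence_threshold),
            class = "mp_pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file holds the same fields as [pipeline_config()]; `systems` is a
#' list of entries as described there.
#'
#' @param path config file (`.yaml`, `.yml` or `.json`).
#' @return an `mp_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stopf("unsupported config format '.%s'", ext))
  args <- raw
  if (!is.null(raw$encoding))
    args$encoding <- do.call(encoding_config, raw$encoding)
  do.call(pipeline_config, args)
}

#' The six-system comparison of the fluidity analyses
#'
#' Convenience constructor for the standard design: each membrane
#' composition alone and with the probe in its two excited tautomer states.
#'
#' @param probe_states probe states added to each membrane besides
#'   `"none"`.
#' @param ... passed to [pipeline_config()].
#' @return an `mp_pipeline_config` with 6 systems (2 membranes x 3 states).
#' @export
default_six_systems <- function(probe_states = c("N*", "T*"), ...) {
  systems <- list()
  for (preset in c("popc", "dppc-chol"))
    for (probe in c("none", probe_states))
      systems[[length(systems) + 1]] <- list(preset = preset, probe = probe)
  pipeline_config(systems, ...)
}

load_system <- function(entry, config, i) {
  if (!is.null(entry$preset)) {
    spec <- bilayer_preset(entry$preset, entry$probe %||% "none",
                           n_lipids_per_leaflet =
                             config$n_lipids_per_leaflet,
                           seed = config$seed + i)
    # generate enough cadence to cover the analysis window with headroom
    n_gen <- max(config$n_frames + 4, ceiling(config$window_ns / 0.5) + 1)
    sim <- gen_bilayer(spec, n_frames = n_gen, frame_spacing_ns = 0.5,
                       start_time_ns = 15 - 0.5 * (n_gen - 1))
    list(trajectory = sim$trajectory, topology = sim$topology,
         probe_residue = sim$ground_truth$probe_residue,
         chol_fraction = spec$chol_fraction,
         membrane = spec$membrane,
         name = entry$name %||%
           paste0(spec$membrane,
                  if (spec$probe != "none") paste0("+", spec$probe)))
  } else {
    top <- entry$topology
    if (is.character(top)) top <- read_topology(top)
    traj <- read_structure(entry$path, top)
    list(trajectory = traj, topology = top,
         probe_residue = entry$probe_residue,
         chol_fraction = entry$chol_fraction %||% 0,
         membrane = entry$membrane %||% top$name,
         name = entry$name %||% basename(entry$path))
  }
}

#' Run the full membrane-comparison pipeline
#'
#' For every system: select analysis frames, compute thickness and area per
#' lipid, per-frame SCD profiles for each chain (restricted to lipids near
#' the probe when one is present), and one encoded string per frame. Across
#' systems: the pooled k-mer overlap distance matrix, a 2-D t-SNE
#' embedding, and the silhouette of the membrane-composition grouping.
#' When binding-energy series are supplied, all pairs are compared with
#' Welch tests. Identical configuration and seed reproduce identical
#' outputs.
#'
#' @param config an `mp_pipeline_config`.
#' @param output_dir if non-`NULL`, write `metrics.csv`, `scd.csv`,
#'   `strings.tsv`, `distances.csv`, `embedding.csv`, `silhouette.json`,
#'   `ttests.json` and `manifest.json` there.
#' @param verbose log each stage via `message()`.
#' @return an `mp_pipeline_report` (list) with per-system metrics and
#'   profiles, the strings table, distances, embedding, silhouette and
#'   energy-test results.
#' @export
run_pipeline <- function(config, output_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "mp_pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  systems <- list()
  strings <- character(); str_sys <- character(); str_mem <- character()
  str_time <- numeric()
  metrics_rows <- list(); scd_rows_out <- list()

  for (i in seq_along(config$systems)) {
    sys <- load_system(config$systems[[i]], config, i)
    say("[%s] loaded: %d frames", sys$name, length(sys$trajectory))
    traj <- analysis_frames(sys$trajectory, config$window_ns, config$n_frames)
    met <- bilayer_metrics(traj, sys$topology, sys$chol_fraction)
    say("[%s] thickness %.2f A, A_l %.2f A^2", sys$name, met$thickness_mean,
        met$apl_mean)
    metrics_rows[[i]] <- data.frame(
      system = sys$name, frame_time_ns = met$per_frame_time,
      thickness_A = met$per_frame_thickness,
      apl_A2 = met$per_frame_area_per_lipid)

    chain_ids <- names(sys$topology$chains)
    per_frame <- lapply(chain_ids, function(chid)
      scd_profile(traj, sys$topology, chid,
                  probe_residue = sys$probe_residue, cutoff = config$cutoff,
                  frames = "per_frame"))
    names(per_frame) <- chain_ids
    avg <- lapply(chain_ids, function(chid)
      scd_profile(traj, sys$topology, chid,
                  probe_residue = sys$probe_residue, cutoff = config$cutoff))
    names(avg) <- chain_ids
    scd_rows_out[[i]] <- do.call(rbind, lapply(chain_ids, function(chid)
      cbind(system = sys$name, as.data.frame(avg[[chid]]))))

    times <- frame_times(traj)
    for (fi in seq_along(times)) {
      s <- encode_profile(lapply(chain_ids, function(chid)
        per_frame[[chid]][[fi]]), config$encoding)
      strings <- c(strings, s)
      str_sys <- c(str_sys, sys$name)
      str_mem <- c(str_mem, sys$membrane)
      str_time <- c(str_time, times[fi])
    }
    say("[%s] %d encoded strings", sys$name, length(times))
    systems[[sys$name]] <- list(metrics = met, scd = avg,
                                membrane = sys$membrane)
  }

  strings_df <- data.frame(system = str_sys, membrane = str_mem,
                           time_ns = str_time, string = strings)
  distances <- NULL; embedding <- NULL; silhouette <- NULL
  if (length(config$systems) >= 2) {
    labels <- sprintf("%s@%gns", str_sys, str_time)
    distances <- string_distance_matrix(strings, labels, config$k_min,
                                        config$k_max)
    embedding <- embed_2d(distances, seed = config$seed,
                          perplexity = config$perplexity)
    silhouette <- cluster_quality(distances, str_mem)
    say("distance matrix %dx%d, silhouette (membrane grouping) %.3f",
        nrow(distances$d), ncol(distances$d), silhouette)
  } else {
    say("single system: clustering stage skipped")
  }

  ttests <- NULL
  if (!is.null(config$energies)) {
    en <- config$energies
    if (is.character(en)) en <- read_energy_csv(en)
    pairs <- utils::combn(names(en), 2, simplify = FALSE)
    ttests <- lapply(pairs, function(pr) {
      wt <- welch_t_test(en[[pr[1]]], en[[pr[2]]])
      c(list(a = pr[1], b = pr[2]), wt,
        significance_report(wt$p, config$confidence_threshold))
    })
    say("%d pairwise Welch tests", length(ttests))
  }

  report <- structure(list(
    systems = systems, strings = strings_df, distances = distances,
    embedding = embedding, silhouette = silhouette, ttests = ttests,
    metrics_table = do.call(rbind, metrics_rows),
    scd_table = do.call(rbind, scd_rows_out),
    config = config), class = "mp_pipeline_report")

  if (!is.null(output_dir)) write_report(report, output_dir, verbose)
  report
}

write_report <- function(report, output_dir, verbose = TRUE) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(output_dir, f)
  utils::write.csv(report$metrics_table, p("metrics.csv"), row.names = FALSE)
  utils::write.csv(report$scd_table, p("scd.csv"), row.names = FALSE)
  utils::write.table(report$strings, p("strings.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  files <- c("metrics.csv", "scd.csv", "strings.tsv")
  if (!is.null(report$distances)) {
    utils::write.csv(report$distances$d, p("distances.csv"))
    emb <- data.frame(label = report$embedding$labels,
                      x = report$embedding$coords[, 1],
                      y = report$embedding$coords[, 2])
    utils::write.csv(emb, p("embedding.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(silhouette = report$silhouette, grouping = "membrane"),
      p("silhouette.json"), auto_unbox = TRUE, digits = NA)
    files <- c(files, "distances.csv", "embedding.csv", "silhouette.json")
  }
  if (!is.null(report$ttests)) {
    jsonlite::write_json(report$ttests, p("ttests.json"), auto_unbox = TRUE,
                         digits = NA)
    files <- c(files, "ttests.json")
  }
  cfg <- report$config
  manifest <- list(
    parameters = list(
      cutoff = cfg$cutoff, window_ns = cfg$window_ns,
      n_frames = cfg$n_frames,
      n_lipids_per_leaflet = cfg$n_lipids_per_leaflet,
      encoding = unclass(cfg$encoding)[c("scd_low", "scd_high")],
      k_min = cfg$k_min, k_max = cfg$k_max, perplexity = cfg$perplexity,
      seed = cfg$seed, systems = cfg$systems),
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(output_dir, files))), files)))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (verbose) message(sprintf("wrote %d files to %s", length(files) + 1,
                               output_dir))
  invisible(output_dir)
}

#' @export
print.mp_pipeline_report <- function(x, ...) {
  cat(sprintf("Pipeline report: %d system(s), %d encoded strings\n",
              length(x$systems), nrow(x$strings)))
  for (nm in names(x$systems)) {
    m <- x$systems[[nm]]$metrics
    cat(sprintf("  %-16s thickness %6.2f A   A_l %6.2f A^2\n", nm,
                m$thickness_mean, m$apl_mean))
  }
  if (!is.null(x$silhouette))
    cat(sprintf("  silhouette (membrane grouping): %.3f\n", x$silhouette))
  invisible(x)
}
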