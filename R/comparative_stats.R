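#' Per-frame binding-energy series
#'
#' @param values binding energies (kcal/mol), finite, length >= 2.
#' @param times optional frame times in ns, strictly increasing.
#' @param label optional [system_label()] or string.
#' @return an `mp_energy_series`.
#' @export
energy_series <- function(values, times = NULL, label = NULL) {
  values <- as.numeric(values)
  if (length(values) < 2) stopf("an energy series needs at least 2 values")
  if (any(!is.finite(values))) stopf("non-finite energies")
  if (!is.null(times)) {
    if (length(times) != length(values)) stopf("times/values length mismatch")
    if (any(diff(times) <= 0)) stopf("times must be strictly increasing")
  }
  structure(list(values = values, times = times, label = label),
            class = "mp_energy_series")
}

#' Read binding-energy series from CSV
#'
#' Expected columns: `system`, `time_ns`, `energy_kcal_mol`. Binding
#' energies are an input here — they come from the MD engine, never from
#' this package.
#'
#' @param path CSV file.
#' @return named list of `mp_energy_series`, one per system.
#' @export
read_energy_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("system", "time_ns", "energy_kcal_mol")
  if (!all(need %in% names(df)))
    stopf("energy CSV must have columns: %s", paste(need, collapse = ", "))
  out <- lapply(split(df, df$system), function(s) {
    s <- s[order(s$time_ns), ]
    energy_series(s$energy_kcal_mol, s$time_ns, s$system[1])
  })
  out
}

#' Welch two-sample t test on binding-energy series
#'
#' Unequal-variance (Welch) t statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p value — the safe default when the two membrane
#' systems fluctuate differently.
#'
#' @param a,b `mp_energy_series` objects or numeric vectors (length >= 2,
#'   with nonzero variance in at least one).
#' @return list with `t`, `df`, `p`.
#' @export
welch_t_test <- function(a, b) {
  x <- if (inherits(a, "mp_energy_series")) a$values else as.numeric(a)
  y <- if (inherits(b, "mp_energy_series")) b$values else as.numeric(b)
  if (length(x) < 2 || length(y) < 2)
    stopf("each series needs at least 2 values")
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stopf("degenerate data: both series have zero variance%s",
          if (mean(x) == mean(y)) " and equal means" else "")
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Significance verdict at a confidence threshold
#'
#' A comparison is called significant when `1 - p` strictly exceeds the
#' threshold; the default 0.98 corresponds to demanding over 98%
#' probability of statistical significance.
#'
#' @param p two-sided p value in `(0, 1]`.
#' @param confidence_threshold fraction in `(0, 1)`.
#' @return list with `p`, `one_minus_p`, `threshold`, `significant`.
#' @export
significance_report <- function(p, confidence_threshold = 0.98) {
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p > 1)
    stopf("configuration error: p must be in (0, 1]")
  if (!is.numeric(confidence_threshold) || confidence_threshold <= 0 ||
      confidence_threshold >= 1)
    stopf("configuration error: threshold must be in (0, 1)")
  list(p = p, one_minus_p = 1 - p, threshold = confidence_threshold,
       significant = (1 - p) > confidence_threshold)
}
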