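#' Letter-encoding configuration for SCD profiles
#'
#' Uniform-width bins over `[scd_low, scd_high]` mapped onto an ordered
#' alphabet. The default 26 letters over `[0, 0.52]` give 0.02 resolution
#' on `|S_CD|`, covering the range acyl-chain order parameters occupy.
#'
#' @param scd_low,scd_high range bounds, `scd_low < scd_high`.
#' @param alphabet ordered letters, at least 2.
#' @return an `mp_encoding` list.
#' @export
encoding_config <- function(scd_low = 0, scd_high = 0.52, alphabet = LETTERS) {
  if (!(scd_low < scd_high)) stopf("scd_low must be < scd_high")
  alphabet <- as.character(alphabet)
  if (length(alphabet) < 2) stopf("alphabet needs at least 2 letters")
  structure(list(scd_low = scd_low, scd_high = scd_high, alphabet = alphabet,
                 bin_width = (scd_high - scd_low) / length(alphabet)),
            class = "mp_encoding")
}

#' Encode SCD profiles as a letter string
#'
#' Each per-carbon `|S_CD|` value becomes one letter: bin index
#' `floor((scd - scd_low) / bin_width)`, with the top edge mapping to the
#' last letter. Profiles are concatenated in the order given (conventionally
#' sn-1 then sn-2), carbons in increasing index. Values outside the range
#' are clamped with a warning.
#'
#' @param profiles an `mp_order_profile`, a numeric vector of `|S_CD|`
#'   values, or a list of either (concatenated in order).
#' @param config an [encoding_config()].
#' @return a single character string, one letter per carbon.
#' @examples
#' encode_profile(c(0.21, 0.21, 0.05))   # "KKC" under the defaults
#' @export
encode_profile <- function(profiles, config = encoding_config()) {
  stopifnot(inherits(config, "mp_encoding"))
  if (inherits(profiles, "mp_order_profile") || is.numeric(profiles))
    profiles <- list(profiles)
  vals <- unlist(lapply(profiles, function(p)
    if (inherits(p, "mp_order_profile")) p$scd else as.numeric(p)))
  if (length(vals) == 0) stopf("empty profile: nothing to encode")
  if (any(vals < config$scd_low | vals > config$scd_high)) {
    warnf("%d SCD value(s) outside [%g, %g] clamped before encoding",
          sum(vals < config$scd_low | vals > config$scd_high),
          config$scd_low, config$scd_high)
    vals <- pmin(pmax(vals, config$scd_low), config$scd_high)
  }
  nb <- length(config$alphabet)
  bin <- pmin(floor((vals - config$scd_low) / config$bin_width), nb - 1)
  paste(config$alphabet[bin + 1], collapse = "")
}

#' All contiguous k-mers of a string
#'
#' The set (unique values) of contiguous substrings of every length `k` in
#' `[k_min, k_max]`, skipping lengths exceeding the string.
#'
#' @param s a character string with `nchar(s) >= k_min`.
#' @param k_min,k_max substring length bounds, `2 <= k_min <= k_max`.
#' @return character vector of unique k-mers.
#' @export
kmer_set <- function(s, k_min = 2, k_max = 8) {
  stopifnot(k_min >= 2, k_min <= k_max)
  n <- nchar(s)
  if (n < k_min)
    stopf("short string: length %d < k_min = %d", n, k_min)
  out <- unlist(lapply(k_min:min(k_max, n), function(k)
    substring(s, 1:(n - k + 1), k:n)))
  unique(out)
}

#' Szymkiewicz-Simpson overlap coefficient
#'
#' `|a intersect b| / min(|a|, |b|)`: 1 when one set contains the other,
#' 0 when disjoint.
#'
#' @param a,b non-empty sets (character vectors; duplicates ignored).
#' @return similarity in `[0, 1]`.
#' @export
overlap_coefficient <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 || length(b) == 0)
    stopf("empty set in overlap coefficient")
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Pairwise pseudo-semantic distance matrix
#'
#' Distance between two encoded strings is `1 - overlap`, where overlap is
#' the Szymkiewicz-Simpson coefficient of their k-mer sets. In the default
#' `"pooled"` mode all k-mer lengths contribute to one set per string; in
#' `"per_k"` mode the coefficient is computed per length and averaged over
#' the lengths valid for both strings. The overlap distance is symmetric
#' with a zero diagonal but need not satisfy the triangle inequality.
#'
#' @param strings character vector of encoded strings.
#' @param labels optional row/col labels (default names or indices).
#' @param k_min,k_max k-mer length bounds.
#' @param pooling `"pooled"` or `"per_k"`.
#' @param drop_duplicates remove exact duplicate strings first (the
#'   redundancy-elimination preprocessing; disabled by default).
#' @return an `mp_distances` object: `$d` (symmetric matrix in `[0,1]`),
#'   `$labels`, `$strings`.
#' @export
string_distance_matrix <- function(strings, labels = NULL, k_min = 2,
                                   k_max = 8,
                                   pooling = c("pooled", "per_k"),
                                   drop_duplicates = FALSE) {
  pooling <- match.arg(pooling)
  labels <- labels %||% names(strings) %||% as.character(seq_along(strings))
  if (drop_duplicates) {
    keep <- !duplicated(strings)
    strings <- strings[keep]; labels <- labels[keep]
  }
  n <- length(strings)
  if (n < 2) stopf("need at least 2 strings")
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  if (pooling == "pooled") {
    sets <- lapply(strings, kmer_set, k_min = k_min, k_max = k_max)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      d[i, j] <- d[j, i] <- 1 - overlap_coefficient(sets[[i]], sets[[j]])
  } else {
    per_k <- lapply(strings, function(s)
      lapply(k_min:k_max, function(k)
        if (nchar(s) >= k) kmer_set(s, k, k) else NULL))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      sims <- mapply(function(a, b)
        if (is.null(a) || is.null(b)) NA_real_ else overlap_coefficient(a, b),
        per_k[[i]], per_k[[j]])
      if (all(is.na(sims))) stopf("no common k-mer length for items %d, %d", i, j)
      d[i, j] <- d[j, i] <- 1 - mean(sims, na.rm = TRUE)
    }
  }
  structure(list(d = d, labels = labels, strings = strings,
                 k_min = k_min, k_max = k_max, pooling = pooling),
            class = "mp_distances")
}

#' @export
print.mp_distances <- function(x, ...) {
  cat(sprintf("Pseudo-semantic distances: %d items, k = %d..%d (%s)\n",
              nrow(x$d), x$k_min, x$k_max, x$pooling))
  invisible(x)
}

#' Embed a distance matrix in two dimensions with t-SNE
#'
#' Runs exact t-SNE on the precomputed pseudo-semantic distances (no
#' re-featurisation), deterministically for a fixed seed.
#'
#' @param distances an `mp_distances` object or a symmetric matrix.
#' @param seed RNG seed (default 42).
#' @param perplexity t-SNE perplexity; must satisfy
#'   `3 * perplexity < n - 1`.
#' @param max_iter gradient-descent iterations.
#' @return an `mp_embedding`: `$coords` (n x 2), `$labels`, `$seed`,
#'   `$perplexity`, `$cost` (final KL divergence).
#' @export
embed_2d <- function(distances, seed = 42, perplexity = 10, max_iter = 1000) {
  d <- if (inherits(distances, "mp_distances")) distances$d
       else as.matrix(distances)
  n <- nrow(d)
  labels <- rownames(d) %||% as.character(seq_len(n))
  if (3 * perplexity >= n - 1)
    stopf("configuration error: perplexity %g too large for %d items (need 3*perplexity < n - 1)",
          perplexity, n)
  set.seed(seed)
  fit <- Rtsne::Rtsne(d, is_distance = TRUE, dims = 2, theta = 0,
                      perplexity = perplexity, max_iter = max_iter,
                      check_duplicates = FALSE, pca = FALSE, verbose = FALSE)
  structure(list(coords = fit$Y, labels = labels, seed = seed,
                 perplexity = perplexity,
                 cost = fit$itercosts[length(fit$itercosts)]),
            class = "mp_embedding")
}

#' @export
print.mp_embedding <- function(x, ...) {
  cat(sprintf("2-D embedding of %d items (seed %d, perplexity %g, KL %.3f)\n",
              nrow(x$coords), x$seed, x$perplexity, x$cost))
  invisible(x)
}

#' Silhouette score of a grouping on pseudo-semantic distances
#'
#' Mean silhouette width over all items, computed directly on the distance
#' matrix (not on the embedding), in `[-1, 1]`. Large positive values mean
#' the grouping (e.g. membrane composition) explains the distances.
#'
#' @param distances an `mp_distances` or symmetric distance matrix.
#' @param groups vector of group labels, one per item; at least 2 distinct
#'   groups.
#' @return mean silhouette width.
#' @export
cluster_quality <- function(distances, groups) {
  d <- if (inherits(distances, "mp_distances")) distances$d
       else as.matrix(distances)
  if (length(groups) != nrow(d))
    stopf("'groups' must have one label per item")
  g <- as.integer(factor(groups))
  if (length(unique(g)) < 2)
    stopf("configuration error: silhouette needs at least 2 groups")
  sil <- cluster::silhouette(g, dmatrix = d)
  mean(sil[, "sil_width"])
}
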