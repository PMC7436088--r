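# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

vec_norm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vec_norm(v)
  if (n == 0) stop("cannot normalise a zero vector", call. = FALSE)
  v / n
}

# row-wise normalisation of an n x 3 matrix
unit_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  m / n
}

# second Legendre polynomial, the order-parameter kernel
p2 <- function(x) (3 * x^2 - 1) / 2

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x >= 1 && x == round(x)

# centred moving average with partial windows at the edges, so no point is
# dropped and a monotone segment keeps its argmax position
moving_average <- function(x, width) {
  if (width <= 1) return(x)
  half <- floor(width / 2)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}
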