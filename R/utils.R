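# Internal helpers shared across modules.

# Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}

# Derive a reproducible child seed from a parent seed and an index.
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(index)) %% 2147483647)
}

# Voxel spacings (um) implied by a field of view (mm) and a voxel grid.
spacing_from_fov <- function(fov_mm, shape) {
  as.numeric(fov_mm) * 1000 / as.numeric(shape)
}

# Bilinear interpolation of matrix `z` (rows = axis1 at coords x1, cols =
# axis2 at x2) onto the outer grid of `xo1`, `xo2`. Coordinates must be
# ascending and the output grid clamped inside the input extent is the
# caller's job; values outside are linearly extrapolated from the edge cell.
bilinear_grid <- function(z, x1, x2, xo1, xo2) {
  i <- findInterval(xo1, x1, all.inside = TRUE)
  j <- findInterval(xo2, x2, all.inside = TRUE)
  f1 <- (xo1 - x1[i]) / (x1[i + 1] - x1[i])
  f2 <- (xo2 - x2[j]) / (x2[j + 1] - x2[j])
  z11 <- z[i, j, drop = FALSE]; z21 <- z[i + 1, j, drop = FALSE]
  z12 <- z[i, j + 1, drop = FALSE]; z22 <- z[i + 1, j + 1, drop = FALSE]
  w1 <- matrix(f1, length(xo1), length(xo2))
  w2 <- matrix(f2, length(xo1), length(xo2), byrow = TRUE)
  z11 * (1 - w1) * (1 - w2) + z21 * w1 * (1 - w2) +
    z12 * (1 - w1) * w2 + z22 * w1 * w2
}

# Shift a numeric vector by a real-valued amount with linear interpolation;
# out[k] = v[k - s]; positions outside [1, n] get `fill`.
shift_vector <- function(v, s, fill = 0) {
  n <- length(v)
  pos <- seq_len(n) - s
  if (abs(s - round(s)) < 1e-12) {
    si <- as.integer(round(s))
    out <- rep(fill, n)
    src <- seq_len(n) - si
    ok <- src >= 1L & src <= n
    out[ok] <- v[src[ok]]
    return(out)
  }
  lo <- floor(pos)
  fr <- pos - lo
  out <- rep(as.numeric(fill), n)
  ok <- lo >= 1L & lo + 1 <= n
  out[ok] <- v[lo[ok]] * (1 - fr[ok]) + v[lo[ok] + 1L] * fr[ok]
  edge <- lo == 0L
  out[edge] <- v[1L] * fr[edge] + as.numeric(fill) * (1 - fr[edge])
  edge2 <- lo == n
  out[edge2] <- v[n] * (1 - fr[edge2]) + as.numeric(fill) * fr[edge2]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
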