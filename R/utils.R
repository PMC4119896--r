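# Internal helpers: validation, deterministic substreams, rounding.

is_point <- function(p, d) {
  is.numeric(p) && length(p) == d && all(is.finite(p))
}

assert_point3 <- function(p, what) {
  if (!is_point(p, 3L)) {
    stop(sprintf("'%s' must be a finite numeric 3-vector (mm)", what), call. = FALSE)
  }
  as.numeric(p)
}

assert_point2 <- function(p, what) {
  if (!is_point(p, 2L)) {
    stop(sprintf("'%s' must be a finite numeric 2-vector (mm)", what), call. = FALSE)
  }
  as.numeric(p)
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

vnorm <- function(v) sqrt(sum(v^2))

#' @keywords internal
#' @noRd
point_plane_distance <- function(p, plane_points, tol = 1e-9) {
  a <- plane_points[1, ]
  n <- cross3(plane_points[2, ] - a, plane_points[3, ] - a)
  nn <- vnorm(n)
  if (nn < tol) stop("degenerate occlusal plane: defining points are collinear", call. = FALSE)
  abs(sum((p - a) * n)) / nn
}

point_segment_distance <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- if (len2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / len2))
  vnorm(p - (a + t * ab))
}

# Minimum distance from a 2D point to a piecewise-linear curve.
polyline_distance <- function(p, pts) {
  d <- Inf
  for (i in seq_len(nrow(pts) - 1L)) {
    d <- min(d, point_segment_distance(p, pts[i, ], pts[i + 1L, ]))
  }
  d
}

# Deterministic named substream: a sub-seed derived from the master seed and a
# path of labels, so that e.g. adding raters never perturbs case generation.
substream_seed <- function(seed, ...) {
  parts <- paste(c(...), collapse = "/")
  h <- 5381
  for (ch in utf8ToInt(parts)) h <- (h * 31 + ch) %% 2147483647
  as.integer(((as.numeric(seed) %% 99991) * 20011 + h) %% 2147483562 + 1)
}

# Run `fun` under the substream, restoring the caller's RNG state afterwards.
with_substream <- function(seed, name, fun) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(substream_seed(seed, name))
  fun()
}

# Round half away from zero (the convention used when comparing derived
# metrics against values printed to three decimals).
round_half_away <- function(x, digits = 3L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Small stable content hash for provenance stamps (FNV-style over a JSON dump).
content_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10)
  h <- 5381
  for (ch in utf8ToInt(as.character(s))) h <- (h * 33 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}
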