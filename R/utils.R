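# Internal helpers shared across modules.

# Evaluate expr with a private RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards. All simulator randomness flows through
# this so results are reproducible and callers' streams are untouched.
with_rng <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number", call. = FALSE)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

check_scalar <- function(x, field, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a single finite number")
  if (x < min) stop_field(field, sprintf("must be >= %g", min))
  if (x > max) stop_field(field, sprintf("must be <= %g", max))
  invisible(x)
}

# Cumulative arc length of a polyline given as an n x 2 matrix (nm).
polyline_arclength <- function(pts) {
  d <- sqrt(rowSums((pts[-1L, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  c(0, cumsum(d))
}

# Point and unit tangent at arc-length positions s along a polyline.
polyline_point_at <- function(pts, s) {
  cs <- polyline_arclength(pts)
  total <- cs[length(cs)]
  s <- pmin(pmax(s, 0), total)
  seg <- findInterval(s, cs, rightmost.closed = TRUE)
  seg <- pmin(seg, nrow(pts) - 1L)
  p0 <- pts[seg, , drop = FALSE]
  p1 <- pts[seg + 1L, , drop = FALSE]
  len <- cs[seg + 1L] - cs[seg]
  t <- (s - cs[seg]) / len
  tang <- (p1 - p0) / len
  list(point = p0 + t * (p1 - p0), tangent = tang)
}

# Minimum distance from points (n x 2) to a polyline (m x 2).
dist_to_polyline <- function(pts, line) {
  n <- nrow(pts)
  best <- rep(Inf, n)
  for (k in seq_len(nrow(line) - 1L)) {
    a <- line[k, ]
    b <- line[k + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- ((pts[, 1L] - a[1L]) * ab[1L] + (pts[, 2L] - a[2L]) * ab[2L]) / len2
    t <- pmin(pmax(t, 0), 1)
    dx <- pts[, 1L] - (a[1L] + t * ab[1L])
    dy <- pts[, 2L] - (a[2L] + t * ab[2L])
    best <- pmin(best, sqrt(dx^2 + dy^2))
  }
  best
}
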