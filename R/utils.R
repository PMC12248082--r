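# run expr under a local seed when one is given, without disturbing the
# caller's RNG stream; seed = NULL uses the current stream
with_seed_opt <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# shoelace area of a polygon given vertex coordinates in order
polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# convex hull area of a 2-D point cloud (0 if degenerate)
hull_area <- function(x, y) {
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 3) return(0)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  polygon_area(pts[h, 1], pts[h, 2])
}

# derive a bounded child seed from a run seed, for per-module re-runs
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 10007) %% 2147483399 + 1)
}
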