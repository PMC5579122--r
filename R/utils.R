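# Internal geometry and graph helpers.

# Connected components of an undirected adjacency matrix (logical, symmetric).
# Returns integer component label per node. Tiny graphs only (per-period
# rosters), so a plain BFS is ample.
components_of <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# Shoelace area of a polygon given as an n x 2 matrix of vertices (open ring).
polygon_area <- function(v) {
  if (nrow(v) < 3L) return(0)
  x <- v[, 1L]; y <- v[, 2L]
  j <- c(seq_len(nrow(v))[-1L], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

polygon_perimeter <- function(v) {
  if (nrow(v) < 2L) return(0)
  j <- c(seq_len(nrow(v))[-1L], 1L)
  sum(sqrt((v[j, 1L] - v[, 1L])^2 + (v[j, 2L] - v[, 2L])^2))
}

# Distance from points (px, py) to the segment (x1,y1)-(x2,y2), vectorised
# over points.
dist_point_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((px - x1)^2 + (py - y1)^2))
  t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

# Distance from points to a convex polygon (0 inside). `v` is an n x 2 vertex
# matrix in hull order; degenerate hulls (1 or 2 vertices) are supported.
dist_to_convex <- function(v, px, py) {
  n <- nrow(v)
  if (n == 1L) return(sqrt((px - v[1, 1])^2 + (py - v[1, 2])^2))
  if (n == 2L) return(dist_point_segment(px, py, v[1, 1], v[1, 2], v[2, 1], v[2, 2]))
  j <- c(seq_len(n)[-1L], 1L)
  orient <- sign(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]))
  inside <- rep(TRUE, length(px))
  d <- rep(Inf, length(px))
  for (k in seq_len(n)) {
    cross <- (v[j[k], 1] - v[k, 1]) * (py - v[k, 2]) -
             (v[j[k], 2] - v[k, 2]) * (px - v[k, 1])
    inside <- inside & (cross * orient >= 0)
    d <- pmin(d, dist_point_segment(px, py, v[k, 1], v[k, 2], v[j[k], 1], v[j[k], 2]))
  }
  d[inside] <- 0
  d
}

# Deterministic child seeds below 2^31, spread by a fixed multiplier.
child_seeds <- function(master, n) {
  (as.numeric(master) * 48271 + 7919 * seq_len(n)) %% 2147483559 + 1
}

`%||%` <- function(a, b) if (is.null(a)) b else a
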