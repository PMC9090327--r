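# fixture builders shared across the suite; everything is generated in code

unit_square <- function() {
  closed_contour(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
}

rect_contour <- function(w = 1, h = 2) {
  closed_contour(rbind(c(0, 0), c(w, 0), c(w, h), c(0, h)))
}

circle_contour <- function(n = 360, r = 1) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  closed_contour(cbind(r * cos(th), r * sin(th)))
}

# three square sides closed by a semicircular cap on top (y-down: cap at the
# "bottom" in math coords); side length s, cap radius s/2
stadium_contour <- function(s = 2, n_arc = 200) {
  th <- seq(0, pi, length.out = n_arc)
  cap <- cbind(s / 2 + (s / 2) * cos(th), (s / 2) * sin(th))
  pts <- rbind(c(s, 0), c(s, -s), c(0, -s), c(0, 0), cap[-1, , drop = FALSE])
  closed_contour(pts)
}

bowtie_contour <- function() {
  closed_contour(rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1)), normalize = FALSE)
}

# random star-shaped polygon: always simple
random_star_polygon <- function(n = 24, seed = 1) {
  set.seed(seed)
  th <- sort(stats::runif(n, 0, 2 * pi))
  while (min(diff(th)) < 1e-3) th <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, 0.5, 1.5)
  closed_contour(cbind(r * cos(th), r * sin(th)))
}

# independent O(n^2) segment-intersection oracle (scalar, textbook form)
oracle_self_intersects <- function(contour) {
  p <- contour$points
  n <- nrow(p)
  nxt <- c(seq_len(n)[-1], 1)
  seg_int <- function(p1, p2, p3, p4) {
    d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
    d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
    if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
        ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    on_seg <- function(a, b, c) {
      min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
    }
    (d1 == 0 && on_seg(p3, p4, p1)) || (d2 == 0 && on_seg(p3, p4, p2)) ||
    (d3 == 0 && on_seg(p1, p2, p3)) || (d4 == 0 && on_seg(p1, p2, p4))
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j == i + 1 || (i == 1 && j == n)) next
      if (seg_int(p[i, ], p[nxt[i], ], p[j, ], p[nxt[j], ])) return(TRUE)
    }
  }
  FALSE
}

# vectorized even-odd ray-casting point-in-polygon, independent of the
# package's geometry helpers
oracle_in_polygon <- function(poly, pts) {
  n <- nrow(poly)
  nxt <- c(seq_len(n)[-1], 1)
  inside <- rep(FALSE, nrow(pts))
  for (e in seq_len(n)) {
    x1 <- poly[e, 1]; y1 <- poly[e, 2]
    x2 <- poly[nxt[e], 1]; y2 <- poly[nxt[e], 2]
    crosses <- ((y1 > pts[, 2]) != (y2 > pts[, 2])) &
      (pts[, 1] < (x2 - x1) * (pts[, 2] - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  inside
}

# tiny deterministic cohort used by several analysis tests
tiny_cohort <- function(seed = 7) {
  generate_cohort(n_drawers = 3L, n_variations = 4L, n_exemplars = 3L,
                  seed = seed)
}
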