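#' Closed contour objects
#'
#' A `closed_contour` stores the silhouette of a drawing as an ordered,
#' circular list of 2D points in screen coordinates (y axis pointing down).
#' The first point is not repeated at the end; the closing edge from the last
#' point back to the first is implicit. On construction the point order is
#' normalized so that traversal is clockwise on a y-down screen (equivalently,
#' the mathematical y-up shoelace area of the stored order is positive).
#'
#' @param points numeric matrix (or data.frame) with two columns, `x` and `y`,
#'   at least three rows, all coordinates finite. Consecutive duplicate points
#'   (including a repeated closing point) are dropped.
#' @param stroke_mode optional character vector with one entry per edge
#'   (`"freehand"` or `"straight"`), recording the drawing mode of the
#'   segment that starts at the corresponding point. Recycled metadata from
#'   the drawing interface; `NULL` when unknown.
#' @param id optional shape identifier.
#' @param category optional category identifier.
#' @param normalize logical; normalize orientation to clockwise (default).
#' @return an object of class `closed_contour`.
#' @export
closed_contour <- function(points, stroke_mode = NULL, id = NULL,
                           category = NA_character_, normalize = TRUE) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2L) stop("`points` must have two columns (x, y)")
  storage.mode(pts) <- "double"
  if (!all(is.finite(pts))) stop("contour coordinates must be finite")
  # drop an explicit closing point and consecutive duplicates
  n0 <- nrow(pts)
  if (n0 >= 2L && all(pts[n0, ] == pts[1L, ])) {
    pts <- pts[-n0, , drop = FALSE]
    if (!is.null(stroke_mode) && length(stroke_mode) == n0) {
      stroke_mode <- stroke_mode[-n0]
    }
  }
  dup <- c(FALSE, rowSums(abs(diff(pts))) == 0)
  if (any(dup)) {
    pts <- pts[!dup, , drop = FALSE]
    if (!is.null(stroke_mode) && length(stroke_mode) == length(dup)) {
      stroke_mode <- stroke_mode[!dup]
    }
  }
  if (nrow(pts) < 3L) stop("a closed contour needs at least 3 distinct points")
  if (!is.null(stroke_mode)) {
    stroke_mode <- rep_len(as.character(stroke_mode), nrow(pts))
    if (!all(stroke_mode %in% c("freehand", "straight"))) {
      stop("stroke_mode entries must be 'freehand' or 'straight'")
    }
  }
  obj <- structure(
    list(points = unname(pts), stroke_mode = stroke_mode,
         id = id, category = category),
    class = "closed_contour"
  )
  if (normalize && signed_area_yup(obj) < 0) obj <- reverse_contour(obj)
  obj
}

#' @export
print.closed_contour <- function(x, ...) {
  cat(sprintf("<closed_contour%s: %d points, perimeter %.3f%s>\n",
              if (!is.null(x$id)) paste0(" ", x$id) else "",
              n_points(x), perimeter(x),
              if (!is.null(x$stroke_mode)) ", stroke metadata" else ""))
  invisible(x)
}

#' Number of points of a contour
#' @param contour a `closed_contour`.
#' @return integer point count.
#' @export
n_points <- function(contour) nrow(contour$points)

# signed shoelace area under the mathematical y-up convention;
# positive for the stored (clockwise on a y-down screen) orientation
signed_area_yup <- function(contour) {
  p <- contour$points
  x <- p[, 1L]; y <- p[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

# reverse traversal direction keeping point 1 first; edge modes follow edges
reverse_contour <- function(contour) {
  n <- n_points(contour)
  ord <- c(1L, n:2L)
  contour$points <- contour$points[ord, , drop = FALSE]
  if (!is.null(contour$stroke_mode)) {
    # edge k (p_k -> p_{k+1}) becomes the edge ending at p_k's new position
    contour$stroke_mode <- contour$stroke_mode[c(n:1L)]
  }
  contour
}

edge_lengths <- function(contour) {
  p <- contour$points
  d <- p[c(seq_len(nrow(p))[-1L], 1L), , drop = FALSE] - p
  sqrt(rowSums(d^2))
}

#' Perimeter of a closed contour
#'
#' Sum of consecutive point-to-point distances including the closing edge.
#' @param contour a `closed_contour`.
#' @return non-negative length in drawing units.
#' @export
perimeter <- function(contour) sum(edge_lengths(contour))

#' Enclosed area of a simple closed contour
#'
#' Absolute shoelace area of the polygon.
#' @param contour a `closed_contour`.
#' @param check if `TRUE`, raise an error when the contour self-intersects
#'   (the shoelace value is meaningless for non-simple polygons). Off by
#'   default because the check is quadratic in the point count.
#' @return area in squared drawing units.
#' @export
contour_area <- function(contour, check = FALSE) {
  if (check && self_intersects(contour)) {
    stop("contour is self-intersecting; area undefined")
  }
  abs(signed_area_yup(contour))
}

#' Resample a contour to equally spaced points
#'
#' Linear arc-length resampling: the output has exactly `n_points` points,
#' consecutive arc spacings equal to perimeter / `n_points`, and starts at the
#' original first point. Per-edge stroke metadata is carried over by assigning
#' each new edge the mode of the original edge covering its midpoint.
#'
#' @param contour a `closed_contour`.
#' @param n_points number of output points (>= 3), default 360: the package's
#'   standard count for all cross-shape analyses.
#' @return a resampled `closed_contour`.
#' @export
resample_contour <- function(contour, n_points = 360L) {
  n_points <- as.integer(n_points)
  if (n_points < 3L) stop("n_points must be >= 3")
  P <- perimeter(contour)
  if (P <= 0) stop("degenerate contour: zero perimeter")
  p <- contour$points
  n <- nrow(p)
  el <- edge_lengths(contour)
  s <- c(0, cumsum(el))                       # arc position of vertices, 0..P
  xs <- c(p[, 1L], p[1L, 1L])
  ys <- c(p[, 2L], p[1L, 2L])
  t <- (seq_len(n_points) - 1L) * P / n_points
  newp <- cbind(stats::approx(s, xs, xout = t)$y,
                stats::approx(s, ys, xout = t)$y)
  sm <- NULL
  if (!is.null(contour$stroke_mode)) {
    mid <- t + P / (2 * n_points)
    k <- findInterval(mid, s, rightmost.closed = TRUE)
    k[k > n] <- n
    sm <- contour$stroke_mode[k]
  }
  closed_contour(newp, stroke_mode = sm, id = contour$id,
                 category = contour$category, normalize = FALSE)
}

#' Index of the left-most contour point
#'
#' Ties on x are broken by minimum y (top-most under the y-down convention),
#' then by the lowest index. This is the anchor for clockwise part-circle
#' traversal.
#' @param contour a `closed_contour`.
#' @return 1-based point index.
#' @export
leftmost_start_index <- function(contour) {
  p <- contour$points
  order(p[, 1L], p[, 2L])[1L]
}

# unsigned turning angle (degrees) at each vertex: angle between the incoming
# and outgoing edge directions
turning_angles <- function(contour) {
  p <- contour$points
  n <- nrow(p)
  prv <- p[c(n, seq_len(n - 1L)), , drop = FALSE]
  nxt <- p[c(seq_len(n)[-1L], 1L), , drop = FALSE]
  v1 <- p - prv
  v2 <- nxt - p
  cr <- v1[, 1L] * v2[, 2L] - v1[, 2L] * v2[, 1L]
  dt <- v1[, 1L] * v2[, 1L] + v1[, 2L] * v2[, 2L]
  abs(atan2(cr, dt)) * 180 / pi
}

#' Fraction of the perimeter drawn as straight lines
#'
#' When the contour carries stroke metadata from the drawing interface, the
#' fraction is the arc length of straight-mode edges divided by the perimeter.
#' Otherwise a geometric classifier is used: a point counts as straight when
#' the total absolute turning angle over a centred window of `2*window + 1`
#' vertices is below `theta_deg` per vertex (strict), and the fraction is the
#' share of straight points. Both routes are exposed because recorded drawing
#' mode and local geometry are different notions of "straight".
#'
#' @param contour a `closed_contour`, resampled to the standard point count
#'   for cross-shape comparability.
#' @param window half-width `k` of the turning-angle window (default 3).
#' @param theta_deg straightness threshold in degrees per vertex (default 1).
#' @param use_stroke honour stroke metadata when present (default `TRUE`).
#' @return fraction in `[0, 1]`.
#' @export
straight_fraction <- function(contour, window = 3L, theta_deg = 1,
                              use_stroke = TRUE) {
  if (use_stroke && !is.null(contour$stroke_mode)) {
    el <- edge_lengths(contour)
    return(sum(el[contour$stroke_mode == "straight"]) / sum(el))
  }
  ta <- turning_angles(contour)
  w <- 2L * as.integer(window) + 1L
  tot <- as.numeric(stats::filter(ta, rep(1, w), sides = 2, circular = TRUE))
  # strict threshold with a guard against round-off exactly at the boundary
  mean(tot < theta_deg * w * (1 - 1e-9))
}

#' Circular contour segments
#'
#' A `contour_segment` is a half-open circular index range on a contour of
#' `n` points: indices `start, start+1, ..., start+length-1` taken modulo `n`
#' (1-based). Parts produced by chord cuts are stored this way.
#'
#' @param start 1-based start index.
#' @param length number of points in the segment (1..n).
#' @param n total number of points of the parent contour.
#' @return an object of class `contour_segment`.
#' @export
contour_segment <- function(start, length, n) {
  start <- as.integer(start); length <- as.integer(length); n <- as.integer(n)
  if (start < 1L || start > n) stop("segment start out of range")
  if (length < 1L || length > n) stop("segment length out of range")
  structure(list(start = start, length = length, n = n),
            class = "contour_segment")
}

#' @export
print.contour_segment <- function(x, ...) {
  cat(sprintf("<contour_segment: start %d, length %d of %d>\n",
              x$start, x$length, x$n))
  invisible(x)
}

#' Point indices covered by a segment
#' @param seg a `contour_segment`.
#' @return integer vector of 1-based indices in traversal order.
#' @export
segment_indices <- function(seg) {
  ((seg$start - 1L + seq_len(seg$length) - 1L) %% seg$n) + 1L
}

#' Polygon of a chord-cut part
#'
#' The closed polygon delimited by a segment and its closing chord: the
#' segment's points plus the chord endpoint that follows the segment.
#' @param contour the parent `closed_contour`.
#' @param seg a `contour_segment` on it.
#' @return two-column coordinate matrix.
#' @export
part_polygon <- function(contour, seg) {
  idx <- segment_indices(seg)
  nxt <- (idx[length(idx)] %% seg$n) + 1L
  contour$points[c(idx, nxt), , drop = FALSE]
}

# --- segment-intersection machinery -----------------------------------------

# vectorized test: does segment (a1,a2) intersect segments (b1[k,],b2[k,])?
# touching and collinear overlap count as intersection.
seg_intersect_any <- function(a1, a2, b1, b2) {
  o <- function(p, q, rx, ry) {
    (q[1L] - p[1L]) * (ry - p[2L]) - (q[2L] - p[2L]) * (rx - p[1L])
  }
  d1 <- o(a1, a2, b1[, 1L], b1[, 2L])
  d2 <- o(a1, a2, b2[, 1L], b2[, 2L])
  # orientation of a's endpoints w.r.t. each b segment
  d3 <- (b2[, 1L] - b1[, 1L]) * (a1[2L] - b1[, 2L]) -
        (b2[, 2L] - b1[, 2L]) * (a1[1L] - b1[, 1L])
  d4 <- (b2[, 1L] - b1[, 1L]) * (a2[2L] - b1[, 2L]) -
        (b2[, 2L] - b1[, 2L]) * (a2[1L] - b1[, 1L])
  proper <- (d1 * d2 < 0) & (d3 * d4 < 0)
  if (any(proper)) return(TRUE)
  # collinear / touching cases
  onseg <- function(p, q, rx, ry) {
    rx >= pmin(p[1L], q[1L]) & rx <= pmax(p[1L], q[1L]) &
    ry >= pmin(p[2L], q[2L]) & ry <= pmax(p[2L], q[2L])
  }
  touch <- (d1 == 0 & onseg(a1, a2, b1[, 1L], b1[, 2L])) |
           (d2 == 0 & onseg(a1, a2, b2[, 1L], b2[, 2L])) |
           (d3 == 0 & rep(onseg_pt(b1, b2, a1), 1L)) |
           (d4 == 0 & rep(onseg_pt(b1, b2, a2), 1L))
  any(touch)
}

onseg_pt <- function(b1, b2, a) {
  a[1L] >= pmin(b1[, 1L], b2[, 1L]) & a[1L] <= pmax(b1[, 1L], b2[, 1L]) &
  a[2L] >= pmin(b1[, 2L], b2[, 2L]) & a[2L] <= pmax(b1[, 2L], b2[, 2L])
}

#' Does a contour intersect itself?
#'
#' True iff any two non-adjacent edges intersect (touching counts). Quadratic
#' in the number of points but fully vectorized.
#' @param contour a `closed_contour`.
#' @return logical.
#' @export
self_intersects <- function(contour) {
  p <- contour$points
  n <- nrow(p)
  if (n < 4L) return(FALSE)
  nxt <- c(seq_len(n)[-1L], 1L)
  # all unordered non-adjacent edge pairs i < j
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n))
  adj <- (j == i + 1L) | (i == 1L & j == n)
  i <- i[!adj]; j <- j[!adj]
  # bounding-box prefilter: disjoint boxes cannot intersect
  ex0 <- pmin(p[, 1L], p[nxt, 1L]); ex1 <- pmax(p[, 1L], p[nxt, 1L])
  ey0 <- pmin(p[, 2L], p[nxt, 2L]); ey1 <- pmax(p[, 2L], p[nxt, 2L])
  keep <- ex0[i] <= ex1[j] & ex0[j] <= ex1[i] &
          ey0[i] <= ey1[j] & ey0[j] <= ey1[i]
  if (!any(keep)) return(FALSE)
  i <- i[keep]; j <- j[keep]
  a1 <- p[i, , drop = FALSE];  a2 <- p[nxt[i], , drop = FALSE]
  b1 <- p[j, , drop = FALSE];  b2 <- p[nxt[j], , drop = FALSE]
  d1 <- (a2[, 1] - a1[, 1]) * (b1[, 2] - a1[, 2]) -
        (a2[, 2] - a1[, 2]) * (b1[, 1] - a1[, 1])
  d2 <- (a2[, 1] - a1[, 1]) * (b2[, 2] - a1[, 2]) -
        (a2[, 2] - a1[, 2]) * (b2[, 1] - a1[, 1])
  d3 <- (b2[, 1] - b1[, 1]) * (a1[, 2] - b1[, 2]) -
        (b2[, 2] - b1[, 2]) * (a1[, 1] - b1[, 1])
  d4 <- (b2[, 1] - b1[, 1]) * (a2[, 2] - b1[, 2]) -
        (b2[, 2] - b1[, 2]) * (a2[, 1] - b1[, 1])
  if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  # touching / collinear contacts between non-adjacent edges (rare: only
  # evaluated where an orientation vanishes exactly)
  z <- which(d1 == 0 | d2 == 0 | d3 == 0 | d4 == 0)
  if (!length(z)) return(FALSE)
  a1 <- a1[z, , drop = FALSE]; a2 <- a2[z, , drop = FALSE]
  b1 <- b1[z, , drop = FALSE]; b2 <- b2[z, , drop = FALSE]
  deg <- (d1[z] == 0 & onseg2(a1, a2, b1)) | (d2[z] == 0 & onseg2(a1, a2, b2)) |
         (d3[z] == 0 & onseg2(b1, b2, a1)) | (d4[z] == 0 & onseg2(b1, b2, a2))
  any(deg)
}

onseg2 <- function(p, q, r) {
  r[, 1] >= pmin(p[, 1], q[, 1]) & r[, 1] <= pmax(p[, 1], q[, 1]) &
  r[, 2] >= pmin(p[, 2], q[, 2]) & r[, 2] <= pmax(p[, 2], q[, 2])
}

# points strictly (numerically) inside the polygon
points_in_contour <- function(contour, pts) {
  bnd <- rbind(contour$points, contour$points[1L, ])
  mgcv::in.out(bnd, matrix(pts, ncol = 2L))
}

#' Is a chord between two contour points admissible?
#'
#' A chord is admissible when the straight line between points `i` and `j`
#' stays inside the polygon, touching the boundary only at its endpoints —
#' the rule the part-picking interface enforced ("a part could only be picked
#' if the resulting line did not intersect with other parts of the shape").
#' @param contour a `closed_contour`.
#' @param i,j distinct 1-based point indices.
#' @return logical.
#' @export
chord_is_valid <- function(contour, i, j) {
  n <- n_points(contour)
  i <- as.integer(i); j <- as.integer(j)
  if (i == j || i < 1L || j < 1L || i > n || j > n) return(FALSE)
  # a chord between adjacent points coincides with an edge: not a cut
  if (abs(i - j) %in% c(1L, n - 1L)) return(FALSE)
  p <- contour$points
  a1 <- p[i, ]; a2 <- p[j, ]
  nxt <- c(seq_len(n)[-1L], 1L)
  keep <- !(seq_len(n) %in% c(i, j) | nxt %in% c(i, j))
  if (any(keep)) {
    b1 <- p[which(keep), , drop = FALSE]
    b2 <- p[nxt[which(keep)], , drop = FALSE]
    if (seg_intersect_any(a1, a2, b1, b2)) return(FALSE)
  }
  # interior test at several chord positions guards against chords that leave
  # the polygon through a notch mouth without crossing an edge
  tt <- c(0.25, 0.5, 0.75)
  probe <- cbind(a1[1L] + tt * (a2[1L] - a1[1L]),
                 a1[2L] + tt * (a2[2L] - a1[2L]))
  all(points_in_contour(contour, probe))
}

#' Cut a contour into two parts along a chord
#'
#' Splits the circular point list into the two complementary half-open
#' segments on either side of the chord `i`–`j`; their lengths sum to the
#' contour's point count. The chord must lie strictly inside the polygon
#' (see [chord_is_valid()]); invalid chords are rejected with an error, as
#' the picking interface did.
#'
#' @param contour a `closed_contour`.
#' @param i,j distinct 1-based point indices defining the chord.
#' @return list with elements `side1` (segment starting at `i`) and `side2`
#'   (segment starting at `j`), both `contour_segment`s.
#' @export
cut_part <- function(contour, i, j) {
  if (i == j) stop("chord endpoints must differ")
  if (!chord_is_valid(contour, i, j)) {
    stop(sprintf("chord %d-%d does not lie inside the shape", i, j))
  }
  n <- n_points(contour)
  len1 <- ((j - i) %% n)
  list(side1 = contour_segment(i, len1, n),
       side2 = contour_segment(j, n - len1, n))
}
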