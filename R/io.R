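#' Read a contour from JSON
#'
#' The on-disk format is `{"id", "category", "points": [[x,y],...],
#' "stroke_meta": [["freehand"|"straight", start_idx], ...]}` where
#' `stroke_meta` is an optional run list of drawing modes and `start_idx` is
#' the 0-based edge index at which a run starts. In-memory indices are
#' 1-based; conversion happens here at the I/O boundary.
#'
#' @param path file path or a literal JSON string.
#' @return a `closed_contour`.
#' @export
read_contour_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  pts <- obj$points
  if (is.list(pts)) pts <- do.call(rbind, pts)
  sm <- NULL
  if (!is.null(obj$stroke_meta) && length(obj$stroke_meta)) {
    runs <- obj$stroke_meta
    if (is.list(runs)) {
      mode <- vapply(runs, function(r) as.character(r[[1L]]), "")
      start <- vapply(runs, function(r) as.integer(r[[2L]]), 0L)
    } else {
      mode <- as.character(runs[, 1L]); start <- as.integer(runs[, 2L])
    }
    o <- order(start)
    mode <- mode[o]; start <- start[o]
    n <- nrow(pts)
    if (n >= 2L && all(pts[n, ] == pts[1L, ])) n <- n - 1L
    sm <- character(n)
    k <- findInterval(seq_len(n) - 1L, start)
    k[k < 1L] <- 1L
    sm <- mode[k]
  }
  closed_contour(pts, stroke_mode = sm,
                 id = obj$id %||% NULL,
                 category = obj$category %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a contour to JSON
#' @param contour a `closed_contour`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_contour_json <- function(contour, path) {
  obj <- list(id = contour$id, category = contour$category,
              points = unname(contour$points))
  if (!is.null(contour$stroke_mode)) {
    r <- rle(contour$stroke_mode)
    start0 <- cumsum(c(0L, r$lengths[-length(r$lengths)]))
    obj$stroke_meta <- mapply(function(m, s) list(m, s), r$values, start0,
                              SIMPLIFY = FALSE, USE.NAMES = FALSE)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Import a contour from an SVG file
#'
#' Reads the first `<polygon>`/`<polyline>` element, or a `<path>` whose `d`
#' attribute uses only absolute/relative move, line and close commands
#' (`M m L l H h V v Z z`). Curved path commands are rejected.
#'
#' @param path SVG file path.
#' @param id,category optional identifiers attached to the contour.
#' @return a `closed_contour`.
#' @export
read_contour_svg <- function(path, id = NULL, category = NA_character_) {
  doc <- xml2::read_xml(path)
  poly <- xml2::xml_find_first(doc, ".//*[local-name()='polygon' or local-name()='polyline']")
  if (!inherits(poly, "xml_missing")) {
    raw <- xml2::xml_attr(poly, "points")
    nums <- as.numeric(strsplit(trimws(raw), "[,[:space:]]+")[[1L]])
    pts <- matrix(nums, ncol = 2L, byrow = TRUE)
    return(closed_contour(pts, id = id, category = category))
  }
  pth <- xml2::xml_find_first(doc, ".//*[local-name()='path']")
  if (inherits(pth, "xml_missing")) stop("no polygon, polyline or path element found")
  d <- xml2::xml_attr(pth, "d")
  toks <- regmatches(d, gregexpr("[MmLlHhVvZz]|-?[0-9.]+(e-?[0-9]+)?", d))[[1L]]
  if (grepl("[CcSsQqTtAa]", d)) stop("only line-based path commands are supported")
  cur <- c(0, 0); pts <- NULL; cmd <- "M"
  k <- 1L
  while (k <= length(toks)) {
    t <- toks[k]
    if (grepl("^[A-Za-z]$", t)) { cmd <- t; k <- k + 1L; next }
    val <- as.numeric(t)
    if (cmd %in% c("M", "L")) {
      cur <- c(val, as.numeric(toks[k + 1L])); k <- k + 2L
      if (cmd == "M") cmd <- "L"
    } else if (cmd %in% c("m", "l")) {
      cur <- cur + c(val, as.numeric(toks[k + 1L])); k <- k + 2L
      if (cmd == "m") cmd <- "l"
    } else if (cmd == "H") { cur[1L] <- val; k <- k + 1L
    } else if (cmd == "h") { cur[1L] <- cur[1L] + val; k <- k + 1L
    } else if (cmd == "V") { cur[2L] <- val; k <- k + 1L
    } else if (cmd == "v") { cur[2L] <- cur[2L] + val; k <- k + 1L
    } else stop("unsupported path command: ", cmd)
    pts <- rbind(pts, cur)
  }
  closed_contour(pts, id = id, category = category)
}

#' Export contours (with optional per-point colouring) to SVG
#'
#' Writes one `<polygon>` per contour; when a numeric `field` in `[0, 100]`
#' is supplied for a single contour, the silhouette is additionally traced
#' edge-by-edge with a white-to-red gradient encoding the field value, the
#' rendering used for distinctiveness overlays.
#'
#' @param contours a `closed_contour` or list of them.
#' @param path output SVG path.
#' @param field optional numeric vector (one value per point of a single
#'   contour) on a 0-100 scale.
#' @param width,height canvas size in px.
#' @return `path`, invisibly.
#' @export
write_contour_svg <- function(contours, path, field = NULL,
                              width = 400, height = 400) {
  if (inherits(contours, "closed_contour")) contours <- list(contours)
  allp <- do.call(rbind, lapply(contours, function(cc) cc$points))
  rng <- apply(allp, 2L, range)
  span <- pmax(rng[2L, ] - rng[1L, ], 1e-9)
  sc <- 0.9 * min(width / span[1L], height / span[2L])
  tx <- function(p) cbind((p[, 1L] - rng[1L, 1L]) * sc + 0.05 * width,
                          (p[, 2L] - rng[1L, 2L]) * sc + 0.05 * height)
  lines <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%g" height="%g">',
    width, height))
  for (cc in contours) {
    q <- tx(cc$points)
    ptstr <- paste(sprintf("%.2f,%.2f", q[, 1L], q[, 2L]), collapse = " ")
    lines <- c(lines, sprintf(
      '<polygon points="%s" fill="none" stroke="black" stroke-width="1"/>',
      ptstr))
  }
  if (!is.null(field) && length(contours) == 1L) {
    q <- tx(contours[[1L]]$points)
    n <- nrow(q)
    v <- pmin(pmax(field / 100, 0), 1)
    g <- sprintf("#%02x%02x%02x", 255L,
                 as.integer(round(255 * (1 - v))),
                 as.integer(round(255 * (1 - v))))
    nxt <- c(seq_len(n)[-1L], 1L)
    lines <- c(lines, sprintf(
      '<line x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f" stroke="%s" stroke-width="3"/>',
      q[, 1L], q[, 2L], q[nxt, 1L], q[nxt, 2L], g))
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, path)
  invisible(path)
}
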