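#' Synthetic exemplars, variations and rater responses
#'
#' The generator emulates the structure of the drawing study: eight exemplar
#' shapes built from a main body with 0-5 attached parts (positive
#' protrusions or negative indentations), 17 drawers each producing 12
#' variations per exemplar via warp / shuffle / add / omit / substitute
#' strategies, and simulated raters for the similarity-placement,
#' classification, part-correspondence and distinctiveness-painting tasks.
#' Shapes are radial functions around their centroid (star-shaped), which
#' guarantees simple polygons and lets part spans be tracked exactly through
#' every transformation, so each analysis stage can be checked against known
#' ground truth.
#'
#' @name synthetic
NULL

BODY_RADIUS <- 100   # drawing units; all synthetic shapes share this scale

# radial body: polygonal = convex polygon, curved = low-frequency Fourier blob
make_body <- function(curvature_class) {
  if (curvature_class == "polygonal") {
    m <- sample(5:7, 1L)
    ang <- sort(stats::runif(m, 0, 2 * pi))
    # angular gaps bounded below (well-conditioned edges) and above (origin
    # must stay well inside for the radial representation)
    gaps <- function(a) diff(c(a, a[1L] + 2 * pi))
    while (min(gaps(ang)) < 0.25 || max(gaps(ang)) > 2.2) {
      ang <- sort(stats::runif(m, 0, 2 * pi))
    }
    list(type = "polygonal", angles = ang,
         radii = BODY_RADIUS * stats::runif(m, 0.8, 1.15))
  } else {
    k <- 2:5
    list(type = "curved", freqs = k,
         amps = stats::runif(length(k), 0.02, 0.10) *
           (stats::runif(length(k)) < 0.8),
         phases = stats::runif(length(k), 0, 2 * pi))
  }
}

# is angle theta inside the arc [th0, th1] (which may extend past 2*pi)?
in_arc <- function(theta, th0, th1) {
  (theta >= th0 & theta <= th1) |
    (theta + 2 * pi >= th0 & theta + 2 * pi <= th1) |
    (theta - 2 * pi >= th0 & theta - 2 * pi <= th1)
}

arc_param <- function(theta, th0, th1) {
  t <- (theta - th0) %% (2 * pi)
  t / ((th1 - th0) %% (2 * pi) + if (th1 - th0 >= 2 * pi) 2 * pi else 0)
}

# start/length of the single circular run of TRUE entries in a mask
mask_run <- function(mask) {
  n <- length(mask)
  if (all(mask)) return(c(1L, n))
  if (!any(mask)) return(NULL)
  prev <- c(mask[n], mask[-n])
  start <- which(mask & !prev)[1L]
  c(start, sum(mask))
}

body_radius_at <- function(body, theta) {
  if (body$type == "curved") {
    r <- rep(1, length(theta))
    for (q in seq_along(body$freqs)) {
      r <- r + body$amps[q] * cos(body$freqs[q] * theta + body$phases[q])
    }
    BODY_RADIUS * r
  } else {
    a <- body$angles; rr <- body$radii; m <- length(a)
    a_ext <- c(a, a[1L] + 2 * pi); r_ext <- c(rr, rr[1L])
    th <- theta %% (2 * pi)
    th[th < a[1L]] <- th[th < a[1L]] + 2 * pi
    k <- findInterval(th, a_ext, rightmost.closed = TRUE)
    k[k < 1L] <- 1L; k[k > m] <- m
    a1 <- a_ext[k]; a2 <- a_ext[k + 1L]
    r1 <- r_ext[k]; r2 <- r_ext[k + 1L]
    # radius of the chord between the two polygon vertices along ray theta
    r1 * r2 * sin(a2 - a1) / (r2 * sin(a2 - th) + r1 * sin(th - a1))
  }
}

# bump profiles over t in [0,1]; polygonal parts get piecewise-linear
# profiles, curved parts smooth ones
part_profile <- function(shape, t) {
  switch(shape,
    triangle  = 1 - abs(2 * t - 1),
    trapezoid = pmin(1, 3 * t, 3 * (1 - t)),
    round     = sin(pi * t)^2,
    pointed   = sin(pi * t)^4,
    stop("unknown profile shape: ", shape))
}

# assemble a shape from a body and a placed-parts table, resample to the
# standard count, and recover each part's index span on the result
build_shape <- function(body, parts, n_std = 360L, n_fine = 1440L,
                        warp = NULL, id = NULL, category = NA_character_,
                        curvature_class = "curved") {
  theta <- 2 * pi * (seq_len(n_fine) - 1L) / n_fine
  r <- body_radius_at(body, theta)
  if (!is.null(parts) && nrow(parts) > 0L) {
    for (q in seq_len(nrow(parts))) {
      th0 <- parts$theta0[q]; th1 <- parts$theta1[q]
      inside <- in_arc(theta, th0, th1)
      t <- arc_param(theta[inside], th0, th1)
      r[inside] <- r[inside] +
        parts$polarity_sign[q] * parts$height[q] *
        part_profile(parts$profile[q], t)
    }
  }
  if (!is.null(warp) && warp$magnitude > 0) {
    g <- rep(0, n_fine)
    for (q in seq_along(warp$freqs)) {
      g <- g + warp$coefs[q] * cos(warp$freqs[q] * theta + warp$phases[q])
    }
    g <- g / max(abs(g), 1e-12)
    r <- r * (1 + 0.35 * warp$magnitude * g)
  }
  r <- pmax(r, 0.12 * BODY_RADIUS)
  cc <- closed_contour(cbind(r * cos(theta), r * sin(theta)),
                       id = id, category = category)
  cc <- resample_contour(cc, n_std)
  cc$stroke_mode <- rep(
    if (curvature_class == "polygonal") "straight" else "freehand", n_std)
  th_res <- atan2(cc$points[, 2L], cc$points[, 1L]) %% (2 * pi)
  spans <- NULL
  if (!is.null(parts) && nrow(parts) > 0L) {
    spans <- parts
    spans$span_start <- spans$span_length <- NA_integer_
    for (q in seq_len(nrow(parts))) {
      run <- mask_run(in_arc(th_res, parts$theta0[q], parts$theta1[q]))
      if (is.null(run)) stop("part span lost in resampling")
      spans$span_start[q] <- run[1L]
      spans$span_length[q] <- run[2L]
    }
  }
  list(contour = cc, spans = spans)
}

# lay out n parts over disjoint angular sectors, avoiding the theta = 0 seam
layout_parts <- function(n_parts, curvature_class, p_negative = 0.3) {
  if (n_parts == 0L) {
    return(tibble::tibble(label = character(), theta0 = double(),
                          theta1 = double(), polarity = character(),
                          polarity_sign = double(), height = double(),
                          profile = character(), weight = double()))
  }
  sector <- 2 * pi / n_parts
  centers <- (seq_len(n_parts) - 0.5) * sector +
    stats::runif(n_parts, -0.15, 0.15) * sector
  width <- stats::runif(n_parts, 0.22, 0.34) * pmin(sector, 2 * pi / 5)
  polarity <- c("positive",
                sample(c("positive", "negative"), max(n_parts - 1L, 0L),
                       replace = TRUE,
                       prob = c(1 - p_negative, p_negative)))[seq_len(n_parts)]
  sign <- ifelse(polarity == "positive", 1, -1)
  height <- ifelse(polarity == "positive",
                   stats::runif(n_parts, 0.30, 0.55),
                   stats::runif(n_parts, 0.18, 0.30)) * BODY_RADIUS
  profile <- if (curvature_class == "polygonal") {
    sample(c("triangle", "trapezoid"), n_parts, replace = TRUE)
  } else {
    sample(c("round", "pointed"), n_parts, replace = TRUE)
  }
  # ground-truth salience: taller parts are more distinctive, ordering strict
  w <- rank(height, ties.method = "first")
  weight <- 0.3 + 0.7 * (w / n_parts)
  tibble::tibble(label = paste0("P", seq_len(n_parts)),
                 theta0 = centers - width / 2, theta1 = centers + width / 2,
                 polarity = polarity, polarity_sign = sign, height = height,
                 profile = profile, weight = weight)
}

#' Generate a synthetic exemplar shape
#'
#' Builds a main body (convex polygon or low-frequency radial blob) with
#' `n_parts` attached parts over disjoint contour spans. Each part carries a
#' ground-truth distinctiveness weight in `[0, 1]` (taller parts are more
#' salient). Polygonal exemplars carry straight-line stroke metadata, curved
#' ones freehand metadata, emulating the drawing interface's recorded mode.
#'
#' @param n_parts number of parts, 0 to 5.
#' @param curvature_class `"polygonal"` or `"curved"`.
#' @param seed integer seed; the same seed reproduces the shape exactly.
#' @param category category id attached to the shape.
#' @param n_std standard resampled point count (default 360).
#' @param p_negative probability that a part beyond the first is an
#'   indentation rather than a protrusion (default 0.3).
#' @return list with `contour` (a `closed_contour`) and `spec` (body, placed
#'   parts with index spans, class, seed); class `exemplar`.
#' @export
generate_exemplar <- function(n_parts, curvature_class = c("curved", "polygonal"),
                              seed = 1L, category = 1L, n_std = 360L,
                              p_negative = 0.3) {
  curvature_class <- match.arg(curvature_class)
  if (n_parts < 0L || n_parts > 5L) stop("n_parts must be between 0 and 5")
  set.seed(seed)
  for (try in 1:20) {
    body <- make_body(curvature_class)
    parts <- layout_parts(n_parts, curvature_class, p_negative)
    built <- build_shape(body, parts, n_std = n_std,
                         id = paste0("E", category), category = category,
                         curvature_class = curvature_class)
    if (!self_intersects(built$contour)) {
      return(structure(
        list(contour = built$contour,
             spec = list(category = category, curvature_class = curvature_class,
                         n_parts = n_parts, body = body, parts = built$spans,
                         seed = seed)),
        class = "exemplar"))
    }
  }
  stop("could not produce a simple exemplar polygon (seed ", seed, ")")
}

#' Specify a variation of an exemplar
#'
#' @param drawer drawer id.
#' @param strategies character subset of
#'   `c("warp", "shuffle", "add", "omit", "substitute")`.
#' @param magnitude warp magnitude in `[0, 1]`.
#' @param permutation for `shuffle`: character vector giving the new clockwise
#'   order of the retained labels (any rotation of it is equivalent).
#' @param omit,substitute labels of exemplar parts to drop / replace.
#' @param add number of new parts to insert (default 1 when the strategy is
#'   active).
#' @param seed integer seed for the variation's own randomness.
#' @return list of class `variation_spec`.
#' @export
variation_spec <- function(drawer = 1L, strategies = "warp", magnitude = 0.3,
                           permutation = NULL, omit = character(),
                           substitute = character(), add = 1L, seed = 1L) {
  strategies <- unique(strategies)
  bad <- setdiff(strategies, c("warp", "shuffle", "add", "omit", "substitute"))
  if (length(bad)) stop("unknown strategies: ", paste(bad, collapse = ", "))
  if (magnitude < 0 || magnitude > 1) stop("magnitude must be in [0, 1]")
  structure(list(drawer = drawer, strategies = strategies,
                 magnitude = magnitude, permutation = permutation,
                 omit = omit, substitute = substitute, add = add,
                 seed = seed),
            class = "variation_spec")
}

# rigid (rotation + translation) alignment residual, normalized by the
# exemplar's RMS radius
rigid_residual <- function(X, Y) {
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  s <- svd(crossprod(Xc, Yc))
  R <- s$u %*% diag(c(1, det(s$u %*% t(s$v)))) %*% t(s$v)
  d <- Yc - Xc %*% R
  mean(sqrt(rowSums(d^2))) / sqrt(mean(rowSums(Xc^2)))
}

#' Generate a variation of an exemplar
#'
#' Applies the spec's part-level strategies (omit / substitute / add /
#' shuffle) to the exemplar's construction, then a smooth radial warp of the
#' given magnitude. Ground truth is recorded: retained labels keep exact
#' index spans on the result, the clockwise order of retained labels follows
#' the requested permutation, and a scalar deviation magnitude (normalized
#' mean point displacement after optimal rigid alignment, plus 0.15 per part
#' change, capped at 1) is stored. A zero-magnitude spec with no strategies
#' reproduces the exemplar exactly.
#'
#' @param exemplar an object from [generate_exemplar()].
#' @param spec a [variation_spec()].
#' @param id shape id for the result.
#' @return list with `contour`, `parts` (ground-truth spans; added parts are
#'   labelled `A*`, substituted ones `S*`), `spec`, `magnitude`; class
#'   `variation`.
#' @export
generate_variation <- function(exemplar, spec, id = NULL) {
  es <- exemplar$spec
  set.seed(spec$seed)
  parts <- es$parts
  if (is.null(parts)) {
    parts <- layout_parts(0L, es$curvature_class)
    parts$span_start <- integer(); parts$span_length <- integer()
  }
  changes <- 0L
  if ("omit" %in% spec$strategies && length(spec$omit)) {
    if (!all(spec$omit %in% parts$label)) stop("omit lists unknown labels")
    parts <- parts[!parts$label %in% spec$omit, , drop = FALSE]
    changes <- changes + length(spec$omit)
  }
  if ("substitute" %in% spec$strategies && length(spec$substitute)) {
    if (!all(spec$substitute %in% parts$label)) stop("substitute lists unknown labels")
    for (lb in spec$substitute) {
      q <- which(parts$label == lb)
      parts$label[q] <- paste0("S", lb)
      parts$polarity_sign[q] <- -parts$polarity_sign[q]
      parts$polarity[q] <- ifelse(parts$polarity_sign[q] > 0, "positive", "negative")
      parts$height[q] <- stats::runif(1, 0.18, 0.45) * BODY_RADIUS
      parts$profile[q] <- sample(c("triangle", "round"), 1L)
    }
    changes <- changes + length(spec$substitute)
  }
  if ("shuffle" %in% spec$strategies && !is.null(spec$permutation)) {
    retained <- parts$label[parts$label %in% es$parts$label]
    perm <- spec$permutation
    if (!setequal(perm, retained)) {
      stop("permutation must be a reordering of the retained labels")
    }
    # slots = current spans in clockwise (theta) order; permute which part
    # occupies which retained slot so that reading the slots clockwise
    # yields the requested cyclic order (rotations are equivalent)
    slots <- parts[order(parts$theta0), , drop = FALSE]
    ret_slots <- which(slots$label %in% retained)
    newparts <- slots
    for (q in seq_along(ret_slots)) {
      src <- which(slots$label == perm[q])
      row <- slots[src, , drop = FALSE]
      row$theta0 <- slots$theta0[ret_slots[q]]
      row$theta1 <- slots$theta1[ret_slots[q]]
      newparts[ret_slots[q], ] <- row
    }
    parts <- newparts
  }
  if ("add" %in% spec$strategies && spec$add > 0L) {
    for (k in seq_len(spec$add)) {
      gaps <- find_free_sector(parts)
      if (is.null(gaps)) break
      width <- min(0.5, (gaps[2L] - gaps[1L]) * 0.5)
      ctr <- mean(gaps)
      newrow <- tibble::tibble(
        label = paste0("A", k), theta0 = ctr - width / 2,
        theta1 = ctr + width / 2, polarity = "positive", polarity_sign = 1,
        height = stats::runif(1, 0.25, 0.5) * BODY_RADIUS,
        profile = sample(c("triangle", "round"), 1L),
        weight = stats::runif(1, 0.3, 1))
      for (cn in setdiff(names(parts), names(newrow))) newrow[[cn]] <- NA
      parts <- rbind(parts, newrow[, names(parts)])
      changes <- changes + 1L
    }
  }
  warp <- NULL
  mag <- if ("warp" %in% spec$strategies) spec$magnitude else 0
  if (mag > 0) {
    warp <- list(magnitude = mag, freqs = 1:3,
                 coefs = stats::rnorm(3), phases = stats::runif(3, 0, 2 * pi))
  }
  # radial builds (positive single-valued radius, radial warp included) are
  # star-shaped and therefore always simple: no intersection check needed
  built <- build_shape(es$body, parts, id = id, category = es$category,
                       curvature_class = es$curvature_class, warp = warp)
  dev <- rigid_residual(exemplar$contour$points, built$contour$points)
  magnitude <- min(1, dev / 0.35 + 0.15 * changes)
  structure(list(contour = built$contour, parts = built$spans, spec = spec,
                 magnitude = magnitude, exemplar_category = es$category),
            class = "variation")
}

# largest angular gap between placed parts (with margin), or NULL
find_free_sector <- function(parts, margin = 0.12) {
  if (nrow(parts) == 0L) return(c(0.5, 2.5))
  o <- order(parts$theta0)
  a0 <- parts$theta0[o]; a1 <- parts$theta1[o]
  gaps <- cbind(a1, c(a0[-1L], a0[1L] + 2 * pi))
  w <- gaps[, 2L] - gaps[, 1L]
  k <- which.max(w)
  if (w[k] < 3 * margin) return(NULL)
  c(gaps[k, 1L] + margin, gaps[k, 2L] - margin)
}

#' Generate a full synthetic cohort of drawings
#'
#' Emulates the drawing study's data set: `n_exemplars` exemplar shapes
#' (parts ranging over 0-5, alternating polygonal and curved bodies) and
#' `n_drawers` drawers each contributing `n_variations` variations per
#' exemplar (defaults 8 x 17 x 12 = 1632 drawings, 204 per exemplar). Each
#' drawer has a characteristic warp-magnitude level (evenly laddered over the
#' cohort), which induces a stable ground-truth "creativity" ordering;
#' variations additionally shuffle / add / omit / substitute parts with fixed
#' probabilities.
#'
#' @param n_drawers,n_variations,n_exemplars design counts (defaults 17, 12, 8).
#' @param seed master seed; all per-shape seeds derive from it.
#' @param p_shuffle,p_omit,p_add,p_substitute per-variation strategy
#'   probabilities (defaults 0.15, 0.15, 0.10, 0.10).
#' @return object of class `shape_cohort`: list with `exemplars` (list),
#'   `variations` (tibble with list-columns `contour` and `parts`), `params`.
#' @export
generate_cohort <- function(n_drawers = 17L, n_variations = 12L,
                            n_exemplars = 8L, seed = 1L,
                            p_shuffle = 0.15, p_omit = 0.15,
                            p_add = 0.10, p_substitute = 0.10) {
  if (n_drawers < 1L || n_variations < 1L || n_exemplars < 1L) {
    stop("design counts must be positive")
  }
  set.seed(seed)
  npart_cycle <- rep_len(c(3L, 2L, 4L, 0L, 5L, 1L, 3L, 2L), n_exemplars)
  class_cycle <- rep_len(c("polygonal", "curved"), n_exemplars)
  ex_seeds <- sample.int(.Machine$integer.max, n_exemplars)
  var_seeds <- matrix(sample.int(.Machine$integer.max,
                                 n_exemplars * n_drawers * n_variations),
                      nrow = n_exemplars)
  drawer_level <- seq(0.12, 0.72, length.out = n_drawers)
  exemplars <- lapply(seq_len(n_exemplars), function(e) {
    generate_exemplar(npart_cycle[e], class_cycle[e], seed = ex_seeds[e],
                      category = e)
  })
  names(exemplars) <- paste0("E", seq_len(n_exemplars))
  rows <- vector("list", n_exemplars * n_drawers * n_variations)
  k <- 0L
  for (e in seq_len(n_exemplars)) {
    ex <- exemplars[[e]]
    labels <- ex$spec$parts$label
    for (d in seq_len(n_drawers)) {
      for (v in seq_len(n_variations)) {
        sd_k <- var_seeds[e, (d - 1L) * n_variations + v]
        set.seed(sd_k)
        strategies <- "warp"
        mag <- min(0.95, max(0.02, stats::rnorm(1, drawer_level[d], 0.08)))
        omit <- character(); subst <- character(); perm <- NULL; addn <- 0L
        if (length(labels) >= 1L && stats::runif(1) < p_omit) {
          strategies <- c(strategies, "omit")
          omit <- sample(labels, 1L)
        }
        retained <- setdiff(labels, omit)
        if (length(retained) >= 1L && stats::runif(1) < p_substitute) {
          strategies <- c(strategies, "substitute")
          subst <- sample(retained, 1L)
          retained <- setdiff(retained, subst)
        }
        if (length(retained) >= 2L && stats::runif(1) < p_shuffle) {
          strategies <- c(strategies, "shuffle")
          perm <- sample(retained)
        }
        if (stats::runif(1) < p_add) {
          strategies <- c(strategies, "add")
          addn <- 1L
        }
        vs <- variation_spec(drawer = d, strategies = strategies,
                             magnitude = mag, permutation = perm,
                             omit = omit, substitute = subst, add = addn,
                             seed = sd_k)
        id <- sprintf("E%d_D%02d_V%02d", e, d, v)
        vr <- generate_variation(ex, vs, id = id)
        k <- k + 1L
        rows[[k]] <- tibble::tibble(
          shape_id = id, category = e, drawer = d, index = v,
          magnitude = vr$magnitude,
          strategies = list(strategies), omitted = list(omit),
          substituted = list(subst), added = addn,
          permutation = list(perm),
          contour = list(vr$contour), parts = list(vr$parts))
      }
    }
  }
  structure(list(exemplars = exemplars,
                 variations = do.call(rbind, rows[seq_len(k)]),
                 params = list(n_drawers = n_drawers,
                               n_variations = n_variations,
                               n_exemplars = n_exemplars, seed = seed,
                               drawer_level = drawer_level)),
            class = "shape_cohort")
}

#' @export
print.shape_cohort <- function(x, ...) {
  cat(sprintf("<shape_cohort: %d exemplars, %d drawers, %d variations (%d drawings)>\n",
              x$params$n_exemplars, x$params$n_drawers,
              x$params$n_variations, nrow(x$variations)))
  invisible(x)
}

# look up any shape (exemplar "E3" or variation id) in a cohort
cohort_shape <- function(cohort, shape_id) {
  if (shape_id %in% names(cohort$exemplars)) {
    return(cohort$exemplars[[shape_id]]$contour)
  }
  k <- match(shape_id, cohort$variations$shape_id)
  if (is.na(k)) stop("unknown shape id: ", shape_id)
  cohort$variations$contour[[k]]
}

cohort_parts <- function(cohort, shape_id) {
  if (shape_id %in% names(cohort$exemplars)) {
    return(cohort$exemplars[[shape_id]]$spec$parts)
  }
  k <- match(shape_id, cohort$variations$shape_id)
  if (is.na(k)) stop("unknown shape id: ", shape_id)
  cohort$variations$parts[[k]]
}

#' Simulate similarity-placement ratings
#'
#' Each simulated rater places every variation of a category on a horizontal
#' axis: distance from the exemplar's position grows monotonically with the
#' variation's ground-truth deviation magnitude, perturbed by Gaussian noise,
#' under a rater-specific affine screen scale. The exemplar's own position is
#' recorded per rater and category.
#'
#' @param cohort a `shape_cohort`.
#' @param n_raters raters per category (default 12).
#' @param noise placement noise SD on the magnitude scale (default 0.05).
#' @param seed integer seed.
#' @return tibble `(rater, category, shape, x, x_exemplar)`.
#' @export
simulate_similarity_ratings <- function(cohort, n_raters = 12L, noise = 0.05,
                                        seed = 1L) {
  set.seed(seed)
  v <- cohort$variations
  out <- vector("list", n_raters)
  for (r in seq_len(n_raters)) {
    x0 <- stats::runif(cohort$params$n_exemplars, 0, 40)
    sc <- stats::runif(cohort$params$n_exemplars, 300, 700)
    eps <- stats::rnorm(nrow(v), 0, noise)
    out[[r]] <- tibble::tibble(
      rater = r, category = v$category, shape = v$shape_id,
      x = x0[v$category] + sc[v$category] * pmax(v$magnitude + eps, 0.001),
      x_exemplar = x0[v$category])
  }
  do.call(rbind, out)
}

#' Simulate the 8-way classification task
#'
#' Each response is the true category with probability `1 - confusability`,
#' otherwise uniform over the remaining categories.
#'
#' @param shapes tibble with columns `shape_id` and `category` (e.g.
#'   `cohort$variations`, or a swap-design table with a `response_truth`
#'   column standing in for `category`).
#' @param n_raters number of raters (default 15).
#' @param confusability lapse probability in `[0, 1]`.
#' @param n_categories total categories (default 8).
#' @param seed integer seed.
#' @return tibble `(rater, shape_id, true, response)`.
#' @export
simulate_classification <- function(shapes, n_raters = 15L,
                                    confusability = 0.1, n_categories = 8L,
                                    seed = 1L) {
  set.seed(seed)
  n <- nrow(shapes)
  out <- vector("list", n_raters)
  for (r in seq_len(n_raters)) {
    lapse <- stats::runif(n) < confusability
    resp <- shapes$category
    if (any(lapse)) {
      resp[lapse] <- vapply(shapes$category[lapse], function(tr) {
        sample(setdiff(seq_len(n_categories), tr), 1L)
      }, 0L)
    }
    out[[r]] <- tibble::tibble(rater = r, shape_id = shapes$shape_id,
                               true = shapes$category, response = resp)
  }
  do.call(rbind, out)
}

#' Enumerate part-correspondence trials
#'
#' For each exemplar: `n_within` of its own variations spanning the deviation
#' range, plus `n_cross` variations of one other (randomly chosen) category —
#' the study's 8 x (10 + 10) = 160 trials per participant.
#'
#' @param cohort a `shape_cohort`.
#' @param n_within,n_cross counts per exemplar (defaults 10, 10).
#' @param seed integer seed.
#' @return tibble `(trial, exemplar_id, shape_id, same_category)`.
#' @export
enumerate_correspondence_trials <- function(cohort, n_within = 10L,
                                            n_cross = 10L, seed = 1L) {
  set.seed(seed)
  ne <- cohort$params$n_exemplars
  v <- cohort$variations
  rows <- list()
  trial <- 0L
  for (e in seq_len(ne)) {
    own <- v[v$category == e, ]
    own <- own[order(own$magnitude), ]
    pick <- own$shape_id[unique(round(seq(1L, nrow(own),
                                          length.out = min(n_within, nrow(own)))))]
    other_cat <- if (ne > 1L) sample(setdiff(seq_len(ne), e), 1L) else e
    oth <- v[v$category == other_cat, ]
    pick2 <- oth$shape_id[sample.int(nrow(oth), min(n_cross, nrow(oth)))]
    for (s in pick) {
      trial <- trial + 1L
      rows[[trial]] <- tibble::tibble(trial = trial, exemplar_id = paste0("E", e),
                                      shape_id = s, same_category = TRUE)
    }
    for (s in pick2) {
      trial <- trial + 1L
      rows[[trial]] <- tibble::tibble(trial = trial, exemplar_id = paste0("E", e),
                                      shape_id = s, same_category = FALSE)
    }
  }
  do.call(rbind, rows)
}

# find a valid chord bracketing a part span, widening step by step
part_chord <- function(contour, span_start, span_length, max_widen = 12L) {
  n <- n_points(contour)
  for (w in 0:max_widen) {
    i <- ((span_start - 2L - w) %% n) + 1L
    j <- ((span_start + span_length - 1L + w) %% n) + 1L
    if (i != j && chord_is_valid(contour, i, j)) {
      return(list(i = i, j = j))
    }
  }
  NULL
}

# cached chords for every part of every shape referenced by the trials
precompute_part_chords <- function(cohort, shape_ids) {
  res <- list()
  for (sid in unique(shape_ids)) {
    cc <- cohort_shape(cohort, sid)
    pp <- cohort_parts(cohort, sid)
    ch <- list()
    if (!is.null(pp) && nrow(pp)) {
      for (q in seq_len(nrow(pp))) {
        ch[[pp$label[q]]] <- part_chord(cc, pp$span_start[q], pp$span_length[q])
      }
    }
    res[[sid]] <- ch
  }
  res
}

#' Simulate part-correspondence picks
#'
#' Noiseless behaviour: on same-category trials each part label retained in
#' both shapes yields one correspondence pair whose chords bracket the
#' ground-truth spans; with probability `bundling` two clockwise-adjacent
#' shared parts are merged into a single pick on both shapes. Cross-category
#' trials yield a spurious single pick with probability `cross_pick_rate`.
#' After pairing the parts on a same-category trial, the rater additionally
#' pairs the rest of both shapes (body-to-body) with probability
#' `rest_pick_rate`, as the interface's rest-of-shape option allowed.
#' Chords are widened minimally until they lie inside the shape (as the
#' interface required); parts with no admissible chord are skipped.
#'
#' @param cohort a `shape_cohort`.
#' @param trials from [enumerate_correspondence_trials()].
#' @param n_raters raters (default 15).
#' @param bundling probability of merging adjacent shared parts.
#' @param cross_pick_rate probability of a spurious pick on cross-category
#'   trials (default 0.15).
#' @param rest_pick_rate probability of closing a same-category trial with a
#'   rest-of-shape pair (default 0.4).
#' @param seed integer seed.
#' @return tibble of picks: `(trial, rater, shape_role, shape_id, i, j, side,
#'   rest_flag, pair_id, label)` with `shape_role` in
#'   `c("exemplar", "variation")`; `label` is the ground-truth part label.
#' @export
simulate_correspondence <- function(cohort, trials, n_raters = 15L,
                                    bundling = 0, cross_pick_rate = 0.15,
                                    rest_pick_rate = 0.4, seed = 1L) {
  set.seed(seed)
  chords <- precompute_part_chords(
    cohort, c(trials$exemplar_id, trials$shape_id))
  rows <- list(); pair_id <- 0L
  for (t in seq_len(nrow(trials))) {
    eid <- trials$exemplar_id[t]; sid <- trials$shape_id[t]
    ep <- cohort_parts(cohort, eid); vp <- cohort_parts(cohort, sid)
    shared <- if (trials$same_category[t] && !is.null(vp)) {
      intersect(ep$label, vp$label)
    } else character()
    # clockwise order of shared labels on the exemplar
    if (length(shared)) {
      shared <- shared[order(ep$theta0[match(shared, ep$label)])]
    }
    for (r in seq_len(n_raters)) {
      if (length(shared)) {
        groups <- as.list(shared)
        if (bundling > 0 && length(shared) >= 2L) {
          g <- list(); k <- 1L
          while (k <= length(shared)) {
            if (k < length(shared) && stats::runif(1) < bundling) {
              g[[length(g) + 1L]] <- shared[c(k, k + 1L)]; k <- k + 2L
            } else {
              g[[length(g) + 1L]] <- shared[k]; k <- k + 1L
            }
          }
          groups <- g
        }
        for (grp in groups) {
          pk_e <- group_pick(cohort, eid, ep, grp, chords[[eid]])
          pk_v <- group_pick(cohort, sid, vp, grp, chords[[sid]])
          if (is.null(pk_e) || is.null(pk_v)) next
          pair_id <- pair_id + 1L
          rows[[length(rows) + 1L]] <- tibble::tibble(
            trial = t, rater = r,
            shape_role = c("exemplar", "variation"),
            shape_id = c(eid, sid),
            i = c(pk_e$i, pk_v$i), j = c(pk_e$j, pk_v$j),
            side = c(pk_e$side, pk_v$side), rest_flag = FALSE,
            pair_id = pair_id, label = paste(grp, collapse = "+"))
        }
        if (stats::runif(1) < rest_pick_rate) {
          pair_id <- pair_id + 1L
          rows[[length(rows) + 1L]] <- tibble::tibble(
            trial = t, rater = r,
            shape_role = c("exemplar", "variation"),
            shape_id = c(eid, sid),
            i = NA_integer_, j = NA_integer_, side = NA_integer_,
            rest_flag = TRUE, pair_id = pair_id, label = "REST")
        }
      } else if (!trials$same_category[t] && stats::runif(1) < cross_pick_rate) {
        if (is.null(ep) || nrow(ep) == 0L || is.null(vp) || nrow(vp) == 0L) next
        le <- sample(ep$label, 1L); lv <- sample(vp$label, 1L)
        pk_e <- group_pick(cohort, eid, ep, le, chords[[eid]])
        pk_v <- group_pick(cohort, sid, vp, lv, chords[[sid]])
        if (is.null(pk_e) || is.null(pk_v)) next
        pair_id <- pair_id + 1L
        rows[[length(rows) + 1L]] <- tibble::tibble(
          trial = t, rater = r,
          shape_role = c("exemplar", "variation"),
          shape_id = c(eid, sid),
          i = c(pk_e$i, pk_v$i), j = c(pk_e$j, pk_v$j),
          side = c(pk_e$side, pk_v$side), rest_flag = FALSE,
          pair_id = pair_id, label = paste0("X", pair_id))
      }
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(trial = integer(), rater = integer(),
                          shape_role = character(), shape_id = character(),
                          i = integer(), j = integer(), side = integer(),
                          rest_flag = logical(), pair_id = integer(),
                          label = character()))
  }
  do.call(rbind, rows)
}

# chord + side for one label (or a pair of adjacent labels, bundled)
group_pick <- function(cohort, sid, ptab, labels, chord_cache) {
  cc <- cohort_shape(cohort, sid)
  n <- n_points(cc)
  rows <- ptab[ptab$label %in% labels, , drop = FALSE]
  if (nrow(rows) == 0L) return(NULL)
  if (nrow(rows) == 1L) {
    ch <- chord_cache[[rows$label]]
    if (is.null(ch)) return(NULL)
  } else {
    o <- order(rows$theta0)
    first <- rows[o[1L], ]; last <- rows[o[nrow(rows)], ]
    ch <- part_chord(cc, first$span_start,
                     ((last$span_start + last$span_length - first$span_start) %% n))
    if (is.null(ch)) return(NULL)
  }
  # the part lies on the side whose segment starts at i (i -> j clockwise)
  list(i = ch$i, j = ch$j, side = 1L)
}

#' Simulate tiered distinctiveness paintings
#'
#' Each simulated rater paints the contour of each shape: tier 1 (red) on the
#' highest-weight ground-truth part span, tiers 2 and 3 optionally on the
#' next-ranked parts, with span boundaries jittered by Gaussian noise. Tiers
#' never overlap within a painting and at least one tier-1 run is always
#' present (shapes without parts receive a tier-1 run at a random location).
#'
#' @param cohort a `shape_cohort`.
#' @param shape_ids shapes to paint (default: all exemplars).
#' @param n_raters raters per shape (default 10).
#' @param jitter boundary jitter SD as a fraction of span length (default 0.1).
#' @param tier_p probabilities of using tiers 2 and 3 (default `c(0.8, 0.6)`).
#' @param seed integer seed.
#' @return named list (by shape id) of integer matrices, raters x points,
#'   entries 0 (unpainted) to 3 (tier number); class `painting_set`.
#' @export
simulate_paintings <- function(cohort, shape_ids = names(cohort$exemplars),
                               n_raters = 10L, jitter = 0.1,
                               tier_p = c(0.8, 0.6), seed = 1L) {
  set.seed(seed)
  out <- list()
  for (sid in shape_ids) {
    cc <- cohort_shape(cohort, sid)
    pp <- cohort_parts(cohort, sid)
    n <- n_points(cc)
    M <- matrix(0L, n_raters, n)
    ranked <- if (!is.null(pp) && nrow(pp)) {
      pp[order(-pp$weight), , drop = FALSE]
    } else NULL
    # part-less shapes: raters agree on the highest-curvature stretch
    salient_start <- if (is.null(ranked)) {
      ta <- turning_angles(cc)
      sm <- as.numeric(stats::filter(ta, rep(1, 15L), sides = 2,
                                     circular = TRUE))
      ((which.max(sm) - 1L - round(0.05 * n)) %% n) + 1L
    } else NA_integer_
    for (r in seq_len(n_raters)) {
      usetier <- c(TRUE, stats::runif(2) < tier_p)
      ntier <- if (is.null(ranked)) 1L else min(3L, nrow(ranked))
      for (ti in seq_len(ntier)) {
        if (!usetier[ti]) next
        if (is.null(ranked)) {
          len <- max(3L, round(0.1 * n))
          start <- ((salient_start - 1L +
                       round(stats::rnorm(1, 0, jitter * len))) %% n) + 1L
        } else {
          start <- ranked$span_start[ti]; len <- ranked$span_length[ti]
          start <- ((start - 1L + round(stats::rnorm(1, 0, jitter * len))) %% n) + 1L
          len <- max(2L, round(len * exp(stats::rnorm(1, 0, jitter))))
          len <- min(len, n - 1L)
        }
        idx <- ((start - 1L + seq_len(len) - 1L) %% n) + 1L
        idx <- idx[M[r, idx] == 0L]          # tiers may not overlap
        M[r, idx] <- ti
      }
      if (!any(M[r, ] == 1L)) {              # at least one tier-1 area
        start <- sample.int(n, 1L)
        idx <- ((start - 1L + 0:9L) %% n) + 1L
        M[r, idx] <- 1L
      }
    }
    out[[sid]] <- M
  }
  structure(out, class = "painting_set")
}
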