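#' Resolve a part pick to a contour segment
#'
#' A pick is a chord `(i, j)` plus the chosen side: side 1 is the half-open
#' segment starting at `i` (running clockwise to just before `j`), side 2
#' the complementary segment starting at `j`. The chord must be admissible
#' under [cut_part()].
#'
#' @param contour a `closed_contour`.
#' @param i,j chord endpoint indices (1-based).
#' @param side 1 or 2.
#' @return a `contour_segment`.
#' @export
resolve_pick <- function(contour, i, j, side = 1L) {
  cp <- cut_part(contour, i, j)
  if (!side %in% c(1L, 2L)) stop("side must be 1 or 2")
  if (side == 1L) cp$side1 else cp$side2
}

# picks table (rows with i, j, side, rest_flag) -> list of index sets;
# rest_flag rows resolve to the complement of all other picks in the group
resolve_pick_rows <- function(contour, rows) {
  n <- n_points(contour)
  segs <- vector("list", nrow(rows))
  taken <- integer()
  for (k in seq_len(nrow(rows))) {
    if (isTRUE(rows$rest_flag[k])) next
    seg <- resolve_pick(contour, rows$i[k], rows$j[k], rows$side[k])
    segs[[k]] <- segment_indices(seg)
    taken <- c(taken, segs[[k]])
  }
  for (k in which(rows$rest_flag %in% TRUE)) {
    segs[[k]] <- setdiff(seq_len(n), taken)
  }
  segs
}

#' The circular-median point of a segment
#'
#' The point at half the segment's (point-count) arc length; for even
#' lengths the tie resolves toward the lower index.
#' @param seg a `contour_segment`.
#' @return 1-based point index on the parent contour.
#' @export
segment_median_point <- function(seg) {
  ((seg$start - 1L + (seg$length - 1L) %/% 2L) %% seg$n) + 1L
}

#' Per-point correspondence field for one exemplar-variation pair
#'
#' For every point of the variation: the exemplar segment it was most often
#' included in across raters' picks (modal vote over identical segments),
#' represented by that segment's circular-median point, plus the number of
#' raters whose picks included the point (the colour-saturation support of
#' the overlay figures).
#'
#' @param pairs pick table for ONE exemplar x variation pair: rows in pairs
#'   of `shape_role` `"exemplar"`/`"variation"` sharing `pair_id`, with
#'   columns `rater`, `i`, `j`, `side`, `rest_flag`.
#' @param exemplar,variation the two `closed_contour`s.
#' @return tibble `(point, exemplar_point, support)`; `exemplar_point` is NA
#'   where no rater included the point.
#' @export
point_correspondence_field <- function(pairs, exemplar, variation) {
  nv <- n_points(variation)
  out <- tibble::tibble(point = seq_len(nv),
                        exemplar_point = NA_integer_,
                        support = 0L)
  if (is.null(pairs) || nrow(pairs) == 0L) return(out)
  ids <- unique(pairs$pair_id)
  vote_key <- vector("list", nv)   # exemplar-segment key per vote
  vote_rater <- vector("list", nv)
  med <- list()
  for (pid in ids) {
    er <- pairs[pairs$pair_id == pid & pairs$shape_role == "exemplar", ]
    vr <- pairs[pairs$pair_id == pid & pairs$shape_role == "variation", ]
    if (nrow(er) != 1L || nrow(vr) != 1L) next
    eseg <- resolve_pick(exemplar, er$i, er$j, er$side)
    vidx <- segment_indices(resolve_pick(variation, vr$i, vr$j, vr$side))
    key <- paste(eseg$start, eseg$length)
    med[[key]] <- segment_median_point(eseg)
    for (p in vidx) {
      vote_key[[p]] <- c(vote_key[[p]], key)
      vote_rater[[p]] <- c(vote_rater[[p]], er$rater)
    }
  }
  for (p in seq_len(nv)) {
    if (!length(vote_key[[p]])) next
    tab <- table(vote_key[[p]])
    modal <- names(tab)[which.max(tab)]
    out$exemplar_point[p] <- med[[modal]]
    out$support[p] <- length(unique(vote_rater[[p]]))
  }
  out
}

#' Fraction of an exemplar's area covered by corresponding parts
#'
#' Per rater and trial, the area of the union of the rater's picked exemplar
#' part polygons (segment plus closing chord; picking the rest of the shape
#' covers everything not yet picked) divided by the exemplar's area. The
#' per-trial value averages over raters (raters who saw no correspondence
#' contribute 0), and the headline fraction averages over trials. Trials with
#' unresolvable picks are excluded and reported.
#'
#' @param exemplar the exemplar `closed_contour`.
#' @param picks pick table rows for this exemplar (`shape_role ==
#'   "exemplar"`), with columns `trial`, `rater`, `i`, `j`, `side`,
#'   `rest_flag`.
#' @param n_raters total raters per trial (defaults to the maximum rater id
#'   seen).
#' @param trials optional vector of trial ids that were run (trials with no
#'   picks at all then enter as 0).
#' @return list with `fraction`, `per_trial` (tibble `trial`, `fraction`),
#'   and `excluded` (trial ids dropped for invalid picks).
#' @export
corresponding_area_fraction <- function(exemplar, picks, n_raters = NULL,
                                        trials = NULL) {
  A <- contour_area(exemplar)
  if (is.null(n_raters)) {
    n_raters <- if (nrow(picks)) max(picks$rater) else 1L
  }
  if (is.null(trials)) trials <- unique(picks$trial)
  excluded <- c()
  per_trial <- numeric(0)
  for (t in trials) {
    pt <- picks[picks$trial == t, , drop = FALSE]
    rater_frac <- rep(0, n_raters)
    bad <- FALSE
    if (nrow(pt)) {
      for (r in unique(pt$rater)) {
        rows <- pt[pt$rater == r, , drop = FALSE]
        area_sum <- 0
        ok <- TRUE
        if (any(rows$rest_flag)) { rater_frac[r] <- 1; next }
        for (k in seq_len(nrow(rows))) {
          seg <- tryCatch(resolve_pick(exemplar, rows$i[k], rows$j[k],
                                       rows$side[k]),
                          error = function(e) NULL)
          if (is.null(seg)) { ok <- FALSE; break }
          area_sum <- area_sum +
            abs(polygon_area_xy(part_polygon(exemplar, seg)))
        }
        if (!ok) { bad <- TRUE; break }
        rater_frac[r] <- min(1, area_sum / A)
      }
    }
    if (bad) { excluded <- c(excluded, t); next }
    per_trial <- c(per_trial, mean(rater_frac))
    names(per_trial)[length(per_trial)] <- as.character(t)
  }
  if (length(excluded)) {
    message("excluded ", length(excluded), " trial(s) with unresolvable picks")
  }
  list(fraction = if (length(per_trial)) mean(per_trial) else NA_real_,
       per_trial = tibble::tibble(trial = names(per_trial),
                                  fraction = unname(per_trial)),
       excluded = excluded)
}

polygon_area_xy <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Regress correspondence area on similarity
#'
#' OLS of the mean corresponding-area fraction on the similarity-bin
#' midpoint.
#' @param fractions mean area fraction per bin.
#' @param bin_similarity similarity midpoint per bin (>= 3 bins).
#' @return an [ols_trend()] result list.
#' @export
regress_area_on_similarity <- function(fractions, bin_similarity) {
  if (length(fractions) < 3L) stop("need at least 3 bins")
  ols_trend(bin_similarity, fractions)
}

#' Part circles
#'
#' A part circle is the cyclic, run-length-merged sequence of part labels
#' and gap markers met when traversing a shape clockwise from its left-most
#' point. `GAP` entries mark stretches not covered by any designated part.
#'
#' @param entries character vector of labels with `"GAP"` markers.
#' @return object of class `part_circle`.
#' @export
part_circle <- function(entries) {
  entries <- as.character(entries)
  if (!length(entries)) stop("a part circle needs at least one entry")
  # merge consecutive duplicates, cyclically
  r <- rle(entries)$values
  if (length(r) > 1L && r[1L] == r[length(r)]) r <- r[-length(r)]
  structure(list(entries = r), class = "part_circle")
}

#' @export
print.part_circle <- function(x, ...) {
  cat("[", paste(x$entries, collapse = ", "), "]\n")
  invisible(x)
}

# per-point label assignment -> part circle, traversing clockwise from the
# left-most point
circle_from_assignment <- function(contour, lab) {
  n <- n_points(contour)
  start <- leftmost_start_index(contour)
  ordidx <- ((start - 1L + seq_len(n) - 1L) %% n) + 1L
  ent <- lab[ordidx]
  ent[is.na(ent)] <- "GAP"
  part_circle(ent)
}

#' Build a part circle from labelled picks
#'
#' Each point of the shape is tested for membership in a labelled pick's
#' segment while traversing clockwise from the left-most point; runs of
#' equal labels (or uncovered, gap points) collapse to single entries.
#' Rest-of-shape picks are not localized parts and are excluded. Overlapping
#' picks violate the picking interface and raise an error.
#'
#' @param contour a `closed_contour`.
#' @param picks data frame with columns `label`, `i`, `j`, `side`, and
#'   optionally `rest_flag`.
#' @return a `part_circle`.
#' @export
build_part_circle <- function(contour, picks) {
  n <- n_points(contour)
  lab <- rep(NA_character_, n)
  if (!is.null(picks) && nrow(picks)) {
    if (is.null(picks$rest_flag)) picks$rest_flag <- FALSE
    picks <- picks[!picks$rest_flag, , drop = FALSE]
    for (k in seq_len(nrow(picks))) {
      idx <- segment_indices(resolve_pick(contour, picks$i[k], picks$j[k],
                                          picks$side[k]))
      if (any(!is.na(lab[idx]))) stop("overlapping picks")
      lab[idx] <- picks$label[k]
    }
  }
  circle_from_assignment(contour, lab)
}

#' Build a part circle from ground-truth part spans
#'
#' With `include_body_gaps = TRUE` (default) uncovered body stretches enter
#' as `GAP` entries, mirroring the per-point scan over picks. For part-change
#' analysis the body is not a missing part, so `include_body_gaps = FALSE`
#' yields the idealized circle holding only the part labels in clockwise
#' order — there, omitted/added/substituted parts are the only gap sources.
#'
#' @param contour a `closed_contour`.
#' @param parts ground-truth parts table with `label`, `span_start`,
#'   `span_length` (as stored by the synthetic generator).
#' @param include_body_gaps include uncovered stretches as `GAP` entries.
#' @return a `part_circle`.
#' @export
ground_truth_circle <- function(contour, parts, include_body_gaps = TRUE) {
  n <- n_points(contour)
  lab <- rep(NA_character_, n)
  if (!is.null(parts) && nrow(parts)) {
    for (k in seq_len(nrow(parts))) {
      idx <- segment_indices(contour_segment(parts$span_start[k],
                                             parts$span_length[k], n))
      lab[idx] <- parts$label[k]
    }
  }
  if (!include_body_gaps) {
    if (is.null(parts) || !nrow(parts)) return(part_circle("GAP"))
    start <- leftmost_start_index(contour)
    ordidx <- ((start - 1L + seq_len(n) - 1L) %% n) + 1L
    ent <- lab[ordidx]
    return(part_circle(ent[!is.na(ent)]))
  }
  circle_from_assignment(contour, lab)
}

circle_labels <- function(circle) {
  circle$entries[circle$entries != "GAP"]
}

is_rotation <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!length(a)) return(TRUE)
  any(vapply(seq_along(a), function(k) {
    all(b == a[((seq_along(a) + k - 2L) %% length(a)) + 1L])
  }, FALSE))
}

#' Compare the cyclic part order of two shapes
#'
#' Gap entries are ignored; the comparison asks whether the variation's
#' cyclic sequence of shared labels is a rotation of the exemplar's
#' (`identical`), a rotation of its reversal (`reversed`), or neither
#' (`shuffled`). With two or fewer shared labels cyclic order is not
#' informative (the circle `[A, B]` equals `[B, A]`) and the relation is
#' `undefined`.
#'
#' @param exemplar_circle,variation_circle `part_circle`s.
#' @return list with `relation` in
#'   `c("identical", "reversed", "shuffled", "undefined")`, `n_shared`, and
#'   `reason` (`"no_shared"` / `"too_few"` / `"duplicated_label"` for
#'   undefined results).
#' @export
compare_part_order <- function(exemplar_circle, variation_circle) {
  la <- circle_labels(exemplar_circle)
  lb <- circle_labels(variation_circle)
  shared <- intersect(la, lb)
  if (!length(shared)) {
    return(list(relation = "undefined", n_shared = 0L, reason = "no_shared"))
  }
  a <- la[la %in% shared]
  b <- lb[lb %in% shared]
  if (anyDuplicated(a) || anyDuplicated(b)) {
    return(list(relation = "undefined", n_shared = length(shared),
                reason = "duplicated_label"))
  }
  if (length(shared) <= 2L) {
    return(list(relation = "undefined", n_shared = length(shared),
                reason = "too_few"))
  }
  rel <- if (is_rotation(a, b)) "identical"
         else if (is_rotation(rev(a), b)) "reversed"
         else "shuffled"
  list(relation = rel, n_shared = length(shared), reason = NULL)
}

# walk clockwise in `entries` from the occurrence of `from` to the next
# shared label; report that label and whether a gap (GAP or non-shared
# entry) was crossed
walk_to_next_shared <- function(entries, from, shared) {
  m <- length(entries)
  k0 <- which(entries == from)[1L]
  gap <- FALSE
  for (d in seq_len(m)) {
    e <- entries[((k0 + d - 1L) %% m) + 1L]
    if (e %in% shared) return(list(next_label = e, gap = gap))
    gap <- TRUE
  }
  list(next_label = from, gap = gap)
}

#' Classify part changes between two part circles
#'
#' For each interval between consecutive shared labels in the exemplar's
#' cyclic order: a gap (uncovered stretch or non-shared part) on the
#' exemplar side only is an `omission`, on the variation side only an
#' `addition`, on both sides at the same spot a `substitution`; intervals
#' with no gap on either side report no change. "Same spot" is
#' operationalized as the interval following the same shared label on both
#' circles.
#'
#' @param exemplar_circle,variation_circle `part_circle`s sharing at least
#'   one label.
#' @return tibble `(kind, after_label, before_label)`, one row per change.
#' @export
classify_gap_changes <- function(exemplar_circle, variation_circle) {
  ea <- exemplar_circle$entries
  va <- variation_circle$entries
  shared <- intersect(ea[ea != "GAP"], va[va != "GAP"])
  if (!length(shared)) stop("circles share no labels")
  seq_e <- ea[ea %in% shared]
  out <- list()
  for (lb in seq_e) {
    we <- walk_to_next_shared(ea, lb, shared)
    wv <- walk_to_next_shared(va, lb, shared)
    kind <- if (we$gap && !wv$gap) "omission"
            else if (!we$gap && wv$gap) "addition"
            else if (we$gap && wv$gap) "substitution"
            else NA_character_
    if (!is.na(kind)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        kind = kind, after_label = lb, before_label = we$next_label)
    }
  }
  if (!length(out)) {
    return(tibble::tibble(kind = character(), after_label = character(),
                          before_label = character()))
  }
  do.call(rbind, out)
}
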