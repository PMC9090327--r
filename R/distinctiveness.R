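#' Aggregate tiered paintings into a distinctiveness field
#'
#' Each rater's painting assigns every contour point a tier: 1 (most
#' distinctive, weight 3), 2 (weight 2), 3 (weight 1) or 0 (unpainted,
#' weight 0). Point scores sum across raters and are normalized between 0
#' and 100, where 100 is the highest possible score (`3 * n_raters`,
#' attained only when every rater paints the point tier 1).
#'
#' @param paintings integer matrix, raters x points, entries 0-3.
#' @param shape_id optional shape id carried on the result.
#' @return object of class `distinctiveness_field`: list with `D` (0-100 per
#'   point), `raw`, `n_raters`, `max_raw`, `shape_id`.
#' @export
aggregate_paintings <- function(paintings, shape_id = NULL) {
  M <- as.matrix(paintings)
  if (nrow(M) < 1L) stop("need at least one painting")
  if (!all(M %in% 0:3)) stop("painting tiers must be 0, 1, 2 or 3")
  w <- c(0, 3, 2, 1)
  raw <- colSums(matrix(w[M + 1L], nrow = nrow(M)))
  maxraw <- 3 * nrow(M)
  structure(list(D = 100 * raw / maxraw, raw = raw, n_raters = nrow(M),
                 max_raw = maxraw, shape_id = shape_id),
            class = "distinctiveness_field")
}

#' @export
print.distinctiveness_field <- function(x, ...) {
  cat(sprintf("<distinctiveness_field%s: %d points, %d raters, max D %.1f>\n",
              if (!is.null(x$shape_id)) paste0(" ", x$shape_id) else "",
              length(x$D), x$n_raters, max(x$D)))
  invisible(x)
}

field_values <- function(field) {
  if (inherits(field, "distinctiveness_field")) field$D else as.numeric(field)
}

#' Maximal high-distinctiveness regions
#'
#' Maximal circular runs of points whose score strictly exceeds the
#' threshold (default 75 on the 0-100 scale).
#'
#' @param field a `distinctiveness_field` (or numeric vector of scores).
#' @param threshold strict lower bound (default 75).
#' @return list of `contour_segment`s (empty when no point qualifies).
#' @export
high_score_regions <- function(field, threshold = 75) {
  D <- field_values(field)
  n <- length(D)
  mask <- D > threshold
  if (!any(mask)) return(list())
  if (all(mask)) return(list(contour_segment(1L, n, n)))
  prev <- c(mask[n], mask[-n])
  starts <- which(mask & !prev)
  lapply(starts, function(s) {
    len <- 1L
    while (mask[((s - 1L + len) %% n) + 1L]) len <- len + 1L
    contour_segment(s, len, n)
  })
}

#' Perimeter share of high-distinctiveness regions
#'
#' Arc-length share of the largest (default) or of all high-score region(s),
#' on contours resampled to equal spacing, so the share equals the covered
#' point count over the total.
#'
#' @param field a `distinctiveness_field` or numeric score vector.
#' @param mode `"largest"` (the mean-consecutive-area statistic) or
#'   `"total"`.
#' @param threshold strict threshold (default 75).
#' @return fraction in `[0, 1]`.
#' @export
high_region_perimeter_fraction <- function(field, mode = c("largest", "total"),
                                           threshold = 75) {
  mode <- match.arg(mode)
  regs <- high_score_regions(field, threshold)
  if (!length(regs)) return(0)
  lens <- vapply(regs, function(s) s$length, 0L)
  n <- regs[[1L]]$n
  if (mode == "largest") max(lens) / n else sum(lens) / n
}

#' Fit the randomized-response null model from human paintings
#'
#' Estimates, per distinctiveness tier: how often the tier was used at all,
#' the distribution of consecutive painted run lengths, and the distribution
#' of the number of non-consecutive painted areas per painting. These
#' empirical distributions drive [sample_null_paintings()], which mimics
#' human painting extent while placing paint uniformly at random.
#'
#' @param paintings a `painting_set` (named list of rater x point matrices)
#'   or a single matrix; typically all paintings of one category.
#' @return object of class `painting_null_model` with `usage`,
#'   `run_lengths`, `area_counts` (each indexed by tier 1-3), `n_points`.
#' @export
fit_null_model <- function(paintings) {
  if (is.matrix(paintings)) paintings <- list(paintings)
  if (!length(paintings)) stop("need at least one painting")
  usage <- numeric(3)
  run_lengths <- vector("list", 3)
  area_counts <- vector("list", 3)
  n_paint <- 0L
  npts <- ncol(paintings[[1L]])
  for (M in paintings) {
    for (r in seq_len(nrow(M))) {
      n_paint <- n_paint + 1L
      for (t in 1:3) {
        runs <- circular_runs(M[r, ] == t)
        if (length(runs)) {
          usage[t] <- usage[t] + 1
          run_lengths[[t]] <- c(run_lengths[[t]], runs)
          area_counts[[t]] <- c(area_counts[[t]], length(runs))
        }
      }
    }
  }
  structure(list(usage = usage / n_paint, run_lengths = run_lengths,
                 area_counts = area_counts, n_points = npts,
                 n_paintings = n_paint),
            class = "painting_null_model")
}

# lengths of circular runs of TRUE
circular_runs <- function(mask) {
  n <- length(mask)
  if (!any(mask)) return(integer())
  if (all(mask)) return(n)
  prev <- c(mask[n], mask[-n])
  starts <- which(mask & !prev)
  vapply(starts, function(s) {
    len <- 1L
    while (mask[((s - 1L + len) %% n) + 1L]) len <- len + 1L
    len
  }, 0L)
}

#' Sample randomized paintings from a fitted null model
#'
#' Draws, for each simulated rater and shape, tier usage, area counts and
#' run lengths from the model's empirical distributions and places the runs
#' uniformly at random on the contour, rejecting overlaps (bounded retries;
#' on exhaustion fresh lengths are drawn and the event is counted in the
#' `retries_exhausted` attribute). Tier 1 is always present, as the painting
#' interface required.
#'
#' @param model a `painting_null_model`.
#' @param shape_ids ids of the shapes to paint.
#' @param n_raters simulated raters per shape.
#' @param seed integer seed.
#' @param max_tries placement retries per run (default 50).
#' @return a `painting_set` (named list of rater x point matrices).
#' @export
sample_null_paintings <- function(model, shape_ids, n_raters = 10L, seed = 1L,
                                  max_tries = 50L) {
  set.seed(seed)
  n <- model$n_points
  exhausted <- 0L
  draw1 <- function(v, fallback) {
    if (length(v)) v[sample.int(length(v), 1L)] else fallback
  }
  out <- list()
  for (sid in shape_ids) {
    M <- matrix(0L, n_raters, n)
    for (r in seq_len(n_raters)) {
      for (t in 1:3) {
        use <- if (t == 1L) TRUE else stats::runif(1) < model$usage[t]
        if (!use) next
        cnt <- draw1(model$area_counts[[t]], if (t == 1L) 1L else 0L)
        placed <- 0L
        while (placed < cnt) {
          len <- min(draw1(model$run_lengths[[t]], max(3L, round(0.05 * n))),
                     n - sum(M[r, ] > 0L))
          if (len < 1L) break
          ok <- FALSE
          for (tries in seq_len(max_tries)) {
            s <- sample.int(n, 1L)
            idx <- ((s - 1L + seq_len(len) - 1L) %% n) + 1L
            if (all(M[r, idx] == 0L)) { M[r, idx] <- t; ok <- TRUE; break }
          }
          if (!ok) exhausted <- exhausted + 1L
          placed <- placed + 1L
        }
      }
      if (!any(M[r, ] == 1L)) {
        free <- which(M[r, ] == 0L)
        M[r, free[1L]] <- 1L
      }
    }
    out[[sid]] <- M
  }
  structure(out, class = "painting_set", retries_exhausted = exhausted)
}

#' Compare human and randomized painting agreement
#'
#' Two-sample Kolmogorov-Smirnov test on the per-shape high-score perimeter
#' fractions of human versus null distinctiveness fields: concentrated human
#' agreement produces large consecutive high-score regions, random placement
#' does not.
#'
#' @param human_fields,null_fields lists of `distinctiveness_field`s (or
#'   numeric vectors of precomputed fractions).
#' @param mode,threshold passed to [high_region_perimeter_fraction()].
#' @return list with `statistic`, `p_value`, `human_fractions`,
#'   `null_fractions`.
#' @export
compare_agreement <- function(human_fields, null_fields,
                              mode = "largest", threshold = 75) {
  as_frac <- function(x) {
    if (is.numeric(x)) return(x)
    vapply(x, high_region_perimeter_fraction, 0, mode = mode,
           threshold = threshold)
  }
  h <- as_frac(human_fields); z <- as_frac(null_fields)
  res <- ks_2samp(h, z)
  list(statistic = res$statistic, p_value = res$p_value,
       human_fractions = h, null_fractions = z)
}

#' Correlate part distinctiveness across corresponding parts
#'
#' For each correspondence pair, the mean distinctiveness score over the
#' exemplar segment is compared with the mean score over the matched
#' variation segment; Pearson correlation across pairs.
#'
#' @param pair_segments tibble with one row per pair: `exemplar_id`,
#'   `e_start`, `e_length`, `shape_id`, `v_start`, `v_length`.
#' @param fields named list of `distinctiveness_field`s keyed by shape id.
#' @return list with `r`, `p_value`, `n`, and the paired mean scores
#'   (`exemplar_scores`, `variation_scores`).
#' @export
correlate_part_distinctiveness <- function(pair_segments, fields) {
  if (nrow(pair_segments) < 3L) stop("need at least 3 pairs")
  seg_mean <- function(sid, start, len) {
    f <- fields[[sid]]
    if (is.null(f)) return(NA_real_)
    D <- field_values(f)
    n <- length(D)
    mean(D[((start - 1L + seq_len(len) - 1L) %% n) + 1L])
  }
  es <- mapply(seg_mean, pair_segments$exemplar_id, pair_segments$e_start,
               pair_segments$e_length)
  vs <- mapply(seg_mean, pair_segments$shape_id, pair_segments$v_start,
               pair_segments$v_length)
  keep <- is.finite(es) & is.finite(vs)
  res <- pearson_r(es[keep], vs[keep])
  list(r = res$r, p_value = res$p_value, n = sum(keep),
       exemplar_scores = es[keep], variation_scores = vs[keep])
}

#' Resolve pick chords to segment endpoints for field comparisons
#'
#' Converts paired picks (exemplar + variation rows sharing `pair_id`) into
#' the flat segment table consumed by [correlate_part_distinctiveness()].
#'
#' @param picks pick table as produced by [simulate_correspondence()].
#' @param get_contour function mapping a shape id to its `closed_contour`.
#' @return tibble `(exemplar_id, e_start, e_length, shape_id, v_start,
#'   v_length)`.
#' @export
picks_to_segments <- function(picks, get_contour) {
  rows <- list()
  for (pid in unique(picks$pair_id)) {
    er <- picks[picks$pair_id == pid & picks$shape_role == "exemplar", ]
    vr <- picks[picks$pair_id == pid & picks$shape_role == "variation", ]
    if (nrow(er) != 1L || nrow(vr) != 1L) next
    if (isTRUE(er$rest_flag) || isTRUE(vr$rest_flag)) next
    eseg <- tryCatch(resolve_pick(get_contour(er$shape_id), er$i, er$j, er$side),
                     error = function(e) NULL)
    vseg <- tryCatch(resolve_pick(get_contour(vr$shape_id), vr$i, vr$j, vr$side),
                     error = function(e) NULL)
    if (is.null(eseg) || is.null(vseg)) next
    rows[[length(rows) + 1L]] <- tibble::tibble(
      exemplar_id = er$shape_id, e_start = eseg$start, e_length = eseg$length,
      shape_id = vr$shape_id, v_start = vseg$start, v_length = vseg$length)
  }
  if (!length(rows)) {
    return(tibble::tibble(exemplar_id = character(), e_start = integer(),
                          e_length = integer(), shape_id = character(),
                          v_start = integer(), v_length = integer()))
  }
  do.call(rbind, rows)
}
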