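#' Extract the distinctive part of a shape
#'
#' The largest maximal circular run of contour points whose distinctiveness
#' score strictly exceeds 75; ties break toward the higher mean score, then
#' the lower start index. Shapes with no point above threshold are
#' ineligible and raise an error.
#'
#' @param field a `distinctiveness_field` (or numeric score vector).
#' @param threshold strict threshold (default 75).
#' @return a `contour_segment`.
#' @export
extract_distinctive_part <- function(field, threshold = 75) {
  regs <- high_score_regions(field, threshold)
  if (!length(regs)) {
    stop("no point exceeds the distinctiveness threshold; shape ineligible")
  }
  D <- field_values(field)
  n <- length(D)
  lens <- vapply(regs, function(s) s$length, 0L)
  means <- vapply(regs, function(s) mean(D[segment_indices(s)]), 0)
  starts <- vapply(regs, function(s) s$start, 0L)
  o <- order(-lens, -means, starts)
  regs[[o[1L]]]
}

#' Select the least distinctive window of fixed size
#'
#' Among all circular windows of exactly `n_window` points that do not
#' overlap `exclude`, the one with the lowest mean distinctiveness score;
#' ties break toward the lowest start index.
#'
#' @param field a `distinctiveness_field` or numeric score vector.
#' @param n_window window size in points.
#' @param exclude a `contour_segment` to avoid (typically the distinctive
#'   part), or `NULL`.
#' @return a `contour_segment`.
#' @export
select_indistinctive_part <- function(field, n_window, exclude = NULL) {
  D <- field_values(field)
  n <- length(D)
  if (!is.null(exclude) && n_window >= n - exclude$length) {
    stop("no window of that size avoids the excluded segment")
  }
  blocked <- logical(n)
  if (!is.null(exclude)) blocked[segment_indices(exclude)] <- TRUE
  # window mean and window-overlap via cumulative sums over a doubled vector
  cs <- cumsum(c(0, rep(D, 2)))
  cb <- cumsum(c(0, rep(as.numeric(blocked), 2)))
  starts <- seq_len(n)
  wsum <- cs[starts + n_window] - cs[starts]
  wblk <- cb[starts + n_window] - cb[starts]
  feasible <- wblk == 0
  if (!any(feasible)) stop("no feasible window")
  means <- wsum / n_window
  cand <- which(feasible)
  best <- cand[order(means[cand], cand)][1L]
  contour_segment(best, n_window, n)
}

#' Transplant a donor part into a gap of a recipient contour
#'
#' Removes the `gap` segment from the recipient and inserts the donor part
#' mapped by the unique rotation + uniform scale + translation that takes
#' the donor part's two endpoints exactly onto the points flanking the gap.
#' Of the two mirror solutions, the one pointing outward (maximizing the
#' area of the resulting polygon) is kept. The result is re-closed and
#' resampled to the recipient's point count.
#'
#' @param recipient a `closed_contour`.
#' @param gap a `contour_segment` on the recipient: the points to replace.
#' @param donor the donor `closed_contour`.
#' @param donor_part a `contour_segment` on the donor: the part to insert.
#' @return list with `contour` (resampled), `raw` (before resampling; all
#'   recipient points outside the gap preserved exactly), and `transform`
#'   (`rotation` in radians, `scale`, `translation`, `mirrored`).
#' @export
transplant_part <- function(recipient, gap, donor, donor_part) {
  n <- n_points(recipient)
  gi <- segment_indices(gap)
  a1i <- ((gap$start - 2L) %% n) + 1L                 # retained point before
  a2i <- ((gap$start - 1L + gap$length) %% n) + 1L    # retained point after
  P <- recipient$points
  a1 <- complex(real = P[a1i, 1L], imaginary = P[a1i, 2L])
  a2 <- complex(real = P[a2i, 1L], imaginary = P[a2i, 2L])
  Q <- donor$points[segment_indices(donor_part), , drop = FALSE]
  qz <- complex(real = Q[, 1L], imaginary = Q[, 2L])
  q1 <- qz[1L]; q2 <- qz[length(qz)]
  if (Mod(q2 - q1) < 1e-12) stop("zero-length donor chord")
  # direct and mirrored two-point similarity fits
  aa <- (a2 - a1) / (q2 - q1)
  w_direct <- aa * (qz - q1) + a1
  bb <- (a2 - a1) / Conj(q2 - q1)
  w_mirror <- bb * Conj(qz - q1) + a1
  retained <- setdiff(seq_len(n), gi)
  # circular order of retained points starting at a2 and ending at a1
  ord <- ((a2i - 1L + seq_len(n) - 1L) %% n) + 1L
  ord <- ord[ord %in% retained]
  assemble <- function(w) {
    ins <- if (length(w) > 2L) w[2:(length(w) - 1L)] else complex(0)
    rbind(P[ord, , drop = FALSE], cbind(Re(ins), Im(ins)))
  }
  cand_d <- assemble(w_direct)
  cand_m <- assemble(w_mirror)
  area_of <- function(M) abs(polygon_area_xy(M))
  use_mirror <- area_of(cand_m) > area_of(cand_d)
  pts <- if (use_mirror) cand_m else cand_d
  tf <- if (use_mirror) bb else aa
  raw <- closed_contour(pts, id = recipient$id, category = recipient$category,
                        normalize = FALSE)
  out <- resample_contour(raw, n)
  out$stroke_mode <- recipient$stroke_mode
  list(contour = out, raw = raw,
       transform = list(rotation = Arg(tf), scale = Mod(tf),
                        translation = c(Re(a1 - tf * q1), Im(a1 - tf * q1)),
                        mirrored = use_mirror))
}

#' Screen a synthesized stimulus for artefacts
#'
#' Automated stand-in for manual curation of well-formed shapes: a stimulus
#' passes when its contour is a simple polygon and no two non-adjacent
#' points come closer than `clearance_frac` of the mean point spacing.
#'
#' @param contour a `closed_contour`.
#' @param clearance_frac minimum non-adjacent point clearance as a fraction
#'   of mean spacing (default 0.5).
#' @return list with `pass` (logical) and `reason` (`NA` when passing).
#' @export
screen_stimulus <- function(contour, clearance_frac = 0.5) {
  if (self_intersects(contour)) {
    return(list(pass = FALSE, reason = "self_intersection"))
  }
  p <- contour$points
  n <- nrow(p)
  spacing <- perimeter(contour) / n
  dm <- as.matrix(stats::dist(p))
  idx <- abs(outer(seq_len(n), seq_len(n), "-"))
  adjacent <- idx <= 1L | idx >= n - 1L
  minclear <- min(dm[!adjacent])
  if (minclear < clearance_frac * spacing) {
    return(list(pass = FALSE, reason = "insufficient_clearance"))
  }
  list(pass = TRUE, reason = NA_character_)
}

#' Build the full part-swap stimulus design
#'
#' For every base category x donor category x condition cell, synthesizes
#' `bases_per_cell` stimuli: the base shape's distinctive part (condition
#' `"distinctive"`) or its least distinctive same-size window (condition
#' `"indistinctive"`) is replaced by the donor exemplar's distinctive or
#' least-distinctive part, respectively. Candidate base shapes are consumed
#' in seeded order until enough pass screening; shortfalls are reported.
#' With the study's defaults the design holds 8 x 7 x 2 x 5 = 560 stimuli.
#'
#' @param cohort a `shape_cohort` (supplies exemplar and base contours).
#' @param fields named list of `distinctiveness_field`s covering every
#'   exemplar and candidate base shape.
#' @param bases tibble `(shape_id, category)` of candidate base shapes.
#' @param donors_per_category donor categories per base category (default 7,
#'   i.e. all others).
#' @param conditions subset of `c("distinctive", "indistinctive")`.
#' @param bases_per_cell stimuli per cell (default 5).
#' @param threshold distinctiveness threshold (default 75).
#' @param seed integer seed (orders base candidates).
#' @return tibble with one row per stimulus (`stimulus_id`, `base_id`,
#'   `category`, `donor_category`, `condition`, `scale`, `rotation`,
#'   `mirrored`, `contour` list-column); cell shortfalls in attribute
#'   `"report"`.
#' @export
build_swap_design <- function(cohort, fields, bases,
                              donors_per_category = 7L,
                              conditions = c("distinctive", "indistinctive"),
                              bases_per_cell = 5L, threshold = 75,
                              seed = 1L) {
  set.seed(seed)
  base_cats <- sort(unique(bases$category))
  # donor categories: every category with an exemplar field
  all_cats <- sort(as.integer(sub("^E", "",
    grep("^E[0-9]+$", names(cohort$exemplars), value = TRUE))))
  donor_parts <- list()
  for (c0 in all_cats) {
    eid <- paste0("E", c0)
    f <- fields[[eid]]
    if (is.null(f)) stop("missing field for exemplar ", eid)
    dp <- extract_distinctive_part(f, threshold)
    ip <- select_indistinctive_part(f, dp$length, exclude = dp)
    donor_parts[[eid]] <- list(distinctive = dp, indistinctive = ip)
  }
  rows <- list(); report <- list()
  for (c0 in base_cats) {
    pool <- bases$shape_id[bases$category == c0]
    pool <- pool[sample.int(length(pool))]
    donors <- setdiff(all_cats, c0)[seq_len(min(donors_per_category,
                                                length(all_cats) - 1L))]
    for (d0 in donors) {
      for (cond in conditions) {
        made <- 0L; tried <- 0L
        for (bid in pool) {
          if (made >= bases_per_cell) break
          tried <- tried + 1L
          bf <- fields[[bid]]
          if (is.null(bf)) next
          base_cc <- cohort_shape(cohort, bid)
          res <- tryCatch({
            bdp <- extract_distinctive_part(bf, threshold)
            gap <- if (cond == "distinctive") bdp else {
              select_indistinctive_part(bf, bdp$length, exclude = bdp)
            }
            donor_cc <- cohort_shape(cohort, paste0("E", d0))
            dpart <- donor_parts[[paste0("E", d0)]][[cond]]
            transplant_part(base_cc, gap, donor_cc, dpart)
          }, error = function(e) NULL)
          if (is.null(res)) next
          scr <- screen_stimulus(res$contour)
          if (!scr$pass) next
          made <- made + 1L
          rows[[length(rows) + 1L]] <- tibble::tibble(
            stimulus_id = sprintf("SW_b%d_d%d_%s_%02d", c0, d0,
                                  substr(cond, 1, 4), made),
            base_id = bid, category = c0, donor_category = d0,
            condition = cond, scale = res$transform$scale,
            rotation = res$transform$rotation,
            mirrored = res$transform$mirrored,
            contour = list(res$contour))
        }
        if (made < bases_per_cell) {
          report[[length(report) + 1L]] <- tibble::tibble(
            category = c0, donor_category = d0, condition = cond,
            requested = bases_per_cell, produced = made, tried = tried)
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else tibble::tibble()
  attr(out, "report") <- if (length(report)) do.call(rbind, report) else NULL
  out
}

#' Simulate categorization of swap stimuli
#'
#' A cue-based observer model keyed to ground truth: with probability
#' `lapse` the response is uniform over all categories; otherwise, with
#' probability `reliance` the observer follows the distinctive-part cue
#' (which points to the donor category when the distinctive part was
#' swapped, to the base category otherwise), and with the remaining
#' probability the body cue (the base category, misread uniformly with
#' probability `body_noise` when the body was altered by an indistinctive
#' swap). This reproduces the qualitative accuracy ordering unswapped >
#' indistinctive-swapped > distinctive-swapped.
#'
#' @param stimuli tibble with `stimulus_id`, `category` (base),
#'   `donor_category` and `condition` in
#'   `c("none", "distinctive", "indistinctive")`.
#' @param n_raters raters (default 15).
#' @param reliance probability of using the distinctive-part cue.
#' @param lapse uniform-guess probability.
#' @param body_noise body-cue misread probability for altered bodies.
#' @param n_categories number of categories (default 8).
#' @param seed integer seed.
#' @return tibble `(rater, stimulus_id, condition, true, response)`.
#' @export
simulate_swap_classification <- function(stimuli, n_raters = 15L,
                                         reliance = 0.55, lapse = 0.12,
                                         body_noise = 0.25,
                                         n_categories = 8L, seed = 1L) {
  set.seed(seed)
  n <- nrow(stimuli)
  out <- vector("list", n_raters)
  for (r in seq_len(n_raters)) {
    resp <- integer(n)
    for (k in seq_len(n)) {
      cond <- stimuli$condition[k]
      base <- stimuli$category[k]
      donor <- if (cond == "none") base else stimuli$donor_category[k]
      u <- stats::runif(1)
      if (u < lapse) {
        resp[k] <- sample.int(n_categories, 1L)
      } else if (stats::runif(1) < reliance) {
        resp[k] <- if (cond == "distinctive") donor else base
      } else {
        body_ok <- cond != "indistinctive" || stats::runif(1) >= body_noise
        resp[k] <- if (body_ok) base else sample.int(n_categories, 1L)
      }
    }
    out[[r]] <- tibble::tibble(rater = r, stimulus_id = stimuli$stimulus_id,
                               condition = stimuli$condition,
                               true = stimuli$category, response = resp)
  }
  do.call(rbind, out)
}
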