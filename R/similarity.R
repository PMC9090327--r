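#' Normalize similarity placements for one rater and category
#'
#' Placements are distances on the rater's horizontal axis. Each value is
#' `|x - x_exemplar|`, rescaled so the exemplar maps to 0 and the rater's
#' most-distant shape to 1 — making the result invariant to affine changes
#' of the rater's screen axis. Normalization is per rater and category over
#' the full session.
#'
#' @param x raw x positions of the shapes.
#' @param x_exemplar the rater's exemplar position (scalar or vector).
#' @return numeric vector of normalized similarities in `[0, 1]`.
#' @export
normalize_ratings <- function(x, x_exemplar) {
  d <- abs(x - x_exemplar)
  m <- max(d)
  if (m == 0) stop("degenerate placements: all shapes at the exemplar position")
  d / m
}

#' Aggregate normalized similarity across raters
#'
#' Applies [normalize_ratings()] within each rater x category cell of a
#' placement table, then averages across raters per shape: the shape's
#' similarity score `s` in `[0, 1]` (0 = exemplar-like), with the unbiased
#' between-rater variance and rater count. Shapes missing for some raters
#' are averaged over the raters that placed them.
#'
#' @param placements data frame with columns `rater`, `category`, `shape`,
#'   `x`, `x_exemplar` (as written to `placements.csv`).
#' @return tibble `(category, shape, s, var_s, n_raters)`.
#' @export
aggregate_similarity <- function(placements) {
  pl <- placements
  key <- interaction(pl$rater, pl$category, drop = TRUE)
  s_norm <- numeric(nrow(pl))
  for (ii in split(seq_len(nrow(pl)), key)) {
    s_norm[ii] <- normalize_ratings(pl$x[ii], pl$x_exemplar[ii])
  }
  sp <- split(s_norm, pl$shape, drop = TRUE)
  cat_of <- tapply(pl$category, pl$shape, function(z) z[1L])
  shapes <- names(sp)
  tibble::tibble(
    category = as.vector(cat_of[shapes]),
    shape = shapes,
    s = unname(vapply(sp, mean, 0)),
    var_s = unname(vapply(sp, function(z) {
      if (length(z) > 1L) stats::var(z) else 0
    }, 0)),
    n_raters = unname(vapply(sp, length, 0L)))
}

#' Per-drawer creativity index
#'
#' A drawer's creativity is the mean perceived similarity of their drawings
#' to the exemplar (lower similarity = more creative), with its standard
#' error.
#'
#' @param cohort a `shape_cohort` (for drawer attribution).
#' @param scores output of [aggregate_similarity()].
#' @return tibble `(drawer, mean_s, se_s, n)`, ordered by drawer id.
#' @export
creativity_index <- function(cohort, scores) {
  v <- cohort$variations
  s <- scores$s[match(v$shape_id, scores$shape)]
  keep <- !is.na(s)
  sp <- split(s[keep], v$drawer[keep])
  tibble::tibble(
    drawer = as.integer(names(sp)),
    mean_s = unname(vapply(sp, mean, 0)),
    se_s = unname(vapply(sp, function(z) stats::sd(z) / sqrt(length(z)), 0)),
    n = unname(vapply(sp, length, 0L)))
}

#' Trend of similarity over drawing order
#'
#' Ordinary least squares of the similarity score on the within-session
#' drawing index (1..12): did drawings drift more or less similar over time?
#' Reported per drawer and pooled.
#'
#' @param cohort a `shape_cohort` (for drawer and index attribution).
#' @param scores output of [aggregate_similarity()].
#' @return list with `pooled` (an [ols_trend()] result) and `per_drawer`
#'   (tibble of slope/R-squared/F/p per drawer; drawers with fewer than
#'   3 scored drawings are flagged `degenerate`).
#' @export
order_trend <- function(cohort, scores) {
  v <- cohort$variations
  s <- scores$s[match(v$shape_id, scores$shape)]
  keep <- !is.na(s)
  pooled <- ols_trend(v$index[keep], s[keep])
  sp <- split(seq_len(nrow(v))[keep], v$drawer[keep])
  per <- lapply(names(sp), function(d) {
    ii <- sp[[d]]
    tr <- ols_trend(v$index[ii], s[ii])
    tibble::tibble(drawer = as.integer(d), slope = tr$slope,
                   r_squared = tr$r_squared, f_statistic = tr$f_statistic,
                   p_value = tr$p_value, n = tr$n,
                   degenerate = isTRUE(tr$degenerate))
  })
  list(pooled = pooled, per_drawer = do.call(rbind, per))
}

#' Select a similarity-spanning stimulus subset
#'
#' Divides `[0, 1]` into `n_bins` equal-width bins over the similarity score
#' and returns, per bin, the shape with the lowest between-rater variance.
#' Empty bins are filled from neighbouring bins searched at increasing
#' distance (+1, -1, +2, -2, ...) with a not-yet-used shape, or skipped when
#' none remains. Output ids are unique and reported in bin order, so their
#' scores are non-decreasing (up to neighbour fills).
#'
#' @param scores output of [aggregate_similarity()] for ONE category.
#' @param n_bins number of bins (the study used 20 or 40).
#' @return character vector of shape ids (at most `n_bins`), with the source
#'   bin as attribute `"bin"`.
#' @export
select_spanning_subset <- function(scores, n_bins) {
  if (nrow(scores) == 0L) stop("no scores supplied")
  if (n_bins < 1L) stop("n_bins must be >= 1")
  if (n_bins > nrow(scores)) {
    warning("more bins than shapes; returning fewer ids")
  }
  bin <- pmin(pmax(ceiling(scores$s * n_bins), 1L), n_bins)
  used <- character()
  sel <- character(); selbin <- integer()
  pick_from <- function(b) {
    cand <- which(bin == b & !(scores$shape %in% used))
    if (!length(cand)) return(NULL)
    cand[order(scores$var_s[cand], scores$shape[cand])][1L]
  }
  for (b in seq_len(n_bins)) {
    k <- pick_from(b)
    if (is.null(k)) {
      for (d in seq_len(n_bins - 1L)) {
        for (nb in c(b + d, b - d)) {
          if (nb >= 1L && nb <= n_bins) {
            k <- pick_from(nb)
            if (!is.null(k)) break
          }
        }
        if (!is.null(k)) break
      }
    }
    if (is.null(k)) next
    used <- c(used, scores$shape[k])
    sel <- c(sel, scores$shape[k]); selbin <- c(selbin, b)
  }
  structure(sel, bin = selbin)
}
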