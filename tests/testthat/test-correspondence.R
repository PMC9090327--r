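# convex test polygon on which every chord is admissible
convex36 <- function() resample_contour(circle_contour(36, 10), 36)

test_that("picks resolve to complementary segments with a known median", {
  cc <- convex36()
  s1 <- resolve_pick(cc, 5, 15, side = 1)
  s2 <- resolve_pick(cc, 5, 15, side = 2)
  expect_equal(s1$start, 5L); expect_equal(s1$length, 10L)
  expect_equal(s2$start, 15L); expect_equal(s2$length, 26L)
  # circular median: halfway, even lengths resolve toward the lower index
  expect_equal(segment_median_point(s1), 9L)
  expect_equal(segment_median_point(contour_segment(5, 3, 36)), 6L)
  expect_equal(segment_median_point(contour_segment(35, 4, 36)), 36L)
})

test_that("point correspondence field maps modal segments with support", {
  ex <- convex36(); vr <- convex36()
  one <- tibble::tibble(
    trial = 1L, rater = 1L,
    shape_role = c("exemplar", "variation"), shape_id = c("E", "V"),
    i = c(5L, 7L), j = c(15L, 17L), side = 1L, rest_flag = FALSE,
    pair_id = 1L, label = "P1")
  f1 <- point_correspondence_field(one, ex, vr)
  vidx <- segment_indices(contour_segment(7, 10, 36))
  expect_true(all(f1$exemplar_point[vidx] == 9L))
  expect_true(all(f1$support[vidx] == 1L))
  expect_true(all(is.na(f1$exemplar_point[-vidx])))

  # identical second rater doubles the support
  two <- rbind(one, within(one, { rater <- 2L; pair_id <- 2L }))
  f2 <- point_correspondence_field(two, ex, vr)
  expect_true(all(f2$support[vidx] == 2L))

  # 3-vs-2 disagreement: the modal (3-vote) exemplar segment wins
  maj <- do.call(rbind, lapply(1:5, function(r) {
    ij <- if (r <= 3) c(5L, 15L) else c(20L, 30L)
    tibble::tibble(trial = 1L, rater = r,
                   shape_role = c("exemplar", "variation"),
                   shape_id = c("E", "V"),
                   i = c(ij[1], 7L), j = c(ij[2], 17L), side = 1L,
                   rest_flag = FALSE, pair_id = r, label = "P1")
  }))
  f3 <- point_correspondence_field(maj, ex, vr)
  expect_true(all(f3$exemplar_point[vidx] ==
                    segment_median_point(contour_segment(5, 10, 36))))
  expect_true(all(f3$support[vidx] == 5L))
  # no picks -> empty field
  f0 <- point_correspondence_field(one[0, ], ex, vr)
  expect_true(all(is.na(f0$exemplar_point)))
})

test_that("corresponding area fraction sums picked part polygons", {
  cc <- convex36()
  A <- contour_area(cc)
  no_picks <- tibble::tibble(trial = integer(), rater = integer(),
                             i = integer(), j = integer(), side = integer(),
                             rest_flag = logical())
  expect_equal(corresponding_area_fraction(cc, no_picks, n_raters = 2,
                                           trials = 1)$fraction, 0)
  rest <- tibble::tibble(trial = 1L, rater = 1L, i = NA_integer_,
                         j = NA_integer_, side = NA_integer_, rest_flag = TRUE)
  expect_equal(corresponding_area_fraction(cc, rest, n_raters = 1)$fraction, 1)

  # two disjoint picks: fraction = (a1 + a2) / A, against a shoelace oracle
  pk <- tibble::tibble(trial = 1L, rater = 1L, i = c(2L, 20L), j = c(10L, 30L),
                       side = 1L, rest_flag = FALSE)
  shoelace <- function(p) {
    x <- p[, 1]; y <- p[, 2]
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }
  a1 <- shoelace(cc$points[c(2:10), ])
  a2 <- shoelace(cc$points[c(20:30), ])
  res <- corresponding_area_fraction(cc, pk, n_raters = 1)
  expect_equal(res$fraction, (a1 + a2) / A, tolerance = 1e-12)

  # averaging over raters: second rater saw nothing
  res2 <- corresponding_area_fraction(cc, pk, n_raters = 2)
  expect_equal(res2$fraction, (a1 + a2) / A / 2, tolerance = 1e-12)
  # monotone: adding a pick cannot decrease the fraction
  pk3 <- rbind(pk, tibble::tibble(trial = 1L, rater = 1L, i = 12L, j = 18L,
                                  side = 1L, rest_flag = FALSE))
  expect_gte(corresponding_area_fraction(cc, pk3, n_raters = 2)$fraction,
             res2$fraction)
})

test_that("area-fraction union agrees with a Monte-Carlo oracle", {
  cc <- convex36()
  pk <- tibble::tibble(trial = 1L, rater = 1L, i = c(3L, 25L), j = c(14L, 33L),
                       side = 1L, rest_flag = FALSE)
  res <- corresponding_area_fraction(cc, pk, n_raters = 1)
  set.seed(5)
  bb <- apply(cc$points, 2, range)
  pts <- cbind(runif(2e5, bb[1, 1], bb[2, 1]), runif(2e5, bb[1, 2], bb[2, 2]))
  inside_any <- oracle_in_polygon(cc$points[c(3:14), ], pts) |
    oracle_in_polygon(cc$points[c(25:33), ], pts)
  mc <- mean(inside_any) * prod(bb[2, ] - bb[1, ]) / contour_area(cc)
  expect_equal(res$fraction, mc, tolerance = 0.02)
})

test_that("regressing area on similarity matches OLS oracle", {
  expect_equal(regress_area_on_similarity(c(0.9, 0.6, 0.3), c(0.1, 0.5, 0.9))$r_squared,
               1, tolerance = 1e-10)
  expect_equal(regress_area_on_similarity(rep(0.5, 5), seq(0, 1, length.out = 5))$slope, 0)
  expect_error(regress_area_on_similarity(c(1, 2), c(1, 2)), "3 bins")
})

test_that("part circles merge runs cyclically from the left-most point", {
  expect_equal(part_circle(c("A", "A", "B", "B", "C"))$entries, c("A", "B", "C"))
  expect_equal(part_circle(c("A", "B", "A", "A"))$entries, c("A", "B"))
  expect_equal(part_circle("GAP")$entries, "GAP")

  cc <- convex36()
  picks <- tibble::tibble(label = c("A", "B", "C"),
                          i = c(1L, 13L, 25L), j = c(13L, 25L, 1L),
                          side = 1L, rest_flag = FALSE)
  expect_setequal(build_part_circle(cc, picks)$entries, c("A", "B", "C"))
  # uncovered stretches appear as gaps
  picks2 <- tibble::tibble(label = c("A", "C"), i = c(1L, 18L), j = c(8L, 26L),
                           side = 1L, rest_flag = FALSE)
  pc2 <- build_part_circle(cc, picks2)
  expect_setequal(unique(pc2$entries), c("A", "C", "GAP"))
  # per-point scan oracle
  lab <- rep("GAP", 36)
  lab[1:7] <- "A"; lab[18:25] <- "C"
  start <- leftmost_start_index(cc)
  oracle <- rle(lab[((start - 1 + 0:35) %% 36) + 1])$values
  if (length(oracle) > 1 && oracle[1] == oracle[length(oracle)]) {
    oracle <- oracle[-length(oracle)]
  }
  expect_equal(pc2$entries, oracle)
  # no picks -> [GAP]; overlapping picks -> error
  expect_equal(build_part_circle(cc, NULL)$entries, "GAP")
  bad <- tibble::tibble(label = c("A", "B"), i = c(1L, 5L), j = c(13L, 20L),
                        side = 1L, rest_flag = FALSE)
  expect_error(build_part_circle(cc, bad), "overlap")
})

# independent exhaustive oracle over all rotations and reflected rotations
oracle_order <- function(a, b) {
  if (length(a) != length(b)) return("shuffled")
  rots <- function(v) lapply(seq_along(v), function(k) {
    v[((seq_along(v) + k - 2) %% length(v)) + 1]
  })
  if (any(vapply(rots(a), identical, TRUE, y = b))) return("identical")
  if (any(vapply(rots(rev(a)), identical, TRUE, y = b))) return("reversed")
  "shuffled"
}

test_that("part-order comparison handles rotations, reversals, shuffles", {
  pc <- function(...) part_circle(c(...))
  expect_equal(compare_part_order(pc("A", "B", "C"), pc("B", "C", "A"))$relation,
               "identical")
  expect_equal(compare_part_order(pc("A", "B", "C"), pc("C", "B", "A"))$relation,
               "reversed")
  expect_equal(compare_part_order(pc("A", "B", "C", "D"), pc("A", "C", "B", "D"))$relation,
               "shuffled")
  two <- compare_part_order(pc("A", "B"), pc("B", "A"))
  expect_equal(two$relation, "undefined")
  expect_equal(two$reason, "too_few")
  none <- compare_part_order(pc("A", "B", "C"), pc("X", "Y", "Z"))
  expect_equal(none$reason, "no_shared")
  # gaps and non-shared labels are ignored before comparison
  expect_equal(compare_part_order(pc("A", "GAP", "B", "X", "C"),
                                  pc("B", "GAP", "C", "A"))$relation,
               "identical")
})

test_that("part-order comparison agrees with the exhaustive oracle", {
  set.seed(23)
  labs <- LETTERS[1:5]
  for (k in 1:60) {
    a <- sample(labs)
    b <- sample(labs)
    got <- compare_part_order(part_circle(a), part_circle(b))$relation
    expect_equal(got, oracle_order(a, b), info = paste(c(a, "|", b), collapse = ""))
  }
  # symmetry of the relation and the reversal mapping
  for (k in 1:20) {
    a <- sample(labs)
    b <- sample(labs)
    r1 <- compare_part_order(part_circle(a), part_circle(b))$relation
    r2 <- compare_part_order(part_circle(b), part_circle(a))$relation
    expect_equal(r1, r2)
    expect_equal(compare_part_order(part_circle(a), part_circle(rev(a)))$relation,
                 "reversed")
  }
})

test_that("gap changes follow the four-state interval truth table", {
  pc <- function(...) part_circle(c(...))
  om <- classify_gap_changes(pc("A", "GAP", "B", "C"), pc("A", "B", "C"))
  expect_equal(om$kind, "omission")
  expect_equal(om$after_label, "A"); expect_equal(om$before_label, "B")
  ad <- classify_gap_changes(pc("A", "B"), pc("A", "GAP", "B"))
  expect_equal(ad$kind, "addition")
  sb <- classify_gap_changes(pc("A", "GAP", "B"), pc("A", "GAP", "B"))
  expect_equal(sb$kind, "substitution")
  expect_equal(nrow(classify_gap_changes(pc("A", "B", "C"), pc("A", "B", "C"))), 0L)
  expect_error(classify_gap_changes(pc("A"), pc("B")), "share")
  # exhaustive truth table over one interval (A .. B) x both circles
  states <- list(none = c("A", "B", "Z"), gap = c("A", "GAP", "B", "Z"))
  truth <- rbind(c(NA, "addition"), c("omission", "substitution"))
  for (ei in 1:2) {
    for (vi in 1:2) {
      got <- classify_gap_changes(pc(states[[ei]]), pc(states[[vi]]))
      got_ab <- got$kind[got$after_label == "A"]
      want <- truth[ei, vi]
      if (is.na(want)) expect_equal(length(got_ab), 0L)
      else expect_equal(got_ab, want)
    }
  }
  # non-shared labels count as gaps ("Z" interval unaffected above)
  sub2 <- classify_gap_changes(pc("A", "P", "B"), pc("A", "Q", "B"))
  expect_equal(sub2$kind[sub2$after_label == "A"], "substitution")
})

test_that("noiseless simulated picks recover the generator's order classes", {
  coh <- tiny_cohort(seed = 71)
  trials <- enumerate_correspondence_trials(coh, n_within = 4, n_cross = 0,
                                            seed = 1)
  picks <- simulate_correspondence(coh, trials, n_raters = 1, bundling = 0,
                                   cross_pick_rate = 0, rest_pick_rate = 0,
                                   seed = 2)
  for (t in unique(picks$trial)) {
    pt <- picks[picks$trial == t, ]
    eid <- trials$exemplar_id[t]; sid <- trials$shape_id[t]
    er <- pt[pt$shape_role == "exemplar", ]
    vr <- pt[pt$shape_role == "variation", ]
    ec <- build_part_circle(shapecat:::cohort_shape(coh, eid),
                            data.frame(label = er$label, i = er$i, j = er$j,
                                       side = er$side, rest_flag = er$rest_flag))
    vc <- build_part_circle(shapecat:::cohort_shape(coh, sid),
                            data.frame(label = vr$label, i = vr$i, j = vr$j,
                                       side = vr$side, rest_flag = vr$rest_flag))
    rel <- compare_part_order(ec, vc)
    if (rel$relation == "undefined") next
    # ground truth from the recorded permutation
    k <- match(sid, coh$variations$shape_id)
    truthc <- compare_part_order(
      ground_truth_circle(shapecat:::cohort_shape(coh, eid),
                          shapecat:::cohort_parts(coh, eid)),
      ground_truth_circle(coh$variations$contour[[k]],
                          coh$variations$parts[[k]]))
    if (truthc$relation != "undefined") {
      expect_equal(rel$relation, truthc$relation)
    }
  }
})
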