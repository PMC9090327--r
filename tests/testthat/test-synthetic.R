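test_that("exemplars respect their part-count and curvature contracts", {
  ex5 <- generate_exemplar(5, "curved", seed = 3)
  expect_equal(nrow(ex5$spec$parts), 5L)
  # spans disjoint
  idx <- unlist(lapply(seq_len(5), function(q) {
    segment_indices(contour_segment(ex5$spec$parts$span_start[q],
                                    ex5$spec$parts$span_length[q], 360L))
  }))
  expect_equal(anyDuplicated(idx), 0L)
  expect_false(self_intersects(ex5$contour))

  expect_gte(straight_fraction(generate_exemplar(2, "polygonal", seed = 4)$contour), 0.9)
  expect_lte(straight_fraction(generate_exemplar(2, "curved", seed = 4)$contour), 0.1)

  ex0 <- generate_exemplar(0, "polygonal", seed = 5)
  expect_null(ex0$spec$parts)
  expect_gte(straight_fraction(ex0$contour), 0.9)
  expect_error(generate_exemplar(6, "curved"), "between 0 and 5")
})

test_that("same seed reproduces shapes bit for bit", {
  a <- generate_exemplar(3, "curved", seed = 11)
  b <- generate_exemplar(3, "curved", seed = 11)
  expect_identical(a$contour$points, b$contour$points)
  ca <- generate_cohort(2, 2, 2, seed = 21)
  cb <- generate_cohort(2, 2, 2, seed = 21)
  expect_identical(ca$variations$contour[[5]]$points,
                   cb$variations$contour[[5]]$points)
  expect_identical(ca$variations$magnitude, cb$variations$magnitude)
})

test_that("a null variation spec reproduces the exemplar exactly", {
  ex <- generate_exemplar(3, "curved", seed = 42)
  v <- generate_variation(ex, variation_spec(strategies = character(),
                                             magnitude = 0, seed = 9))
  expect_equal(v$contour$points, ex$contour$points)
  expect_lt(v$magnitude, 1e-9)
})

test_that("variation strategies record faithful ground truth", {
  ex <- generate_exemplar(4, "curved", seed = 13, p_negative = 0)
  labs <- ex$spec$parts$label[order(ex$spec$parts$theta0)]

  # omission bookkeeping
  vo <- generate_variation(ex, variation_spec(strategies = "omit",
                                              omit = labs[2], seed = 2))
  expect_false(labs[2] %in% vo$parts$label)
  expect_equal(sort(vo$parts$label), sort(setdiff(labs, labs[2])))

  # reversal is recovered downstream from ground-truth circles
  vr <- generate_variation(ex, variation_spec(
    strategies = "shuffle", magnitude = 0, permutation = rev(labs), seed = 3))
  rel <- compare_part_order(ground_truth_circle(ex$contour, ex$spec$parts),
                            ground_truth_circle(vr$contour, vr$parts))
  expect_equal(rel$relation, "reversed")

  # addition adds exactly one new label
  va <- generate_variation(ex, variation_spec(strategies = "add", add = 1L,
                                              magnitude = 0, seed = 4))
  expect_equal(sum(startsWith(va$parts$label, "A")), 1L)

  # substitution renames the slot's occupant
  vs <- generate_variation(ex, variation_spec(strategies = "substitute",
                                              substitute = labs[1],
                                              magnitude = 0, seed = 5))
  expect_false(labs[1] %in% vs$parts$label)
  expect_true(paste0("S", labs[1]) %in% vs$parts$label)
})

test_that("cohort counts and creativity structure hold", {
  coh <- generate_cohort(n_drawers = 4, n_variations = 3, n_exemplars = 2,
                         seed = 31)
  expect_equal(nrow(coh$variations), 24L)
  expect_equal(as.vector(table(coh$variations$category)), c(12L, 12L))
  one <- generate_cohort(1, 1, 1, seed = 1)
  expect_equal(nrow(one$variations), 1L)
  # drawer warp ladder induces an increasing creativity ordering
  coh2 <- generate_cohort(n_drawers = 6, n_variations = 8, n_exemplars = 2,
                          seed = 32)
  m <- tapply(coh2$variations$magnitude, coh2$variations$drawer, mean)
  expect_gt(cor(seq_along(m), m, method = "spearman"), 0.7)
})

test_that("warp-only variations preserve the curvature class", {
  coh <- generate_cohort(n_drawers = 3, n_variations = 4, n_exemplars = 4,
                         seed = 33)
  v <- coh$variations
  for (k in seq_len(nrow(v))) {
    dsf <- abs(straight_fraction(v$contour[[k]]) -
                 straight_fraction(coh$exemplars[[v$category[k]]]$contour))
    expect_lte(dsf, 0.15)
  }
})

test_that("noiseless similarity placements reproduce magnitude ranks", {
  coh <- tiny_cohort(seed = 41)
  pl <- simulate_similarity_ratings(coh, n_raters = 3, noise = 0, seed = 2)
  for (r in 1:3) {
    for (e in 1:3) {
      sub <- pl[pl$rater == r & pl$category == e, ]
      truth <- coh$variations$magnitude[match(sub$shape, coh$variations$shape_id)]
      expect_equal(order(abs(sub$x - sub$x_exemplar)), order(truth))
    }
  }
  # noise -> 0 limit: aggregated scores converge to the truth ranking
  rho <- vapply(c(0.3, 0.02), function(ns) {
    p <- simulate_similarity_ratings(coh, n_raters = 8, noise = ns, seed = 3)
    sc <- aggregate_similarity(p)
    truth <- coh$variations$magnitude[match(sc$shape, coh$variations$shape_id)]
    cor(sc$s, truth, method = "spearman")
  }, 0)
  expect_gt(rho[2], 0.95)
  expect_gte(rho[2], rho[1])
  # determinism
  p1 <- simulate_similarity_ratings(coh, n_raters = 2, seed = 5)
  p2 <- simulate_similarity_ratings(coh, n_raters = 2, seed = 5)
  expect_identical(p1, p2)
})

test_that("zero confusability yields a diagonal confusion matrix", {
  coh <- tiny_cohort(seed = 43)
  ch <- simulate_classification(coh$variations, n_raters = 3,
                                confusability = 0, n_categories = 3, seed = 1)
  expect_true(all(ch$response == ch$true))
  ca <- confusion_analysis(ch[, c("true", "response")], categories = 1:3)
  expect_equal(sum(ca$counts) - sum(diag(ca$counts)), 0L)
})

test_that("paintings always carry tier 1 and concentrate on salient spans", {
  coh <- tiny_cohort(seed = 45)
  pp <- simulate_paintings(coh, n_raters = 6, seed = 2)
  for (sid in names(pp)) {
    M <- pp[[sid]]
    expect_true(all(apply(M, 1, function(z) any(z == 1L))))
    expect_true(all(M %in% 0:3))
  }
  # zero jitter, single tier: the aggregated field hits 100 exactly on the
  # most salient ground-truth span
  pp0 <- simulate_paintings(coh, shape_ids = "E1", n_raters = 5, jitter = 0,
                            tier_p = c(0, 0), seed = 3)
  f <- aggregate_paintings(pp0[["E1"]])
  parts <- coh$exemplars[["E1"]]$spec$parts
  top <- parts[which.max(parts$weight), ]
  span <- segment_indices(contour_segment(top$span_start, top$span_length, 360L))
  expect_true(all(f$D[span] == 100))
  expect_true(all(f$D[-span] == 0))
})

test_that("simulated correspondences recover ground truth when noiseless", {
  coh <- tiny_cohort(seed = 47)
  trials <- enumerate_correspondence_trials(coh, n_within = 3, n_cross = 3,
                                            seed = 1)
  expect_equal(nrow(trials), 3 * 6)
  picks <- simulate_correspondence(coh, trials, n_raters = 2, bundling = 0,
                                   cross_pick_rate = 0, rest_pick_rate = 0,
                                   seed = 2)
  expect_true(all(picks$trial %in% trials$trial[trials$same_category]))
  # every pick chord is admissible on its shape
  for (k in seq_len(min(nrow(picks), 40))) {
    cc <- shapecat:::cohort_shape(coh, picks$shape_id[k])
    expect_true(chord_is_valid(cc, picks$i[k], picks$j[k]))
  }
})
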