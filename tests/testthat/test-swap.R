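test_that("distinctive-part extraction follows length and tie rules", {
  D <- rep(0, 100)
  D[10:39] <- 90     # run of 30
  D[60:71] <- 95     # run of 12
  seg <- extract_distinctive_part(D)
  expect_equal(seg$start, 10L); expect_equal(seg$length, 30L)
  # single qualifying point
  D2 <- rep(0, 50); D2[7] <- 80
  expect_equal(extract_distinctive_part(D2)$length, 1L)
  expect_error(extract_distinctive_part(rep(50, 20)), "ineligible")
  # tie on length: higher mean wins, then lower start
  D3 <- rep(0, 100); D3[10:19] <- 80; D3[50:59] <- c(rep(99, 9), 80)
  expect_equal(extract_distinctive_part(D3)$start, 50L)
  D4 <- rep(0, 100); D4[10:19] <- 80; D4[50:59] <- 80
  expect_equal(extract_distinctive_part(D4)$start, 10L)
})

test_that("extraction matches a brute-force run enumeration on random fields", {
  set.seed(13)
  for (k in 1:25) {
    D <- sample(c(0, 50, 80, 90, 100), 80, replace = TRUE)
    if (!any(D > 75)) next
    seg <- extract_distinctive_part(D)
    # oracle: enumerate runs directly
    mask <- D > 75
    runs <- list()
    visited <- rep(FALSE, 80)
    for (s in which(mask)) {
      if (visited[s]) next
      prev <- ((s - 2) %% 80) + 1
      if (mask[prev]) next
      len <- 0
      while (mask[((s - 1 + len) %% 80) + 1]) {
        visited[((s - 1 + len) %% 80) + 1] <- TRUE
        len <- len + 1
      }
      runs[[length(runs) + 1]] <- c(s, len)
    }
    if (all(mask)) runs <- list(c(1, 80))
    lens <- vapply(runs, `[`, 0, 2)
    best <- runs[lens == max(lens)]
    means <- vapply(best, function(r) {
      mean(D[((r[1] - 1 + seq_len(r[2]) - 1) %% 80) + 1])
    }, 0)
    best <- best[means == max(means)]
    starts <- vapply(best, `[`, 0, 1)
    want <- best[[which.min(starts)]]
    expect_equal(c(seg$start, seg$length), c(want[1], want[2]),
                 info = paste("case", k))
  }
})

test_that("indistinctive window selection scans all feasible windows", {
  D <- rep(50, 100); D[30:60] <- 0
  excl <- contour_segment(1, 10, 100)
  seg <- select_indistinctive_part(D, 20, exclude = excl)
  expect_true(all(segment_indices(seg) %in% 30:60))
  expect_equal(mean(D[segment_indices(seg)]), 0)
  # uniform field: lowest admissible start index
  segu <- select_indistinctive_part(rep(10, 100), 15, exclude = excl)
  expect_equal(segu$start, 11L)
  expect_error(select_indistinctive_part(rep(1, 30), 25,
                                         exclude = contour_segment(1, 10, 30)),
               "window")
  # oracle: exhaustive scan
  set.seed(21)
  D2 <- runif(60, 0, 100)
  seg2 <- select_indistinctive_part(D2, 8, exclude = contour_segment(5, 6, 60))
  blocked <- segment_indices(contour_segment(5, 6, 60))
  best <- Inf; beststart <- NA
  for (s in 1:60) {
    idx <- ((s - 1 + 0:7) %% 60) + 1
    if (any(idx %in% blocked)) next
    m <- mean(D2[idx])
    if (m < best - 1e-12) { best <- m; beststart <- s }
  }
  expect_equal(seg2$start, beststart)
})

test_that("transplant maps donor endpoints exactly onto the gap", {
  base <- resample_contour(circle_contour(1000, 10), 360)
  donor <- generate_exemplar(3, "curved", seed = 31)$contour
  gap <- contour_segment(50, 40, 360)
  dpart <- contour_segment(100, 60, 360)
  res <- transplant_part(base, gap, donor, dpart)
  expect_equal(n_points(res$contour), 360L)
  # recipient points outside the gap preserved exactly before resampling
  kept <- setdiff(1:360, segment_indices(gap))
  raw <- res$raw$points
  for (p in base$points[sample(kept, 20), 1]) {
    expect_true(any(abs(raw[, 1] - p) < 1e-12))
  }
  # endpoint mapping: anchors adjacent to the gap appear in the raw contour
  a1 <- base$points[49, ]; a2 <- base$points[90, ]
  expect_lt(min(sqrt(rowSums(sweep(raw, 2, a1)^2))), 1e-9)
  expect_lt(min(sqrt(rowSums(sweep(raw, 2, a2)^2))), 1e-9)
  # the similarity transform's scale equals the chord ratio
  q <- donor$points[segment_indices(dpart), ]
  dchord <- sqrt(sum((q[nrow(q), ] - q[1, ])^2))
  gchord <- sqrt(sum((a2 - a1)^2))
  expect_equal(res$transform$scale, gchord / dchord, tolerance = 1e-9)
  expect_gt(res$transform$scale, 0)
  # congruent donor: same-size circular arc gives scale 1
  res2 <- transplant_part(base, gap, base, contour_segment(200, 42, 360))
  expect_equal(res2$transform$scale, 1, tolerance = 1e-9)
  expect_error(transplant_part(base, gap, donor, contour_segment(5, 1, 360)),
               "zero-length")
})

test_that("screening passes clean shapes and fails crossings", {
  expect_true(screen_stimulus(resample_contour(circle_contour(100), 100))$pass)
  expect_true(screen_stimulus(generate_exemplar(4, "curved", seed = 33)$contour)$pass)
  bad <- screen_stimulus(bowtie_contour())
  expect_false(bad$pass)
  expect_equal(bad$reason, "self_intersection")
  # near-touching points fail the clearance rule
  th <- 2 * pi * (0:99) / 100
  pinch <- cbind(cos(th), sin(th))
  pinch[50, ] <- pinch[2, ] + 1e-9
  pinched <- closed_contour(pinch, normalize = FALSE)
  if (!self_intersects(pinched)) {
    expect_false(screen_stimulus(pinched)$pass)
  }
})

test_that("swap design fills its cells deterministically", {
  coh <- tiny_cohort(seed = 91)
  pp <- simulate_paintings(coh, shape_ids = c(names(coh$exemplars),
                                              coh$variations$shape_id[1:6]),
                           n_raters = 10, seed = 1)
  fields <- lapply(names(pp), function(s) aggregate_paintings(pp[[s]], s))
  names(fields) <- names(pp)
  bases <- tibble::tibble(
    shape_id = coh$variations$shape_id[1:6],
    category = coh$variations$category[1:6])
  des <- build_swap_design(coh, fields, bases[bases$category == 1, ],
                           donors_per_category = 1L,
                           conditions = "distinctive", bases_per_cell = 1L,
                           seed = 5)
  expect_equal(nrow(des), 1L)
  expect_equal(des$condition, "distinctive")
  expect_false(des$donor_category == des$category)
  des2 <- build_swap_design(coh, fields, bases[bases$category == 1, ],
                            donors_per_category = 1L,
                            conditions = "distinctive", bases_per_cell = 1L,
                            seed = 5)
  expect_identical(des$contour[[1]]$points, des2$contour[[1]]$points)
  # both conditions, 2 donors -> 2 x 2 stimuli per base category
  des3 <- build_swap_design(coh, fields, bases[bases$category == 1, ],
                            donors_per_category = 2L, bases_per_cell = 1L,
                            seed = 6)
  expect_equal(nrow(des3), 4L)
  # swapped-in and removed windows have equal point counts in the
  # indistinctive condition by construction: check the transform is sane
  expect_true(all(des3$scale > 0))
})

test_that("swap classification shows the expected accuracy ordering", {
  stim <- tibble::tibble(
    stimulus_id = sprintf("s%d", 1:300),
    category = rep(1:4, length.out = 300),
    donor_category = rep(c(2:4, 1), length.out = 300),
    condition = rep(c("none", "indistinctive", "distinctive"), each = 100))
  resp <- simulate_swap_classification(stim, n_raters = 10, n_categories = 4,
                                       seed = 3)
  acc <- vapply(split(resp, resp$condition),
                function(d) mean(d$response == d$true), 0)
  expect_gt(acc[["none"]], acc[["indistinctive"]])
  expect_gt(acc[["indistinctive"]], acc[["distinctive"]])
})
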