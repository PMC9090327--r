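#' Run configuration
#'
#' Bundles the pipeline's tunable parameters. Defaults follow the study's
#' printed design: 360-point resampling, 20 similarity bins (40 for the
#' classification experiment), a strict distinctiveness threshold of 75,
#' and the full 17 x 12 x 8 drawing cohort.
#'
#' @param seed master seed; every stage derives its own child seed from it.
#' @param resample_n standard contour point count.
#' @param bins similarity bins for subset selection.
#' @param classification_bins bins for the classification experiment.
#' @param distinctiveness_threshold strict high-score threshold.
#' @param null_reps simulated null raters per shape.
#' @param n_drawers,n_variations,n_exemplars cohort design counts.
#' @param n_raters raters per rating-type experiment.
#' @param confusability classification lapse rate.
#' @param placement_noise similarity-placement noise SD.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, resample_n = 360L, bins = 20L,
                       classification_bins = 40L,
                       distinctiveness_threshold = 75, null_reps = 10L,
                       n_drawers = 17L, n_variations = 12L, n_exemplars = 8L,
                       n_raters = 15L, confusability = 0.1,
                       placement_noise = 0.05) {
  structure(as.list(environment()), class = "run_config")
}

# deterministic child-seed scheme: one master seed fans out per stage index
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 16807) %% 2147483562) + 1L
}

#' Simulate the copy-versus-variation two-alternative judgements
#'
#' Emulates the 2-AFC control: on each judgement the probability of
#' correctly identifying the copy grows with the variation's ground-truth
#' deviation magnitude (logistic in the magnitude gap between variation and
#' a near-exact copy), floored at chance.
#'
#' @param cohort a `shape_cohort`.
#' @param n_raters raters (default 15).
#' @param repeats repeats of the full block design (default 3).
#' @param copy_magnitude deviation magnitude of a faithful copy.
#' @param slope logistic slope of discriminability in magnitude units.
#' @param seed integer seed.
#' @return tibble `(rater, shape, repeat, correct)`.
#' @export
simulate_copy_judgements <- function(cohort, n_raters = 15L, repeats = 3L,
                                     copy_magnitude = 0.05, slope = 0.08,
                                     seed = 1L) {
  set.seed(seed)
  v <- cohort$variations
  p_correct <- 0.5 + 0.5 * stats::plogis((v$magnitude - copy_magnitude) / slope)
  out <- vector("list", n_raters * repeats)
  k <- 0L
  for (r in seq_len(n_raters)) {
    for (rep_i in seq_len(repeats)) {
      k <- k + 1L
      out[[k]] <- tibble::tibble(rater = r, shape = v$shape_id,
                                 rep = rep_i,
                                 correct = stats::runif(nrow(v)) < p_correct)
    }
  }
  do.call(rbind, out)
}

#' Write a synthetic dataset to a directory
#'
#' Layout: `contours/*.json` (one per shape, 0-based stroke metadata run
#' indices), `placements.csv`, `choices.csv`, `picks.csv` (0-based chord
#' indices on disk), `paintings.csv` (long format, 0-based point index),
#' and `manifest.json` with the seeds and parameters.
#'
#' @param cohort a `shape_cohort`.
#' @param dir output directory (created).
#' @param placements,choices,picks,paintings optional response tables.
#' @param manifest optional extra manifest entries.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(cohort, dir, placements = NULL, choices = NULL,
                          picks = NULL, paintings = NULL, manifest = list()) {
  dir.create(file.path(dir, "contours"), recursive = TRUE, showWarnings = FALSE)
  for (eid in names(cohort$exemplars)) {
    write_contour_json(cohort$exemplars[[eid]]$contour,
                       file.path(dir, "contours", paste0(eid, ".json")))
  }
  for (k in seq_len(nrow(cohort$variations))) {
    cc <- cohort$variations$contour[[k]]
    write_contour_json(cc, file.path(dir, "contours",
                                     paste0(cohort$variations$shape_id[k], ".json")))
  }
  wcsv <- function(x, f) utils::write.csv(x, file.path(dir, f), row.names = FALSE)
  if (!is.null(placements)) wcsv(placements, "placements.csv")
  if (!is.null(choices)) wcsv(choices, "choices.csv")
  if (!is.null(picks)) {
    pk <- picks
    pk$i <- pk$i - 1L; pk$j <- pk$j - 1L
    wcsv(pk, "picks.csv")
  }
  if (!is.null(paintings)) {
    long <- do.call(rbind, lapply(names(paintings), function(sid) {
      M <- paintings[[sid]]
      idx <- which(M != 0L, arr.ind = TRUE)
      tibble::tibble(rater = idx[, 1L], shape = sid,
                     point_index = idx[, 2L] - 1L, tier = M[idx])
    }))
    wcsv(long, "paintings.csv")
  }
  manifest <- c(list(n_exemplars = cohort$params$n_exemplars,
                     n_drawers = cohort$params$n_drawers,
                     n_variations = cohort$params$n_variations,
                     seed = cohort$params$seed), manifest)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset directory
#'
#' @param dir a directory written by [write_dataset()].
#' @return list with `contours` (named list), the response tables present
#'   (`placements`, `choices`, `picks`, `paintings`), and `manifest`.
#'   Chord and point indices are converted back to 1-based.
#' @export
read_dataset <- function(dir) {
  files <- list.files(file.path(dir, "contours"), pattern = "\\.json$",
                      full.names = TRUE)
  contours <- lapply(files, read_contour_json)
  names(contours) <- sub("\\.json$", "", basename(files))
  rcsv <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) tibble::as_tibble(utils::read.csv(p)) else NULL
  }
  picks <- rcsv("picks.csv")
  if (!is.null(picks)) { picks$i <- picks$i + 1L; picks$j <- picks$j + 1L }
  paintings <- NULL
  pl <- rcsv("paintings.csv")
  if (!is.null(pl)) {
    paintings <- lapply(split(pl, pl$shape), function(d) {
      sid <- d$shape[1L]
      npts <- if (sid %in% names(contours)) {
        n_points(contours[[sid]])
      } else max(d$point_index) + 1L
      M <- matrix(0L, max(d$rater), npts)
      M[cbind(d$rater, d$point_index + 1L)] <- as.integer(d$tier)
      M
    })
  }
  manifest <- NULL
  mf <- file.path(dir, "manifest.json")
  if (file.exists(mf)) manifest <- jsonlite::fromJSON(mf)
  list(contours = contours, placements = rcsv("placements.csv"),
       choices = rcsv("choices.csv"), picks = picks, paintings = paintings,
       manifest = manifest)
}

#' Validate a dataset
#'
#' Checks contour well-formedness (>= 3 points, finite coordinates, no
#' self-intersection), referential integrity of response tables against the
#' contour set, and the tier-1 requirement on paintings. Findings are
#' reported, not raised.
#'
#' @param dataset a directory path or the list returned by [read_dataset()].
#' @return tibble `(severity, where, message)`; zero rows means a clean
#'   dataset.
#' @export
validate_dataset <- function(dataset) {
  if (is.character(dataset)) dataset <- read_dataset(dataset)
  findings <- list()
  add <- function(sev, where, msg) {
    findings[[length(findings) + 1L]] <<- tibble::tibble(
      severity = sev, where = where, message = msg)
  }
  ids <- names(dataset$contours)
  for (sid in ids) {
    cc <- dataset$contours[[sid]]
    if (n_points(cc) < 3L) add("error", sid, "fewer than 3 points")
    if (!all(is.finite(cc$points))) add("error", sid, "non-finite coordinates")
    if (self_intersects(cc)) add("error", sid, "self-intersecting contour")
  }
  check_ref <- function(tab, col, table_name) {
    if (is.null(tab)) return()
    bad <- setdiff(unique(tab[[col]]), ids)
    if (length(bad)) {
      add("error", table_name,
          paste("unknown shape ids:", paste(utils::head(bad, 5), collapse = ", ")))
    }
  }
  check_ref(dataset$placements, "shape", "placements.csv")
  check_ref(dataset$choices, "shape_id", "choices.csv")
  check_ref(dataset$picks, "shape_id", "picks.csv")
  if (!is.null(dataset$paintings)) {
    for (sid in names(dataset$paintings)) {
      M <- dataset$paintings[[sid]]
      for (r in seq_len(nrow(M))) {
        if (sum(M[r, ] != 0L) && !any(M[r, ] == 1L)) {
          add("error", paste0("paintings:", sid),
              sprintf("rater %d painted without any tier-1 area", r))
        }
      }
    }
  }
  if (!length(findings)) {
    return(tibble::tibble(severity = character(), where = character(),
                          message = character()))
  }
  do.call(rbind, findings)
}

#' Run one experiment of the analysis chain on synthetic data
#'
#' Generates (or reuses) a synthetic cohort under the config's master seed
#' and runs the named experiment's full analysis, returning a report list.
#' All randomness derives from the config seed through a fixed child-seed
#' scheme, so identical configs give identical reports.
#'
#' @param name one of `"exp2"` (similarity space), `"exp2b"` (copy 2-AFC),
#'   `"exp3"` (classification), `"exp4"` (correspondence), `"exp5"`
#'   (distinctiveness), `"exp6"` (part swaps).
#' @param config a [run_config()].
#' @param cohort optionally a pre-generated `shape_cohort` (to share one
#'   cohort across experiments).
#' @return a report list; contents depend on the experiment.
#' @export
run_experiment <- function(name = c("exp2", "exp2b", "exp3", "exp4", "exp5",
                                    "exp6"),
                           config = run_config(), cohort = NULL) {
  name <- match.arg(name)
  if (is.null(cohort)) {
    cohort <- generate_cohort(config$n_drawers, config$n_variations,
                              config$n_exemplars, seed = child_seed(config$seed, 1L))
  }
  switch(name,
    exp2 = run_exp2(cohort, config),
    exp2b = run_exp2b(cohort, config),
    exp3 = run_exp3(cohort, config),
    exp4 = run_exp4(cohort, config),
    exp5 = run_exp5(cohort, config),
    exp6 = run_exp6(cohort, config))
}

similarity_scores <- function(cohort, config) {
  pl <- simulate_similarity_ratings(cohort, n_raters = 12L,
                                    noise = config$placement_noise,
                                    seed = child_seed(config$seed, 2L))
  aggregate_similarity(pl)
}

run_exp2 <- function(cohort, config) {
  scores <- similarity_scores(cohort, config)
  subsets <- lapply(seq_len(config$n_exemplars), function(e) {
    select_spanning_subset(scores[scores$category == e, ], config$bins)
  })
  list(scores = scores,
       creativity = creativity_index(cohort, scores),
       order_trend = order_trend(cohort, scores),
       spanning_subsets = subsets)
}

run_exp2b <- function(cohort, config) {
  jj <- simulate_copy_judgements(cohort, n_raters = config$n_raters,
                                 seed = child_seed(config$seed, 3L))
  K <- sum(jj$correct); N <- nrow(jj)
  list(judgements = jj,
       test = binomial_test_one_sided(K, N, 0.5),
       percent_correct = 100 * K / N)
}

run_exp3 <- function(cohort, config) {
  scores <- similarity_scores(cohort, config)
  chosen <- unlist(lapply(seq_len(config$n_exemplars), function(e) {
    select_spanning_subset(scores[scores$category == e, ],
                           config$classification_bins)
  }))
  v <- cohort$variations
  shapes <- v[v$shape_id %in% chosen, c("shape_id", "category")]
  choices <- simulate_classification(shapes, n_raters = config$n_raters,
                                     confusability = config$confusability,
                                     n_categories = config$n_exemplars,
                                     seed = child_seed(config$seed, 4L))
  conf <- confusion_analysis(choices, categories = seq_len(config$n_exemplars),
                             cell_alpha = bonferroni_alpha(0.05, config$n_exemplars))
  # global curvature statistic: straightness of each exemplar vs the mean
  # straightness of its variations
  sf_e <- vapply(cohort$exemplars, function(e) straight_fraction(e$contour), 0)
  sf_v <- vapply(seq_len(config$n_exemplars), function(e) {
    mean(vapply(v$contour[v$category == e], straight_fraction, 0))
  }, 0)
  curv <- if (stats::sd(sf_e) > 0 && stats::sd(sf_v) > 0) {
    pearson_r(sf_e, sf_v)
  } else list(r = NA_real_, p_value = NA_real_)
  list(choices = choices, confusion = conf,
       curvature = list(exemplar_straightness = sf_e,
                        variation_straightness = sf_v, r = curv$r,
                        p_value = curv$p_value))
}

run_exp4 <- function(cohort, config) {
  trials <- enumerate_correspondence_trials(cohort,
                                            seed = child_seed(config$seed, 5L))
  picks <- simulate_correspondence(cohort, trials, n_raters = config$n_raters,
                                   bundling = 0.1,
                                   seed = child_seed(config$seed, 6L))
  n_raters <- config$n_raters
  # area fractions, within- vs cross-category
  frac <- list()
  for (same in c(TRUE, FALSE)) {
    vals <- c()
    for (e in seq_len(config$n_exemplars)) {
      eid <- paste0("E", e)
      tt <- trials$trial[trials$exemplar_id == eid & trials$same_category == same]
      pk <- picks[picks$trial %in% tt & picks$shape_role == "exemplar", ]
      af <- corresponding_area_fraction(cohort$exemplars[[eid]]$contour, pk,
                                        n_raters = n_raters, trials = tt)
      vals <- c(vals, af$per_trial$fraction)
    }
    frac[[if (same) "within" else "cross"]] <- vals
  }
  ttest <- t_test_one_sided(frac$within, frac$cross)
  # part order relations on pick-derived circles, per trial x rater
  relations <- c(); gap_kinds <- c()
  for (t in unique(picks$trial)) {
    pt <- picks[picks$trial == t, ]
    eid <- trials$exemplar_id[trials$trial == t]
    sid <- trials$shape_id[trials$trial == t]
    for (r in unique(pt$rater)) {
      pr <- pt[pt$rater == r, ]
      ec <- tryCatch(build_part_circle(
        cohort_shape(cohort, eid),
        data.frame(label = pr$label[pr$shape_role == "exemplar"],
                   i = pr$i[pr$shape_role == "exemplar"],
                   j = pr$j[pr$shape_role == "exemplar"],
                   side = pr$side[pr$shape_role == "exemplar"],
                   rest_flag = pr$rest_flag[pr$shape_role == "exemplar"])),
        error = function(e) NULL)
      vc <- tryCatch(build_part_circle(
        cohort_shape(cohort, sid),
        data.frame(label = pr$label[pr$shape_role == "variation"],
                   i = pr$i[pr$shape_role == "variation"],
                   j = pr$j[pr$shape_role == "variation"],
                   side = pr$side[pr$shape_role == "variation"],
                   rest_flag = pr$rest_flag[pr$shape_role == "variation"])),
        error = function(e) NULL)
      if (is.null(ec) || is.null(vc)) next
      rel <- compare_part_order(ec, vc)
      relations <- c(relations, rel$relation)
      if (rel$n_shared >= 1L) {
        gc <- classify_gap_changes(ec, vc)
        gap_kinds <- c(gap_kinds, gc$kind)
      }
    }
  }
  decided <- relations[relations != "undefined"]
  list(trials = trials, picks = picks,
       within_fraction = mean(frac$within), cross_fraction = mean(frac$cross),
       t_test = ttest,
       order_relations = table(factor(relations,
         levels = c("identical", "reversed", "shuffled", "undefined"))),
       order_proportions = if (length(decided)) {
         prop.table(table(factor(decided,
           levels = c("identical", "reversed", "shuffled"))))
       } else NULL,
       gap_changes = table(factor(gap_kinds,
         levels = c("omission", "addition", "substitution"))))
}

run_exp5 <- function(cohort, config, n_paint_shapes = 5L) {
  v <- cohort$variations
  paint_ids <- character()
  for (e in seq_len(config$n_exemplars)) {
    own <- v[v$category == e, ]
    own <- own[order(own$magnitude), ]
    take <- unique(round(seq(1L, nrow(own),
                             length.out = min(n_paint_shapes, nrow(own)))))
    paint_ids <- c(paint_ids, own$shape_id[take], paste0("E", e))
  }
  paintings <- simulate_paintings(cohort, paint_ids,
                                  n_raters = config$null_reps,
                                  seed = child_seed(config$seed, 7L))
  fields <- lapply(names(paintings), function(sid) {
    aggregate_paintings(paintings[[sid]], shape_id = sid)
  })
  names(fields) <- names(paintings)
  # category-wise null model and randomized paintings
  cat_of <- function(sid) {
    if (startsWith(sid, "E") & sid %in% names(cohort$exemplars)) {
      return(as.integer(sub("^E", "", sid)))
    }
    v$category[match(sid, v$shape_id)]
  }
  null_fields <- list()
  for (e in seq_len(config$n_exemplars)) {
    sids <- names(paintings)[vapply(names(paintings), cat_of, 0L) == e]
    if (!length(sids)) next
    nm <- fit_null_model(paintings[sids])
    np <- sample_null_paintings(nm, sids, n_raters = config$null_reps,
                                seed = child_seed(config$seed, 100L + e))
    null_fields <- c(null_fields, lapply(names(np), function(sid) {
      aggregate_paintings(np[[sid]], shape_id = paste0("null_", sid))
    }))
  }
  agree <- compare_agreement(fields, null_fields,
                             threshold = config$distinctiveness_threshold)
  list(paintings = paintings, fields = fields, null_fields = null_fields,
       agreement = agree,
       mean_human_fraction = mean(agree$human_fractions),
       mean_null_fraction = mean(agree$null_fractions))
}

run_exp6 <- function(cohort, config, bases_per_cell = 5L,
                     n_base_candidates = 10L) {
  exp5 <- run_exp5(cohort, config, n_paint_shapes = n_base_candidates)
  v <- cohort$variations
  base_ids <- setdiff(names(exp5$fields), names(cohort$exemplars))
  bases <- tibble::tibble(shape_id = base_ids,
                          category = v$category[match(base_ids, v$shape_id)])
  design <- build_swap_design(cohort, exp5$fields, bases,
                              donors_per_category = config$n_exemplars - 1L,
                              bases_per_cell = bases_per_cell,
                              threshold = config$distinctiveness_threshold,
                              seed = child_seed(config$seed, 8L))
  unswapped <- tibble::tibble(stimulus_id = bases$shape_id,
                              category = bases$category,
                              donor_category = NA_integer_,
                              condition = "none")
  all_stim <- rbind(design[, c("stimulus_id", "category", "donor_category",
                               "condition")], unswapped)
  responses <- simulate_swap_classification(
    all_stim, n_raters = config$n_raters, n_categories = config$n_exemplars,
    seed = child_seed(config$seed, 9L))
  acc <- vapply(split(responses, responses$condition),
                function(d) mean(d$response == d$true), 0)
  h_indist <- cohens_h(acc[["none"]], acc[["indistinctive"]])
  h_dist <- cohens_h(acc[["none"]], acc[["distinctive"]])
  list(design = design, responses = responses, accuracy = acc,
       cohens_h = c(indistinctive = h_indist, distinctive = h_dist),
       report = attr(design, "report"))
}
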