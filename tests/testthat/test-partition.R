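test_that("threshold calibration matches order-statistic oracles", {
  # degenerate reference: any percentile of a constant is that constant
  for (pr in c(0, 0.5, 0.95, 1))
    expect_equal(calibrate_threshold(rep(3.7, 9), "percentile",
                                     probability = pr)$threshold, 3.7)

  # independent sort-and-interpolate computation (type-7 convention)
  x <- sample(1:100)
  h <- 0.95 * (100 - 1) + 1
  oracle <- sort(x)[floor(h)] +
    (h - floor(h)) * (sort(x)[floor(h) + 1] - sort(x)[floor(h)])
  m <- calibrate_threshold(x, "percentile", probability = 0.95)
  expect_equal(m$threshold, oracle)
  expect_equal(m$n_reference, 100L)

  expect_equal(calibrate_threshold(c(3, 9, 4), "max")$threshold, 9)
  expect_error(calibrate_threshold(numeric(), "max"), "S-phase")
  expect_equal(calibrate_threshold(statistic = "fixed",
                                   value = 12)$threshold, 12)
})

test_that("annotation pairing is a verbatim passthrough with id checks", {
  me <- data.frame(object_id = 1:12, row = 1:12, col = 1:12,
                   border = FALSE)
  ann <- data.frame(pair_id = 1:6, mother_object_id = 1:6,
                    daughter_object_id = 7:12)
  pr <- pair_telophase(me, ann)
  expect_equal(pr$mother_object_id, 1:6)
  expect_equal(pr$daughter_object_id, 7:12)
  expect_true(all(pr$role_known))

  ann_bad <- data.frame(pair_id = 1, mother_object_id = 1,
                        daughter_object_id = 99)
  expect_error(pair_telophase(me, ann_bad), "99")
})

test_that("heuristic pairing recovers ground-truth pairs; singles drop out", {
  p <- quiet_params(n_cells = 12,
                    stage_mix = c(telophase = 1, s_phase = 0, g1 = 0))
  sc <- generate_scene(p, seed = 31)
  imgs <- render_channels(sc)
  mask <- segment_nuclei(imgs$marker)
  me <- measure_objects(mask, background_ring(mask),
                        list(marker = imgs$marker,
                             reporter = imgs$reporter))
  tt <- match_objects(me, truth_table(sc))
  pr <- pair_telophase(me)
  expect_equal(nrow(pr), 12L)
  truth_pairs <- split(tt$object_id, tt$cell_id)
  got_pairs <- lapply(seq_len(nrow(pr)),
                      function(i) sort(c(pr$mother_object_id[i],
                                         pr$daughter_object_id[i])))
  expect_setequal(vapply(got_pairs, paste, collapse = "-", ""),
                  vapply(truth_pairs,
                         function(v) paste(sort(v), collapse = "-"), ""))

  # a single isolated nucleus yields no pair and is logged as unpaired
  one <- data.frame(object_id = 1L, row = 50, col = 50, border = FALSE)
  pr1 <- pair_telophase(one)
  expect_equal(nrow(pr1), 0L)
  expect_equal(attr(pr1, "n_unpaired"), 1L)
})

test_that("presence calls use strict inequality and partition categories", {
  m <- calibrate_threshold(statistic = "fixed", value = 10)
  expect_equal(classify_pair(4, 50, m), "asymmetric_daughter")
  expect_equal(classify_pair(30, 50, m), "symmetric")
  expect_equal(classify_pair(50, 4, m), "asymmetric_mother")
  expect_equal(classify_pair(10, 10, m), "none")   # boundary stays negative
  expect_equal(classify_pair(NA, 50, m), "unknown")

  # raising the threshold moves calls monotonically away from presence
  set.seed(1)
  mo <- runif(200, 0, 30); da <- runif(200, 0, 30)
  rank_cat <- function(cat) c(none = 0, asymmetric_mother = 1,
                              asymmetric_daughter = 1, symmetric = 2)[cat]
  lo <- classify_pair(mo, da, calibrate_threshold(statistic = "fixed",
                                                  value = 5))
  hi <- classify_pair(mo, da, calibrate_threshold(statistic = "fixed",
                                                  value = 15))
  expect_true(all(rank_cat(hi) <= rank_cat(lo)))

  # tallies partition the classified pairs
  tal <- tally_categories(lo)
  expect_equal(sum(tal$n), 200L)
  expect_equal(sum(tal$fraction), 1)
})

test_that("asymmetry index endpoints, bounds, symmetry, scale invariance", {
  expect_equal(asymmetry_index(0, 5), 1)   # total asymmetry
  expect_equal(asymmetry_index(7, 7), 0)   # total symmetry
  expect_equal(asymmetry_index(1, 3), 0.5)
  expect_true(is.na(asymmetry_index(0, 0)))
  expect_equal(asymmetry_index(-2, 5), 1)  # negatives clamp to zero

  set.seed(99)
  m <- runif(1e4, 0, 100); d <- runif(1e4, 0, 100)
  ai <- asymmetry_index(m, d)
  expect_true(all(ai >= 0 & ai <= 1))
  expect_equal(ai, asymmetry_index(d, m))
  k <- runif(1e4, 0.1, 10)
  expect_equal(asymmetry_index(k * m, k * d), ai)
})

test_that("cumulative intensity sums clamped corrected values", {
  expect_equal(cumulative_intensity(2, 3), 5)
  expect_equal(cumulative_intensity(0, 0), 0)
  expect_equal(cumulative_intensity(-4, 3), 3)
})

test_that("symmetric pairs carry about twice the cumulative signal of
          asymmetric pairs built from the same amplitude", {
  p <- scene_params(n_cells = 40, amplitude_jitter = 0,
                    stage_mix = c(telophase = 1, s_phase = 0, g1 = 0),
                    category_mix = c(asymmetric_daughter = 0.5,
                                     asymmetric_mother = 0,
                                     symmetric = 0.5, none = 0))
  sc <- generate_scene(p, seed = 17)
  imgs <- render_channels(sc)
  mask <- segment_nuclei(imgs$marker)
  me <- measure_objects(mask, background_ring(mask),
                        list(marker = imgs$marker,
                             reporter = imgs$reporter))
  tt <- match_objects(me, truth_table(sc))
  telo <- tt[tt$stage == "telophase", ]
  wide <- merge(telo[telo$role == "mother", c("cell_id", "object_id",
                                              "category")],
                telo[telo$role == "daughter", c("cell_id", "object_id")],
                by = "cell_id", suffixes = c("_m", "_d"))
  pr <- pair_telophase(me, data.frame(pair_id = wide$cell_id,
                                      mother_object_id = wide$object_id_m,
                                      daughter_object_id = wide$object_id_d))
  pr <- classify_pairs(pr, me,
                       calibrate_threshold(statistic = "fixed", value = 20))
  cum <- split(pr$cumulative, wide$category)
  ratio <- median(cum$symmetric) / median(cum$asymmetric_daughter)
  expect_gt(ratio, 1.7)
  expect_lt(ratio, 2.3)
})

test_that("cytokinesis staging follows the bud-neck signal", {
  me <- data.frame(object_id = 1:2, row = c(50, 64), col = c(50, 50))
  pairs <- data.frame(pair_id = 1, mother_object_id = 1,
                      daughter_object_id = 2)
  spot_mid <- data.frame(row = 57, col = 50)
  spot_far <- data.frame(row = 100, col = 100)
  expect_equal(stage_cytokinesis(pairs, me, spot_mid), "before")
  expect_equal(stage_cytokinesis(pairs, me, spot_far), "after")
  expect_equal(stage_cytokinesis(pairs, me, spot_mid[0, , drop = FALSE]),
               "after")
  expect_equal(stage_cytokinesis(pairs, me, NULL), "unknown")

  # noise-free synthetic scene: staging matches ground truth
  p <- quiet_params(n_cells = 14, psf_sigma = 1.5,
                    stage_mix = c(telophase = 1, s_phase = 0, g1 = 0))
  sc <- generate_scene(p, seed = 23)
  imgs <- render_channels(sc)
  mask <- segment_nuclei(imgs$marker)
  me2 <- measure_objects(mask, background_ring(mask),
                         list(marker = imgs$marker,
                              reporter = imgs$reporter))
  tt <- match_objects(me2, truth_table(sc))
  telo <- tt[tt$stage == "telophase", ]
  wide <- merge(telo[telo$role == "mother",
                     c("cell_id", "object_id", "budneck")],
                telo[telo$role == "daughter", c("cell_id", "object_id")],
                by = "cell_id", suffixes = c("_m", "_d"))
  pr <- pair_telophase(me2, data.frame(pair_id = wide$cell_id,
                                       mother_object_id = wide$object_id_m,
                                       daughter_object_id = wide$object_id_d))
  bmask <- segment_budneck(imgs$budneck)
  bme <- measure_objects(bmask, background_ring(bmask),
                         list(budneck = imgs$budneck))
  stg <- stage_cytokinesis(pr, me2, bme)
  expect_equal(stg, ifelse(wide$budneck, "before", "after"))
})
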