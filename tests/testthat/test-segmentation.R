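test_that("degenerate inputs: constant image, wrong shape", {
  expect_equal(max(segment_nuclei(matrix(5, 64, 64))$labels), 0L)
  expect_error(segment_nuclei(array(1, c(4, 4, 2))), "2-D")
  expect_error(segment_nuclei(matrix(c(1, NA, 1, 1), 2)), "finite")
})

test_that("a single bright disc is recovered pixel-exactly", {
  img <- matrix(0, 64, 64)
  inside <- outer((0:63 - 30)^2, (0:63 - 25)^2, "+") <= 16
  img[inside] <- 100
  mask <- segment_nuclei(img)
  expect_equal(max(mask$labels), 1L)
  expect_identical(mask$labels > 0, inside)
  expect_length(mask$border_ids, 0)
})

test_that("reporter-channel segmentation sees only reporter-positive nuclei", {
  p <- quiet_params(n_cells = 8,
                    stage_mix = c(telophase = 1, s_phase = 0, g1 = 0),
                    category_mix = c(asymmetric_daughter = 1,
                                     asymmetric_mother = 0,
                                     symmetric = 0, none = 0))
  sc <- generate_scene(p, seed = 4)
  imgs <- render_channels(sc)
  m <- segment_reporter_nuclei(imgs$reporter)
  expect_equal(max(m$labels), 8L)      # daughter nuclei only
  expect_match(m$note, "not detected")
  tt <- truth_table(sc)
  rings <- background_ring(m)
  me <- measure_objects(m, rings, list(reporter = imgs$reporter))
  matched <- match_objects(me, tt)
  expect_true(all(!is.na(matched$object_id[matched$role == "daughter"])))
  expect_true(all(is.na(matched$object_id[matched$role == "mother"])))

  # all-none scene: nothing to segment
  p0 <- quiet_params(n_cells = 5,
                     stage_mix = c(telophase = 1, s_phase = 0, g1 = 0),
                     category_mix = c(asymmetric_daughter = 0,
                                      asymmetric_mother = 0,
                                      symmetric = 0, none = 1))
  img0 <- render_channels(generate_scene(p0, seed = 2))$reporter
  expect_equal(max(segment_reporter_nuclei(img0)$labels), 0L)

  # same algorithm, same input -> identical mask
  expect_identical(segment_reporter_nuclei(imgs$reporter)$labels,
                   segment_nuclei(imgs$reporter)$labels)
})

test_that("background ring matches analytic morphology", {
  # isolated single-pixel object: 9x9 minus 5x5 squares -> 56 pixels
  lab <- matrix(0L, 21, 21); lab[11, 11] <- 1L
  rs <- background_ring(as_label_mask(lab), 2, 4)
  expect_identical(rs$ring_area, 56L)
  expect_identical(sort(rs$rings[[1]]), sort(brute_ring(lab, 1, 2, 4)))

  # corner object: ring clipped to the image
  labc <- matrix(0L, 21, 21); labc[1, 1] <- 1L
  rc <- background_ring(as_label_mask(labc), 2, 4)
  expect_lt(rc$ring_area, 56L)
  expect_identical(sort(rc$rings[[1]]), sort(brute_ring(labc, 1, 2, 4)))

  # two nuclei 6 px apart: each ring excludes the other's inner dilation
  lab2 <- matrix(0L, 32, 32); lab2[10, 10] <- 1L; lab2[10, 16] <- 2L
  r2 <- background_ring(as_label_mask(lab2), 2, 4)
  for (k in 1:2)
    expect_identical(sort(r2$rings[[k]]), sort(brute_ring(lab2, k, 2, 4)))

  expect_error(background_ring(as_label_mask(lab), 4, 2), "inner_steps")
  expect_error(background_ring(as_label_mask(lab), 2, 2), "inner_steps")
})

test_that("rings match the brute-force oracle on random masks", {
  set.seed(42)
  for (i in 1:25) {
    m <- matrix(rbinom(32 * 32, 1, 0.04), 32, 32)
    lab <- matrix(as.integer(EBImage::bwlabel(m)), 32, 32)
    inner <- sample(0:2, 1); outer <- inner + sample(1:2, 1)
    rs <- background_ring(as_label_mask(lab), inner, outer)
    for (k in seq_len(max(lab))) {
      expect_identical(sort(rs$rings[[k]]),
                       sort(brute_ring(lab, k, inner, outer)))
      # object and ring pixel sets never intersect
      expect_length(intersect(rs$rings[[k]], which(lab == k)), 0)
    }
  }
})

test_that("measurement arithmetic: corrected = object mean - ring mean", {
  lab <- matrix(0L, 21, 21); lab[11, 11] <- 1L
  mask <- as_label_mask(lab)
  rings <- background_ring(mask)
  img <- matrix(40, 21, 21); img[11, 11] <- 100
  me <- measure_objects(mask, rings, list(reporter = img))
  expect_equal(me$mean_reporter, 100)
  expect_equal(me$ring_mean_reporter, 40)
  expect_equal(me$corrected_reporter, 60)
  expect_equal(me$corrected_reporter + me$ring_mean_reporter,
               me$mean_reporter)

  # uniform channel: signal equals background everywhere
  uni <- matrix(7, 21, 21)
  me2 <- measure_objects(mask, rings, list(x = uni))
  expect_equal(me2$corrected_x, 0)

  expect_error(measure_objects(mask, rings, list(x = matrix(0, 5, 5))),
               "shape")
})

test_that("corrected intensity recovers the amplitude over a gradient", {
  p <- scene_params(shape = c(256L, 256L), n_cells = 4,
                    psf_sigma = 0, shot_noise = FALSE, read_noise_sd = 0,
                    reporter_amplitude = 80, amplitude_jitter = 0,
                    stage_mix = c(telophase = 1, s_phase = 0, g1 = 0),
                    category_mix = c(asymmetric_daughter = 0,
                                     asymmetric_mother = 0,
                                     symmetric = 1, none = 0))
  sc <- generate_scene(p, seed = 6)
  imgs <- render_channels(sc)
  mask <- segment_nuclei(imgs$marker)
  me <- measure_objects(mask, background_ring(mask),
                        list(reporter = imgs$reporter))
  expect_true(all(abs(me$corrected_reporter - 80) / 80 < 0.02))
})

test_that("nucleus recovery on a default noisy scene is near-perfect", {
  p <- scene_params(n_cells = 20)
  sc <- generate_scene(p, seed = 7)
  imgs <- render_channels(sc)
  mask <- segment_nuclei(imgs$marker)
  me <- measure_objects(mask, background_ring(mask),
                        list(marker = imgs$marker))
  tt <- truth_table(sc)
  matched <- match_objects(me, tt, max_distance = 1)  # centroid error <= 1 px
  recall <- mean(!is.na(matched$object_id))
  precision <- length(unique(stats::na.omit(matched$object_id))) / nrow(me)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})

test_that("bud-neck segmentation finds spots and honors the area band", {
  expect_equal(max(segment_budneck(matrix(3, 64, 64))$labels), 0L)

  p <- scene_params(n_cells = 10, budneck_fraction = 1,
                    stage_mix = c(telophase = 1, s_phase = 0, g1 = 0))
  sc <- generate_scene(p, seed = 15)
  imgs <- render_channels(sc)
  bm <- segment_budneck(imgs$budneck)
  expect_equal(max(bm$labels), 10L)
  bme <- measure_objects(bm, background_ring(bm),
                         list(budneck = imgs$budneck))
  cl <- sc$cells
  d <- sqrt(outer(cl$budneck_row, bme$row, "-")^2 +
            outer(cl$budneck_col, bme$col, "-")^2)
  expect_true(all(apply(d, 1, min) <= 2))

  # an object larger than the area band (a nucleus bleeding through) is
  # rejected
  big <- matrix(0, 64, 64)
  big[20:30, 20:30] <- 100   # 121 px >> max_area = 40
  big[50, 50] <- 100
  bm2 <- segment_budneck(big, seg_config(method = "fixed", threshold = 50,
                                         min_area = 1, max_area = 40))
  expect_equal(max(bm2$labels), 1L)
})
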