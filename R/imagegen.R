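#' Parameters of a synthetic dividing-cell scene
#'
#' Bundles the geometry, photometry and noise settings used by
#' [generate_scene()] and [render_channels()]. Defaults emulate a field of
#' budding-yeast cells imaged at high magnification with 2x2-binned pixels:
#' nuclei of radius ~4 px, mother and daughter nuclei of a telophase pair
#' ~14 px apart, a smooth camera/medium background with a weak linear
#' gradient, Gaussian optical blur, and Poisson shot noise plus Gaussian
#' read noise. The default category mixture follows the tallies typical of
#' unperturbed cells (~72% of telophase pairs with reporter in the daughter
#' nucleus only, ~13% in both, the remainder in neither).
#'
#' @param shape image size in pixels, `c(rows, cols)`.
#' @param n_cells number of cells to place.
#' @param category_mix named proportions (summing to 1) over the four
#'   telophase categories `asymmetric_daughter`, `asymmetric_mother`,
#'   `symmetric`, `none`.
#' @param stage_mix named proportions over cell-cycle stages `telophase`,
#'   `s_phase`, `g1`. Non-telophase cells carry a single nucleus and no
#'   reporter; S-phase cells are the reference population used for
#'   threshold calibration.
#' @param nucleus_radius nucleus disc radius, pixels.
#' @param separation mother-to-daughter nucleus centre distance, pixels.
#' @param marker_amplitude,reporter_amplitude nuclear signal added above
#'   background in the marker (histone) and reporter channels, a.u.
#' @param amplitude_jitter relative half-width of the uniform cell-to-cell
#'   amplitude variation (0.2 means +/-20%).
#' @param background_level constant background, a.u.
#' @param background_gradient linear background slope per axis,
#'   a.u./pixel, `c(row, col)`.
#' @param psf_sigma Gaussian point-spread sigma, pixels; 0 disables blur.
#' @param shot_noise logical; apply Poisson noise to each pixel.
#' @param read_noise_sd Gaussian read-noise standard deviation, a.u.
#' @param budneck_fraction fraction of telophase cells still carrying a
#'   bud-neck (Myo1) spot, i.e. imaged before cytokinesis.
#' @param budneck_amplitude,budneck_radius photometry of the bud-neck spot.
#' @return A validated list of class `scene_params`.
#' @seealso [generate_scene()]
#' @export
scene_params <- function(shape = c(512L, 512L),
                         n_cells = 50L,
                         category_mix = c(asymmetric_daughter = 0.72,
                                          asymmetric_mother   = 0,
                                          symmetric           = 0.13,
                                          none                = 0.15),
                         stage_mix = c(telophase = 0.7,
                                       s_phase   = 0.2,
                                       g1        = 0.1),
                         nucleus_radius = 4,
                         separation = 14,
                         marker_amplitude = 300,
                         reporter_amplitude = 200,
                         amplitude_jitter = 0.2,
                         background_level = 100,
                         background_gradient = c(0.02, 0.02),
                         psf_sigma = 1.5,
                         shot_noise = TRUE,
                         read_noise_sd = 3,
                         budneck_fraction = 0.5,
                         budneck_amplitude = 400,
                         budneck_radius = 1.5) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 32L))
    stopf("shape must be two integers >= 32")
  if (n_cells < 0) stopf("n_cells must be >= 0")
  cats <- c("asymmetric_daughter", "asymmetric_mother", "symmetric", "none")
  if (!setequal(names(category_mix), cats))
    stopf("category_mix must be named over: %s", paste(cats, collapse = ", "))
  category_mix <- category_mix[cats]
  if (abs(sum(category_mix) - 1) > 1e-8 || any(category_mix < 0))
    stopf("category_mix proportions must be non-negative and sum to 1")
  stages <- c("telophase", "s_phase", "g1")
  if (!setequal(names(stage_mix), stages))
    stopf("stage_mix must be named over: %s", paste(stages, collapse = ", "))
  stage_mix <- stage_mix[stages]
  if (abs(sum(stage_mix) - 1) > 1e-8 || any(stage_mix < 0))
    stopf("stage_mix proportions must be non-negative and sum to 1")
  if (psf_sigma < 0) stopf("psf_sigma must be >= 0")
  if (background_level < 0) stopf("background_level must be >= 0")
  if (read_noise_sd < 0) stopf("read_noise_sd must be >= 0")
  structure(list(
    shape = shape, n_cells = as.integer(n_cells),
    category_mix = category_mix, stage_mix = stage_mix,
    nucleus_radius = nucleus_radius, separation = separation,
    marker_amplitude = marker_amplitude,
    reporter_amplitude = reporter_amplitude,
    amplitude_jitter = amplitude_jitter,
    background_level = background_level,
    background_gradient = background_gradient,
    psf_sigma = psf_sigma, shot_noise = isTRUE(shot_noise),
    read_noise_sd = read_noise_sd,
    budneck_fraction = budneck_fraction,
    budneck_amplitude = budneck_amplitude,
    budneck_radius = budneck_radius
  ), class = "scene_params")
}

#' Generate a synthetic scene of dividing cells with full ground truth
#'
#' Places `n_cells` cells in the image by rejection sampling so that nuclei
#' of distinct cells stay far enough apart that their 4x-dilated background
#' rings never merge. Telophase cells carry a mother and a daughter nucleus
#' `separation` pixels apart and a ground-truth partitioning category that
#' dictates which nuclei receive reporter signal; S-phase and G1 cells
#' carry a single reporter-free nucleus. Mother/daughter identity is part
#' of the ground truth and is never inferred from size (delayed daughters
#' can outgrow their mothers).
#'
#' All randomness derives from `seed`; identical calls give identical
#' scenes. Coordinates are 0-based `(row, col)` with pixel centres at
#' integers.
#'
#' @param params a [scene_params()] list.
#' @param seed integer seed driving every random choice in the scene.
#' @return An object of class `synthetic_scene`: a list with `shape`,
#'   `cells` (one row per cell), `params` and `seed`.
#' @examples
#' sc <- generate_scene(scene_params(n_cells = 5), seed = 1)
#' truth_table(sc)
#' @export
generate_scene <- function(params = scene_params(), seed) {
  stopifnot(inherits(params, "scene_params"))
  seed <- as.integer(seed)
  with_seed(seed, {
    n <- params$n_cells
    r <- params$nucleus_radius
    # 4-step dilation adds 4 px per side; keep dilated discs of distinct
    # cells disjoint, and whole rings inside the frame.
    min_clear <- 2 * (ceiling(r) + 4) + 2
    margin <- ceiling(r) + 5
    lo <- margin
    hi_r <- params$shape[1] - 1 - margin
    hi_c <- params$shape[2] - 1 - margin
    if (hi_r <= lo || hi_c <= lo) stopf("image too small for margins")

    stage <- if (n > 0)
      sample(names(params$stage_mix), n, replace = TRUE,
             prob = params$stage_mix) else character()
    category <- rep("none", n)
    telo <- stage == "telophase"
    if (any(telo))
      category[telo] <- sample(names(params$category_mix), sum(telo),
                               replace = TRUE, prob = params$category_mix)

    placed <- matrix(numeric(0), ncol = 2)  # accepted nucleus centres
    cells <- vector("list", n)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (attempt in seq_len(500L)) {
        m <- c(sample(lo:hi_r, 1L), sample(lo:hi_c, 1L))
        if (telo[i]) {
          th <- stats::runif(1, 0, 2 * pi)
          d <- round(m + params$separation * c(cos(th), sin(th)))
          if (d[1] < lo || d[1] > hi_r || d[2] < lo || d[2] > hi_c) next
          new_pts <- rbind(m, d)
        } else new_pts <- rbind(m)
        if (nrow(placed) > 0) {
          dmin <- min(sqrt(outer(new_pts[, 1], placed[, 1], "-")^2 +
                           outer(new_pts[, 2], placed[, 2], "-")^2))
          if (dmin < min_clear) next
        }
        ok <- TRUE
        break
      }
      if (!ok)
        stopf(paste0("could not place cell %d after 500 attempts: scene too",
                     " dense for %d cells with clearance %d px in a %dx%d",
                     " image"),
              i, n, min_clear, params$shape[1], params$shape[2])
      placed <- rbind(placed, new_pts)
      jit <- function() stats::runif(1, 1 - params$amplitude_jitter,
                                     1 + params$amplitude_jitter)
      rep_m <- if (category[i] %in% c("asymmetric_mother", "symmetric"))
        params$reporter_amplitude * jit() else 0
      rep_d <- if (telo[i] &&
                   category[i] %in% c("asymmetric_daughter", "symmetric"))
        params$reporter_amplitude * jit() else 0
      bn <- telo[i] && stats::runif(1) < params$budneck_fraction
      cells[[i]] <- data.frame(
        cell_id = i, stage = stage[i], category = category[i],
        radius = r,
        mother_row = m[1], mother_col = m[2],
        daughter_row = if (telo[i]) new_pts[2, 1] else NA_real_,
        daughter_col = if (telo[i]) new_pts[2, 2] else NA_real_,
        marker_amp_mother = params$marker_amplitude * jit(),
        marker_amp_daughter = if (telo[i])
          params$marker_amplitude * jit() else NA_real_,
        reporter_amp_mother = rep_m,
        reporter_amp_daughter = if (telo[i]) rep_d else NA_real_,
        budneck = bn,
        budneck_row = if (bn) (m[1] + new_pts[2, 1]) / 2 else NA_real_,
        budneck_col = if (bn) (m[2] + new_pts[2, 2]) / 2 else NA_real_
      )
    }
    cells <- if (n > 0) do.call(rbind, cells) else data.frame()
    structure(list(shape = params$shape, cells = cells,
                   params = params, seed = seed),
              class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("synthetic_scene: %dx%d px, %d cells (seed %d)\n",
              x$shape[1], x$shape[2], nrow(x$cells), x$seed))
  if (nrow(x$cells) > 0) print(table(x$cells$stage, x$cells$category))
  invisible(x)
}

#' Ground-truth table of a scene, one row per nucleus
#'
#' @param scene a `synthetic_scene`.
#' @return data.frame with columns `cell_id`, `role`
#'   (mother/daughter/single), `row`, `col` (0-based), `radius`,
#'   `marker_amp`, `reporter_amp`, `category`, `stage`, `budneck`,
#'   `budneck_row`, `budneck_col`.
#' @export
truth_table <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  cl <- scene$cells
  if (nrow(cl) == 0)
    return(data.frame(cell_id = integer(), role = character(),
                      row = numeric(), col = numeric(), radius = numeric(),
                      marker_amp = numeric(), reporter_amp = numeric(),
                      category = character(), stage = character(),
                      budneck = logical(), budneck_row = numeric(),
                      budneck_col = numeric()))
  telo <- cl$stage == "telophase"
  mk <- function(rows, role, r, c, ma, ra) {
    data.frame(cell_id = rows$cell_id,
               role = rep_len(role, nrow(rows)),
               row = r, col = c, radius = rows$radius,
               marker_amp = ma, reporter_amp = ra,
               category = rows$category, stage = rows$stage,
               budneck = rows$budneck, budneck_row = rows$budneck_row,
               budneck_col = rows$budneck_col)
  }
  out <- rbind(
    mk(cl, ifelse(telo, "mother", "single"), cl$mother_row, cl$mother_col,
       cl$marker_amp_mother, cl$reporter_amp_mother),
    mk(cl[telo, , drop = FALSE], "daughter",
       cl$daughter_row[telo], cl$daughter_col[telo],
       cl$marker_amp_daughter[telo], cl$reporter_amp_daughter[telo])
  )
  out <- out[order(out$cell_id, out$role), ]
  rownames(out) <- NULL
  out
}

# Normalized Gaussian kernel covering +/- 3 sigma.
gaussian_kernel <- function(sigma) {
  h <- max(1L, ceiling(3 * sigma))
  x <- (-h):h
  k <- outer(exp(-x^2 / (2 * sigma^2)), exp(-x^2 / (2 * sigma^2)))
  k / sum(k)
}

# Add a hard disc of `amp` centred at 0-based (r0, c0) to matrix `img`.
add_disc <- function(img, r0, c0, radius, amp) {
  h <- ceiling(radius)
  rows <- max(0, floor(r0) - h):min(nrow(img) - 1, ceiling(r0) + h)
  cols <- max(0, floor(c0) - h):min(ncol(img) - 1, ceiling(c0) + h)
  sub <- outer((rows - r0)^2, (cols - c0)^2, "+") <= radius^2
  img[rows + 1, cols + 1] <- img[rows + 1, cols + 1] + amp * sub
  img
}

#' Render the channels of a synthetic scene
#'
#' Each nucleus is drawn as a hard disc of its amplitude, the summed signal
#' is convolved with a Gaussian point-spread function (circular boundary,
#' so flux is conserved exactly), and the smooth background surface is
#' added. If enabled, Poisson shot noise is applied to each pixel's
#' expected photon count and Gaussian read noise is added afterwards. The
#' marker channel shows every nucleus, the reporter channel only the nuclei
#' the ground-truth category assigns reporter to, and the budneck channel
#' the Myo1-like spots of pre-cytokinesis cells. Noise is seeded from the
#' scene seed, so rendering is reproducible.
#'
#' @param scene a `synthetic_scene`.
#' @return named list of numeric matrices: `marker`, `reporter`, `budneck`.
#' @export
render_channels <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  p <- scene$params
  nr <- scene$shape[1]; nc <- scene$shape[2]
  bg <- p$background_level +
    outer(p$background_gradient[1] * (seq_len(nr) - 1),
          p$background_gradient[2] * (seq_len(nc) - 1), "+")
  blank <- matrix(0, nr, nc)
  sig <- list(marker = blank, reporter = blank, budneck = blank)
  tt <- truth_table(scene)
  for (i in seq_len(nrow(tt))) {
    sig$marker <- add_disc(sig$marker, tt$row[i], tt$col[i], tt$radius[i],
                           tt$marker_amp[i])
    if (tt$reporter_amp[i] > 0)
      sig$reporter <- add_disc(sig$reporter, tt$row[i], tt$col[i],
                               tt$radius[i], tt$reporter_amp[i])
  }
  cl <- scene$cells
  for (i in which(cl$budneck %in% TRUE))
    sig$budneck <- add_disc(sig$budneck, cl$budneck_row[i],
                            cl$budneck_col[i], p$budneck_radius,
                            p$budneck_amplitude)
  if (p$psf_sigma > 0) {
    k <- gaussian_kernel(p$psf_sigma)
    sig <- lapply(sig, function(s)
      if (any(s > 0)) EBImage::filter2(s, k, boundary = "circular") else s)
  }
  imgs <- lapply(sig, function(s) s + bg)
  with_seed(scene$seed + 1L, {
    for (ch in names(imgs)) {
      img <- imgs[[ch]]
      if (p$shot_noise)
        img <- matrix(stats::rpois(length(img), pmax(img, 0)), nr, nc)
      if (p$read_noise_sd > 0)
        img <- img + stats::rnorm(length(img), 0, p$read_noise_sd)
      imgs[[ch]] <- img
    }
    imgs
  })
}

#' Write a scene and its rendered channels as an on-disk fixture
#'
#' Writes one 16-bit TIFF per channel, the ground-truth nucleus table as
#' CSV, and the scene parameters (plus seed) as a JSON sidecar, so a full
#' analysis can be run from files alone.
#'
#' @param scene a `synthetic_scene`.
#' @param images the output of [render_channels()].
#' @param directory output directory, created if missing.
#' @return Invisibly, a named list of the written paths.
#' @export
write_fixture <- function(scene, images, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (ch in names(images)) {
    paths[[ch]] <- file.path(directory, paste0(ch, ".tif"))
    write_image(images[[ch]], paths[[ch]])
  }
  paths$truth <- file.path(directory, "truth.csv")
  write_table(truth_table(scene), paths$truth)
  paths$scene <- file.path(directory, "scene.json")
  meta <- c(unclass(scene$params), list(seed = scene$seed))
  jsonlite::write_json(meta, paths$scene, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

#' Read back a fixture written by [write_fixture()]
#'
#' @param directory fixture directory.
#' @return list with `images` (named matrices), `truth` (data.frame) and
#'   `meta` (scene parameters as a plain list).
#' @export
read_fixture <- function(directory) {
  chans <- c("marker", "reporter", "budneck")
  files <- file.path(directory, paste0(chans, ".tif"))
  present <- file.exists(files)
  images <- lapply(files[present], read_image)
  names(images) <- chans[present]
  truth_path <- file.path(directory, "truth.csv")
  truth <- if (file.exists(truth_path)) read_table(truth_path) else NULL
  meta_path <- file.path(directory, "scene.json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else NULL
  list(images = images, truth = truth, meta = meta)
}
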