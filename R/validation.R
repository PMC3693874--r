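# Built-in validation experiments on synthetic phantoms. These mirror the
# package's standard benchmark scenes: spot-intensity estimation against
# known kernels, and segmentation recovery under increasing noise.

#' Spot-intensity estimator benchmark
#'
#' Places `n_spots` copies of the reference PSF kernel (peak 95.9719,
#' sigma 0.65 px) at pixel centers inside rendered cells whose interior
#' level plays the role of the kernel offset, corrupts the scene with
#' additive Gaussian white noise, and estimates every spot intensity with
#' the anchored Gaussian PSF fit, the max-intensity baseline and the
#' rolling-ball baseline. Errors are measured against the true peak.
#'
#' @param n_spots number of spots per replicate.
#' @param noise_std noise standard deviation, gray levels.
#' @param seeds integer vector; one replicate per seed.
#' @param offset local background level under the spots (cell interior),
#'   gray levels.
#' @param dish optional dish intensity to make the image background
#'   non-uniform (NULL for a flat background).
#' @return list with `abs_errors` (per method, vector over all spots and
#'   seeds), `mae`, `sd` (per method), and `I_real`.
#' @export
spot_intensity_experiment <- function(n_spots = 38, noise_std = 15,
                                      seeds = 1:10, offset = 80,
                                      dish = NULL) {
  I_real <- 95.9719
  spot_sigma <- 0.65
  per_cell <- 2
  n_cells <- ceiling(n_spots / per_cell)
  n_col <- 6
  n_row <- ceiling(n_cells / n_col)
  width <- n_col * 72 + 40
  height <- n_row * 34 + 40
  cells <- list()
  positions <- list()
  for (i in seq_len(n_cells)) {
    r <- (i - 1) %/% n_col
    c <- (i - 1) %% n_col
    ctr <- c(40 + c * 72 + 16, 36 + r * 34)
    cells[[i]] <- phantom_cell(ctr, length = 56, width = 14,
                               orientation = 0, intensity = offset)
    positions[[2 * i - 1]] <- ctr + c(-10, 0)
    positions[[2 * i]] <- ctr + c(10, 0)
  }
  positions <- positions[seq_len(n_spots)]
  spots <- lapply(positions, phantom_spot, A = I_real, sigma = spot_sigma)
  errs <- list(gaussfit = c(), max_int = c(), rolling_ball = c())
  for (seed in seeds) {
    spec <- phantom_spec(c(height, width), cells = cells, spots = spots,
                         background_intensity = 25, dish = dish,
                         noise_std = noise_std, seed = seed)
    img <- render_phantom(spec)$noisy
    rb <- baseline_rolling_ball(img, radius = 10)
    for (p in positions) {
      fit <- fit_spot_gaussian(img, p, window = 9,
                               init_sigma = spot_sigma)
      errs$gaussfit <- c(errs$gaussfit, abs(fit$A - I_real))
      errs$max_int <- c(errs$max_int,
                        abs(baseline_max_intensity(img, p, 5) - I_real))
      errs$rolling_ball <- c(errs$rolling_ball,
                             abs(baseline_max_intensity(rb, p, 5) - I_real))
    }
  }
  list(
    abs_errors = errs,
    mae = vapply(errs, mean, numeric(1)),
    sd = vapply(errs, stats::sd, numeric(1)),
    I_real = I_real
  )
}

#' Segmentation-recovery benchmark
#'
#' Renders the standard single-cell phantom (length 60, width 14, oriented
#' 0.3 rad, interior 229 on background 25) under a given noise level, runs
#' the rodscule from a fixed overlapping initialization, and reports the
#' mean distance between the fitted inner-rod boundary and the ground-truth
#' cell boundary.
#'
#' @param noise_std additive noise standard deviation.
#' @param seed noise seed.
#' @return list with `boundary_dist` (mean, px), `fit` (optimizer result),
#'   `truth` (the ground-truth rodscule state).
#' @export
segmentation_experiment <- function(noise_std, seed = 1) {
  cell <- phantom_cell(c(60, 45), length = 60, width = 14,
                       orientation = 0.3, intensity = 229)
  spec <- phantom_spec(c(90, 120), cells = list(cell),
                       background_intensity = 25,
                       noise_std = noise_std, seed = seed)
  img <- render_phantom(spec)$noisy
  truth <- rodscule_from_rod(cell$center, cell$orientation,
                             half_length = cell$length / 2 - cell$width / 2,
                             radius = cell$width / 2)
  init <- rodscule_from_rod(c(55, 41), 0.1, 18, 9)
  fit <- rodscule_optimize(img, init)
  bp <- rod_boundary_points(fit$state, n = 200)
  gt <- rod_geometry(truth)
  d <- abs(point_segment_distance(bp[, 1], bp[, 2], gt$K1, gt$K2) -
             gt$radius_inner)
  list(boundary_dist = mean(d), fit = fit, truth = truth)
}

#' Low-PSNR tracking benchmark
#'
#' Generates a bounded random-walk spot of amplitude `A` on noise of
#' standard deviation `noise_std` (so `psnr(A, noise_std)` sets the
#' regime), tracks it with the dense DP tracker, and returns the positional
#' RMSE against ground truth.
#'
#' @param n_frames sequence length.
#' @param A spot amplitude above background.
#' @param noise_std noise standard deviation.
#' @param spot_sigma spot spread, px.
#' @param seed replicate seed.
#' @return list with `rmse` (px), `track` and `truth` positions.
#' @export
tracking_experiment <- function(n_frames = 50, A = 20, noise_std = 20,
                                spot_sigma = 2, seed = 1) {
  n <- 64
  truth <- random_walk_track(c(32, 32), n_frames, max_step = 2.8,
                             image_shape = c(n, n), margin = 9, seed = seed)
  spec <- phantom_spec(c(n, n),
                       spots = list(phantom_spot(truth[1, ], A = A,
                                                 sigma = spot_sigma)),
                       background_intensity = 30,
                       noise_std = noise_std, seed = seed)
  tl <- timelapse_spec(spec, n_frames, list(truth),
                       list(rep(A, n_frames)), max_step = 4,
                       seed = seed * 1000)
  frames <- generate_timelapse(tl)$frames
  resps <- lapply(frames, log_filter, sigma = spot_sigma)
  tr <- track_dense(resps, max_displacement = 4)
  rmse <- sqrt(mean((tr$positions$x - truth[, 1])^2 +
                      (tr$positions$y - truth[, 2])^2))
  list(rmse = rmse, track = tr, truth = truth)
}
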