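# Synthetic phantom scenes: rod-shaped cells with optional nucleus holes and
# a petri-dish disc, Gaussian spots, additive Gaussian white noise, and
# time-lapse sequences with ground-truth tracks. The defaults reproduce the
# validation regime used throughout the package: an 8-bit image with
# background 25 and cell interior 229 (signal RMS about 204 over the cell
# support, so noise std {10, 30, 60, 90, 120} spans roughly 26 down to 5 dB).

#' Describe a phantom cell
#'
#' @param center numeric length-2 `c(x, y)` in px.
#' @param length tip-to-tip cell length, px.
#' @param width cell width, px (must be <= length).
#' @param orientation axis angle, radians.
#' @param intensity interior intensity, gray levels.
#' @param holes optional list of `list(center = c(x, y), radius, intensity)`
#'   darker discs emulating nuclei that exclude the cytoplasmic marker.
#' @return a list of class `phantom_cell`.
#' @export
phantom_cell <- function(center, length = 60, width = 14, orientation = 0,
                         intensity = 229, holes = NULL) {
  stopifnot(width > 0, length >= width)
  structure(list(
    center = as.numeric(center), length = length, width = width,
    orientation = orientation, intensity = intensity, holes = holes
  ), class = "phantom_cell")
}

#' Describe a phantom spot
#'
#' An isotropic Gaussian of peak amplitude `A` *added* on top of whatever
#' lies beneath it (cell interior or background), emulating a
#' diffraction-limited fluorescent structure.
#'
#' @param position numeric length-2 `c(x, y)`, px.
#' @param A peak amplitude above the local level, gray levels.
#' @param sigma Gaussian spread, px.
#' @return a list of class `phantom_spot`.
#' @export
phantom_spot <- function(position, A = 95.9719, sigma = 0.65) {
  stopifnot(A >= 0, sigma > 0)
  structure(list(position = as.numeric(position), A = A, sigma = sigma),
            class = "phantom_spot")
}

#' Describe a full phantom scene
#'
#' @param image_shape integer length-2 `c(height, width)` in px.
#' @param cells list of [phantom_cell()] objects; must be pairwise disjoint.
#' @param spots list of [phantom_spot()] objects.
#' @param background_intensity background gray level.
#' @param dish optional `list(center = c(x, y), radius, intensity)` disc
#'   emulating the petri dish.
#' @param noise_std additive Gaussian white-noise standard deviation.
#' @param bit_depth 8 or 16.
#' @param seed integer seed for the noise.
#' @return a list of class `phantom_spec`.
#' @export
phantom_spec <- function(image_shape, cells = list(), spots = list(),
                         background_intensity = 25, dish = NULL,
                         noise_std = 0, bit_depth = 8, seed = 1) {
  stopifnot(length(image_shape) == 2, noise_std >= 0, bit_depth %in% c(8, 16))
  cells <- check_cell_overlap(cells)
  structure(list(
    image_shape = as.integer(image_shape), cells = cells, spots = spots,
    background_intensity = background_intensity, dish = dish,
    noise_std = noise_std, bit_depth = bit_depth, seed = as.integer(seed)
  ), class = "phantom_spec")
}

check_cell_overlap <- function(cells) {
  if (length(cells) < 2) return(cells)
  axes <- lapply(cells, function(cl) {
    r <- cl$width / 2
    l <- cl$length / 2 - r
    d <- c(cos(cl$orientation), sin(cl$orientation))
    list(a = cl$center - l * d, b = cl$center + l * d, r = r)
  })
  for (i in seq_along(cells)) {
    for (j in seq_len(i - 1)) {
      gap <- segment_segment_distance(axes[[i]]$a, axes[[i]]$b,
                                      axes[[j]]$a, axes[[j]]$b) -
        axes[[i]]$r - axes[[j]]$r
      if (gap <= 0) {
        stop(sprintf("cells %d and %d overlap (boundary gap %.2f px)",
                     j, i, gap))
      }
    }
  }
  cells
}

#' Sampled isotropic Gaussian kernel
#'
#' Gaussian of peak `A` sampled at pixel centers on an odd `size` x `size`
#' grid, plus a constant offset `B`. With `A = 95.9719`, `sigma = 0.65` this
#' reproduces the package's reference point-spread-function kernel (see
#' [reference_kernel()]).
#'
#' @param A peak amplitude, gray levels.
#' @param sigma spread, px.
#' @param B constant offset, gray levels.
#' @param size odd kernel side length, px.
#' @return `size` x `size` numeric matrix.
#' @export
gaussian_kernel <- function(A, sigma, B = 0, size = 5) {
  stopifnot(size %% 2 == 1, sigma > 0, A >= 0)
  h <- (size - 1) / 2
  xs <- -h:h
  outer(xs, xs, function(x, y) A * exp(-(x^2 + y^2) / (2 * sigma^2))) + B
}

#' Reference 5x5 PSF kernel
#'
#' The discretised Gaussian kernel used throughout the intensity-estimation
#' validation experiments: peak 95.9719, sigma 0.65 px, optionally with a
#' constant offset (80 is the conventional test offset). Shipped as a
#' plain-text fixture and regenerated analytically here.
#'
#' @param offset constant background offset, gray levels.
#' @return 5 x 5 numeric matrix.
#' @export
reference_kernel <- function(offset = 0) {
  round(gaussian_kernel(95.9719, 0.65, B = 0, size = 5), 4) + offset
}

#' Additive Gaussian white noise
#'
#' Adds zero-mean i.i.d. Gaussian noise, rounds to integer gray levels and
#' clips to the bit range. Reproducible for a given seed.
#'
#' @param image numeric matrix.
#' @param std noise standard deviation, gray levels (>= 0).
#' @param seed integer seed.
#' @param bit_depth 8 or 16.
#' @return numeric matrix of quantised, clipped gray levels.
#' @export
add_noise <- function(image, std, seed = 1, bit_depth = 8) {
  if (std < 0) stop("noise std must be >= 0")
  if (std == 0) return(image)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  noisy <- image + matrix(stats::rnorm(length(image), 0, std),
                          nrow(image), ncol(image))
  clip_quantize(noisy, bit_depth)
}

clip_quantize <- function(image, bit_depth) {
  top <- 2^bit_depth - 1
  matrix(pmin(pmax(round(image), 0), top), nrow(image), ncol(image))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Render a phantom scene
#'
#' Composes background, optional dish disc, anti-aliased cells, nucleus
#' holes and Gaussian spots into a noise-free floating-point image, then
#' adds seeded noise, rounds and clips to the bit range.
#'
#' @param spec a [phantom_spec()].
#' @return a list with `clean` (noise-free, unquantised), `noisy` (quantised
#'   and clipped gray levels) and `ground_truth` (cell poses and spot
#'   positions/amplitudes as data frames).
#' @export
render_phantom <- function(spec) {
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  X <- rep(seq_len(nc), each = nr)
  Y <- rep(seq_len(nr), times = nc)
  img <- rep(spec$background_intensity, nr * nc)
  if (!is.null(spec$dish)) {
    dd <- sqrt((X - spec$dish$center[1])^2 + (Y - spec$dish$center[2])^2)
    w <- edge_profile(dd - spec$dish$radius)
    img <- img + (spec$dish$intensity - spec$background_intensity) * w
  }
  for (cl in spec$cells) {
    r <- cl$width / 2
    l <- cl$length / 2 - r
    d <- c(cos(cl$orientation), sin(cl$orientation))
    w <- stadium_coverage(X, Y, cl$center - l * d, cl$center + l * d, r)
    img <- img + (cl$intensity - img) * w
    for (h in cl$holes %||% list()) {
      dd <- sqrt((X - h$center[1])^2 + (Y - h$center[2])^2)
      wh <- edge_profile(dd - h$radius)
      img <- img + (h$intensity - img) * wh * w
    }
  }
  for (sp in spec$spots) {
    img <- img + sp$A *
      exp(-((X - sp$position[1])^2 + (Y - sp$position[2])^2) /
            (2 * sp$sigma^2))
  }
  clean <- matrix(img, nr, nc)
  noisy <- if (spec$noise_std > 0) {
    add_noise(clean, spec$noise_std, seed = spec$seed,
              bit_depth = spec$bit_depth)
  } else {
    clip_quantize(clean, spec$bit_depth)
  }
  gt_cells <- if (length(spec$cells)) {
    do.call(rbind, lapply(seq_along(spec$cells), function(i) {
      cl <- spec$cells[[i]]
      data.frame(cell = i, x = cl$center[1], y = cl$center[2],
                 length = cl$length, width = cl$width,
                 orientation = cl$orientation, intensity = cl$intensity)
    }))
  } else data.frame()
  gt_spots <- if (length(spec$spots)) {
    do.call(rbind, lapply(seq_along(spec$spots), function(i) {
      sp <- spec$spots[[i]]
      data.frame(spot = i, x = sp$position[1], y = sp$position[2],
                 A = sp$A, sigma = sp$sigma)
    }))
  } else data.frame()
  list(clean = clean, noisy = noisy,
       ground_truth = list(cells = gt_cells, spots = gt_spots))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Peak signal-to-noise ratio of a spot
#'
#' `PSNR = 20 * log10(A / sigma)` in dB, for spot amplitude `A` and noise
#' standard deviation `sigma`.
#'
#' @param A spot amplitude (> 0), gray levels.
#' @param sigma noise standard deviation (> 0), gray levels.
#' @export
psnr <- function(A, sigma) {
  if (any(A <= 0) || any(sigma <= 0)) stop("A and sigma must be positive")
  20 * log10(A / sigma)
}

#' Image signal-to-noise ratio
#'
#' `SNR = 20 * log10(S / sigma)` where the signal measure `S` is the RMS of
#' the background-subtracted noise-free image over the cell support (pixels
#' with cell coverage above one half).
#'
#' @param clean noise-free image matrix.
#' @param noise_std noise standard deviation (> 0).
#' @param background background intensity subtracted before the RMS.
#' @param mask logical matrix marking the cell support; default: pixels more
#'   than 1 gray level away from `background`.
#' @export
snr <- function(clean, noise_std, background = 0, mask = NULL) {
  if (noise_std <= 0) stop("noise_std must be positive")
  if (is.null(mask)) mask <- abs(clean - background) > 1
  s2 <- mean((clean[mask] - background)^2)
  if (!is.finite(s2) || s2 <= 0) stop("zero-signal image")
  20 * log10(sqrt(s2) / noise_std)
}

#' Mean absolute error of intensity estimates
#'
#' @param estimates numeric vector of estimated intensities.
#' @param I_real true intensity.
#' @export
mean_abs_error <- function(estimates, I_real) {
  if (length(estimates) == 0) stop("empty estimate list")
  mean(abs(estimates - I_real))
}

#' Inter- and intra-observer variability
#'
#' For measurements on a complete observer x repetition x spot grid,
#' the inter-observer variability averages absolute differences across all
#' observer pairs within each repetition, and the intra-observer variability
#' averages across all repetition pairs within each observer:
#' `V_inter = (1 / (R * choose(O, 2) * P)) * sum |x_{i,r,p} - x_{j,r,p}|`,
#' `V_intra = (1 / (O * choose(R, 2) * P)) * sum |x_{o,i,p} - x_{o,j,p}|`.
#' With the conventional grid of 4 observers and 3 repetitions the
#' normalising constants are 18 P and 12 P.
#'
#' @param x numeric 3D array `[observer, repetition, spot]`; images are
#'   pooled into the spot index. No missing values allowed.
#' @return named numeric vector `c(V_inter, V_intra)`.
#' @export
observer_variability <- function(x) {
  stopifnot(length(dim(x)) == 3)
  if (any(is.na(x))) stop("missing cells in the measurement grid")
  O <- dim(x)[1]; R <- dim(x)[2]; P <- dim(x)[3]
  stopifnot(O >= 2, R >= 2, P >= 1)
  v_inter <- 0
  for (r in seq_len(R)) {
    for (i in seq_len(O - 1)) for (j in (i + 1):O) {
      v_inter <- v_inter + sum(abs(x[i, r, ] - x[j, r, ]))
    }
  }
  v_inter <- v_inter / (R * choose(O, 2) * P)
  v_intra <- 0
  for (o in seq_len(O)) {
    for (i in seq_len(R - 1)) for (j in (i + 1):R) {
      v_intra <- v_intra + sum(abs(x[o, i, ] - x[o, j, ]))
    }
  }
  v_intra <- v_intra / (O * choose(R, 2) * P)
  c(V_inter = v_inter, V_intra = v_intra)
}

#' Describe a time-lapse phantom
#'
#' @param base a [phantom_spec()]; its spots give the frame-1 positions.
#' @param n_frames number of frames.
#' @param tracks list (one per spot) of `n_frames` x 2 matrices of
#'   ground-truth positions `(x, y)`; per-frame displacement must stay
#'   within `max_step` and every position inside the image.
#' @param amplitudes list (one per spot) of length-`n_frames` amplitude
#'   profiles (constant, or fading below the noise floor at some frame).
#' @param max_step declared per-frame displacement bound, px.
#' @param seed integer; frame noise uses `seed + frame`.
#' @return a list of class `timelapse_spec`.
#' @export
timelapse_spec <- function(base, n_frames, tracks, amplitudes,
                           max_step = 4, seed = 1) {
  stopifnot(inherits(base, "phantom_spec"), n_frames >= 2,
            length(tracks) == length(base$spots),
            length(amplitudes) == length(base$spots))
  nr <- base$image_shape[1]; nc <- base$image_shape[2]
  for (k in seq_along(tracks)) {
    tr <- tracks[[k]]
    stopifnot(nrow(tr) == n_frames, ncol(tr) == 2)
    if (any(tr[, 1] < 1 | tr[, 1] > nc | tr[, 2] < 1 | tr[, 2] > nr)) {
      stop(sprintf("track %d leaves the image", k))
    }
    steps <- sqrt(rowSums((tr[-1, , drop = FALSE] -
                             tr[-n_frames, , drop = FALSE])^2))
    if (any(steps > max_step + 1e-9)) {
      stop(sprintf("track %d exceeds the per-frame displacement bound", k))
    }
    stopifnot(length(amplitudes[[k]]) == n_frames)
  }
  structure(list(base = base, n_frames = n_frames, tracks = tracks,
                 amplitudes = amplitudes, max_step = max_step,
                 seed = as.integer(seed)),
            class = "timelapse_spec")
}

#' Bounded random-walk ground-truth track
#'
#' Uniform per-frame steps bounded by `max_step` (in each coordinate,
#' `max_step/sqrt(2)` so the Euclidean step respects the bound), reflected
#' off a safety margin inside the image.
#'
#' @param start numeric length-2 `c(x, y)`.
#' @param n_frames number of frames.
#' @param max_step Euclidean per-frame bound, px.
#' @param image_shape `c(height, width)`.
#' @param margin kept distance from the borders, px.
#' @param seed integer seed.
#' @return `n_frames` x 2 matrix.
#' @export
random_walk_track <- function(start, n_frames, max_step, image_shape,
                              margin = 8, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  s <- max_step / sqrt(2)
  pos <- matrix(0, n_frames, 2)
  pos[1, ] <- start
  lo <- c(margin, margin)
  hi <- c(image_shape[2] - margin, image_shape[1] - margin)
  for (t in 2:n_frames) {
    repeat {
      p <- pos[t - 1, ] + stats::runif(2, -s, s)
      if (all(p >= lo & p <= hi)) break
    }
    pos[t, ] <- p
  }
  pos
}

#' Render a time-lapse phantom
#'
#' Each frame re-renders the base scene with the spots moved to their
#' ground-truth positions and scaled to their per-frame amplitudes; noise is
#' drawn independently per frame (seed + frame index).
#'
#' @param spec a [timelapse_spec()].
#' @return list with `frames` (list of matrices, quantised), `clean` (list
#'   of noise-free matrices) and `ground_truth` (data frame: frame, spot,
#'   x, y, A).
#' @export
generate_timelapse <- function(spec) {
  frames <- vector("list", spec$n_frames)
  clean <- vector("list", spec$n_frames)
  gt <- list()
  for (t in seq_len(spec$n_frames)) {
    spots_t <- lapply(seq_along(spec$base$spots), function(k) {
      phantom_spot(spec$tracks[[k]][t, ],
                   A = spec$amplitudes[[k]][t],
                   sigma = spec$base$spots[[k]]$sigma)
    })
    spec_t <- spec$base
    spec_t$spots <- spots_t
    spec_t$seed <- spec$seed + t
    out <- render_phantom(spec_t)
    frames[[t]] <- out$noisy
    clean[[t]] <- out$clean
    gt[[t]] <- data.frame(
      frame = t,
      spot = seq_along(spec$base$spots),
      x = vapply(spec$tracks, function(tr) tr[t, 1], numeric(1)),
      y = vapply(spec$tracks, function(tr) tr[t, 2], numeric(1)),
      A = vapply(spec$amplitudes, function(a) a[t], numeric(1))
    )
  }
  list(frames = frames, clean = clean, ground_truth = do.call(rbind, gt))
}
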