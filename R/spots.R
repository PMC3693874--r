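# Spot detection and intensity estimation.
#
# Detection: scale-normalised Laplacian-of-Gaussian filtering (one
# parameter, sigma, tied to the spot size) followed by greedy local-maximum
# selection with non-maximum suppression. Intensity: least-squares fit of a
# rotated 2D Gaussian with constant offset,
#   f(x, y) = A * exp(-(a dx^2 + 2 b dx dy + c dy^2)) + B,
#   a = cos^2(t)/(2 sx^2) + sin^2(t)/(2 sy^2)
#   b = -sin(2t)/(4 sx^2) + sin(2t)/(4 sy^2)
#   c = sin^2(t)/(2 sx^2) + cos^2(t)/(2 sy^2),
# solved with Levenberg-Marquardt. At t = 0 the exponent reduces to the
# axis-aligned Gaussian; the model is invariant under (t + pi/2, sx<->sy).

#' Scale-normalised Laplacian-of-Gaussian kernel
#'
#' Direct LoG kernel truncated at 4 sigma, sign-flipped so bright spots
#' yield positive responses, scale-normalised by sigma^2, and adjusted to
#' zero sum so constant images give exactly zero response.
#'
#' @param sigma scale in px (> 0).
#' @return square numeric matrix of odd side length `2*ceiling(4*sigma)+1`.
#' @export
log_kernel <- function(sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  h <- ceiling(4 * sigma)
  xs <- -h:h
  G <- outer(xs, xs, function(x, y) {
    exp(-(x^2 + y^2) / (2 * sigma^2)) / (2 * pi * sigma^2)
  })
  L <- outer(xs, xs, function(x, y) (x^2 + y^2 - 2 * sigma^2) / sigma^4) * G
  k <- -sigma^2 * L
  k - mean(k)
}

#' Laplacian-of-Gaussian spot-enhancing filter
#'
#' @param image numeric matrix.
#' @param sigma LoG scale in px, matched to the spot size.
#' @return filtered image (same size); bright blobs of spread ~ sigma
#'   appear as positive peaks.
#' @export
log_filter <- function(image, sigma) {
  k <- log_kernel(sigma)
  as.matrix(EBImage::filter2(image, k, boundary = "replicate"))
}

#' Detect spot candidates
#'
#' Local maxima of a (filtered) response image, greedily selected in order
#' of decreasing response with non-maximum suppression at `min_separation`,
#' optionally restricted to a mask and/or thresholded.
#'
#' @param response numeric matrix, e.g. the output of [log_filter()].
#' @param n_max maximum number of candidates to return (>= 1).
#' @param min_separation minimum distance between accepted candidates, px.
#' @param mask optional logical matrix; candidates outside are discarded.
#' @param threshold optional minimum response value.
#' @return data frame with columns `x`, `y`, `response`, ordered by
#'   decreasing response. May have fewer than `n_max` rows.
#' @export
detect_spots <- function(response, n_max = 2, min_separation = 5,
                         mask = NULL, threshold = NULL) {
  stopifnot(n_max >= 1)
  nr <- nrow(response); nc <- ncol(response)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- response
  is_max <- response
  is_max[] <- TRUE
  any_gt <- response
  any_gt[] <- FALSE
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- pad[(2 + dy):(nr + 1 + dy), (2 + dx):(nc + 1 + dx)]
    is_max <- is_max & (response >= nb)
    any_gt <- any_gt | (response > nb)
  }
  is_max <- is_max & any_gt    # exclude flat plateaus
  if (!is.null(mask)) is_max <- is_max & mask
  if (!is.null(threshold)) is_max <- is_max & (response >= threshold)
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(data.frame(x = numeric(0), y = numeric(0), response = numeric(0)))
  }
  ord <- order(response[idx], decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]
  keep <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(idx))) {
    p <- idx[i, ]
    if (nrow(keep) == 0 ||
        all((keep[, 1] - p[1])^2 + (keep[, 2] - p[2])^2 >=
              min_separation^2)) {
      keep <- rbind(keep, p)
    }
    if (nrow(keep) >= n_max) break
  }
  data.frame(x = keep[, 2], y = keep[, 1], response = response[keep])
}

gauss2d_model <- function(p, x, y) {
  # p = (A, B, mx, my, sx, sy, theta)
  ct <- cos(p[7]); st <- sin(p[7]); s2t <- sin(2 * p[7])
  a <- ct^2 / (2 * p[5]^2) + st^2 / (2 * p[6]^2)
  b <- -s2t / (4 * p[5]^2) + s2t / (4 * p[6]^2)
  cc <- st^2 / (2 * p[5]^2) + ct^2 / (2 * p[6]^2)
  dx <- x - p[3]; dy <- y - p[4]
  p[1] * exp(-(a * dx^2 + 2 * b * dx * dy + cc * dy^2)) + p[2]
}

#' Fit a rotated 2D Gaussian with offset to a spot
#'
#' Levenberg-Marquardt least squares over a square window centered on the
#' candidate. Initialisation follows the standard microscope-driven rule:
#' `sigma0 = diffraction_limit / pixel_size` (or `init_sigma`), `theta0 = 0`,
#' `A0 = max - min` and `B0 = min` over the window, center at the candidate.
#'
#' Two center policies are available. `"anchor"` (the default used for
#' intensity estimation) keeps the Gaussian center at the candidate
#' position: for sub-pixel-width point-sampled spots the fully free
#' least-squares problem is weakly identifiable under noise (sigma can
#' collapse while the amplitude inflates), and the detection already
#' localises the peak pixel. `"free"` releases the center (bounded to the
#' window) for sub-pixel localisation; it is exact on noise-free data.
#'
#' @param image numeric matrix.
#' @param candidate numeric length-2 `c(x, y)` candidate position (may be
#'   sub-pixel).
#' @param window odd window side length, px.
#' @param pixel_size,diffraction_limit microscope parameters (same units,
#'   e.g. micrometers); their ratio initialises sigma.
#' @param init_sigma explicit initial sigma, px (overrides the ratio).
#' @param center `"anchor"` or `"free"`.
#' @return a list of class `spot_fit` with elements `A`, `B`, `mu` (length-2
#'   x, y), `sigma` (length-2), `theta` (radians in (-pi/2, pi/2]),
#'   `residual_rms`, `converged`, `at_bounds`.
#' @export
fit_spot_gaussian <- function(image, candidate, window = 9,
                              pixel_size = NULL, diffraction_limit = NULL,
                              init_sigma = NULL,
                              center = c("anchor", "free")) {
  center <- match.arg(center)
  stopifnot(window %% 2 == 1)
  cx <- round(candidate[1]); cy <- round(candidate[2])
  h <- (window - 1) / 2
  xs <- max(1, cx - h):min(ncol(image), cx + h)
  ys <- max(1, cy - h):min(nrow(image), cy + h)
  if (length(xs) < 5 || length(ys) < 5) {
    stop("fit window has fewer than 5x5 valid pixels")
  }
  X <- rep(xs, times = length(ys))
  Y <- rep(ys, each = length(xs))
  Z <- as.numeric(image[cbind(Y, X)])

  s0 <- if (!is.null(init_sigma)) {
    init_sigma
  } else if (!is.null(pixel_size) && !is.null(diffraction_limit)) {
    diffraction_limit / pixel_size
  } else 1
  whalf <- max(length(xs), length(ys)) / 2
  sig_lo <- if (center == "anchor") 0.5 else 0.3
  mu_lo <- if (center == "anchor") c(candidate[1], candidate[2])
           else c(min(xs), min(ys))
  mu_hi <- if (center == "anchor") c(candidate[1], candidate[2])
           else c(max(xs), max(ys))
  lower <- c(0, -Inf, mu_lo, sig_lo, sig_lo, -pi)
  upper <- c(Inf, Inf, mu_hi, whalf, whalf, pi)
  # a symmetric start (theta = 0, sx = sy) has an exactly zero angle
  # gradient, so anisotropic spots need tilted starts as well; the best
  # residual wins (deterministic)
  starts <- list(c(0, 1, 1), c(pi / 4, 1.3, 0.77), c(-pi / 4, 1.3, 0.77))
  fit <- NULL
  for (s in starts) {
    p0 <- c(A = max(Z) - min(Z), B = min(Z),
            mx = candidate[1], my = candidate[2],
            sx = s0 * s[2], sy = s0 * s[3], theta = s[1])
    p0 <- pmin(pmax(p0, lower), upper)
    cand_fit <- minpack.lm::nls.lm(
      par = p0, lower = lower, upper = upper,
      fn = function(p) gauss2d_model(p, X, Y) - Z,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    if (is.null(fit) || cand_fit$deviance < fit$deviance) fit <- cand_fit
  }
  p <- coef(fit)
  theta <- normalize_orientation(p[7])
  if (abs(p[5] - p[6]) < 1e-6) theta <- 0   # isotropic: angle meaningless
  at_bounds <- any(abs(p[c(5, 6)] - sig_lo) < 1e-9) ||
    any(abs(p[c(5, 6)] - whalf) < 1e-9)
  structure(list(
    A = unname(p[1]), B = unname(p[2]),
    mu = unname(p[3:4]), sigma = unname(p[5:6]), theta = unname(theta),
    residual_rms = sqrt(mean(fit$fvec^2)),
    converged = fit$info %in% 1:4,
    at_bounds = at_bounds
  ), class = "spot_fit")
}

#' @export
print.spot_fit <- function(x, ...) {
  cat(sprintf(
    "spot_fit: A=%.3f B=%.3f mu=(%.2f, %.2f) sigma=(%.2f, %.2f) theta=%.3f\n",
    x$A, x$B, x$mu[1], x$mu[2], x$sigma[1], x$sigma[2], x$theta
  ))
  invisible(x)
}

#' Maximum-intensity baseline estimator
#'
#' The classical estimate: the maximum pixel value in an odd neighborhood
#' around the candidate. No background subtraction, hence strongly biased
#' when the spot sits on a non-zero offset.
#'
#' @inheritParams fit_spot_gaussian
#' @param neighborhood odd side length, px.
#' @export
baseline_max_intensity <- function(image, candidate, neighborhood = 5) {
  stopifnot(neighborhood %% 2 == 1)
  h <- (neighborhood - 1) / 2
  cx <- round(candidate[1]); cy <- round(candidate[2])
  xs <- max(1, cx - h):min(ncol(image), cx + h)
  ys <- max(1, cy - h):min(nrow(image), cy + h)
  max(image[ys, xs])
}

#' Rolling-ball background subtraction
#'
#' Morphological background estimate: grayscale opening with a disc
#' structuring element of the given radius; the opened image is subtracted
#' and the result clipped at zero. Small bright features narrower than the
#' disc survive; smooth background is removed.
#'
#' @param image numeric matrix.
#' @param radius ball/disc radius, px (> 0).
#' @return background-subtracted image, non-negative.
#' @export
baseline_rolling_ball <- function(image, radius = 10) {
  if (radius <= 0) stop("radius must be positive")
  lo <- min(image); hi <- max(image)
  if (hi - lo < 1e-12) return(matrix(0, nrow(image), ncol(image)))
  scaled <- (image - lo) / (hi - lo)   # EBImage morphology expects [0, 1]
  brush <- EBImage::makeBrush(2 * ceiling(radius) + 1, shape = "disc")
  bg <- as.matrix(EBImage::opening(EBImage::Image(t(scaled)), brush))
  bg <- t(bg) * (hi - lo) + lo
  pmax(matrix(image - bg, nrow(image), ncol(image)), 0)
}
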