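# The rodscule: a parametric active contour for rod-shaped (stadium) cells.
#
# The contour is parametrised by three points P, Q, R on the border of an
# ellipse whose center is the centroid of the triangle PQR (the Steiner
# circumellipse; the same construction as the ovuscule family of surface
# snakes). The ellipse carries a pair of concentric stadium shapes: the
# outer rod Sigma with radius equal to the semi-minor axis and caps centered
# so the major-axis extremal points lie on the cap arcs, and an inner rod
# Sigma' with the same orientation and barycenter and exactly half the area
# (the outer rod scaled by 1/sqrt(2)). The contrast energy drives the inner
# rod onto the cell: at the optimum Sigma' covers the bright interior while
# the ring Sigma \ Sigma' samples background, so the *inner* rod is the
# reported segmentation.

#' Create a rodscule state
#'
#' @param P,Q,R numeric length-2 points `c(x, y)` on the border of the
#'   defining ellipse. They must not be collinear.
#' @return an object of class `rodscule_state`.
#' @examples
#' s <- rodscule_state(c(30, 10), c(5, 18), c(5, 2))
#' rod_geometry(s)$area_outer
#' @export
rodscule_state <- function(P, Q, R) {
  stopifnot(length(P) == 2, length(Q) == 2, length(R) == 2)
  P <- as.numeric(P); Q <- as.numeric(Q); R <- as.numeric(R)
  cross <- (Q[1] - P[1]) * (R[2] - P[2]) - (Q[2] - P[2]) * (R[1] - P[1])
  if (abs(cross) < 1e-9) {
    stop("P, Q, R are collinear: they must define a triangle")
  }
  structure(list(P = P, Q = Q, R = R), class = "rodscule_state")
}

#' @export
print.rodscule_state <- function(x, ...) {
  g <- rod_geometry(x)
  cat(sprintf(
    "rodscule_state: M=(%.2f, %.2f) length=%.2f width=%.2f angle=%.3f rad\n",
    g$M[1], g$M[2], 2 * (g$half_length_inner + g$radius_inner),
    2 * g$radius_inner, g$theta
  ))
  invisible(x)
}

as_state_vector <- function(state) {
  c(state$P, state$Q, state$R)
}

state_from_vector <- function(v) {
  structure(list(P = v[1:2], Q = v[3:4], R = v[5:6]), class = "rodscule_state")
}

#' Derived rod geometry of a rodscule state
#'
#' Computes the outer ellipse through P, Q, R (center at the triangle
#' centroid, conjugate semi-diameters `u = P - M`, `v = (Q - R)/sqrt(3)`),
#' the outer and inner stadium shapes, extremal points and areas.
#'
#' @param state a [rodscule_state()].
#' @param min_aspect smallest admissible ratio of semi-minor to semi-major
#'   axis before the ellipse is considered degenerate.
#' @return a list with elements `M` (barycenter), `a`, `b` (semi-axes),
#'   `theta` (axis orientation, radians in (-pi/2, pi/2]), `axis` (unit
#'   vector), `C1`, `C2` (outer cap centers), `K1`, `K2` (inner cap
#'   centers), `radius_outer`, `radius_inner`, `half_length_outer`,
#'   `half_length_inner` (straight-segment half-lengths), `area_outer`,
#'   `area_inner`, and the extremal points `e_outer`, `e_inner` (4 x 2
#'   matrices).
#' @export
rod_geometry <- function(state, min_aspect = 0.02) {
  M <- (state$P + state$Q + state$R) / 3
  u <- state$P - M
  v <- (state$Q - state$R) / sqrt(3)
  S <- tcrossprod(u) + tcrossprod(v)
  e <- eigen(S, symmetric = TRUE)
  a <- sqrt(max(e$values[1], 0))
  b <- sqrt(max(e$values[2], 0))
  if (b <= 1e-9 || b / a < min_aspect) {
    stop("degenerate ellipse: the three points are nearly collinear")
  }
  axis <- e$vectors[, 1]
  theta <- normalize_orientation(atan2(axis[2], axis[1]))
  axis <- c(cos(theta), sin(theta))
  nvec <- c(-sin(theta), cos(theta))

  l_out <- a - b                       # straight-segment half-length, outer
  r_out <- b
  l_in <- l_out / sqrt(2)
  r_in <- r_out / sqrt(2)

  area_outer <- 4 * l_out * r_out + pi * r_out^2
  list(
    M = M, a = a, b = b, theta = theta, axis = axis, normal = nvec,
    C1 = M - l_out * axis, C2 = M + l_out * axis,
    K1 = M - l_in * axis, K2 = M + l_in * axis,
    radius_outer = r_out, radius_inner = r_in,
    half_length_outer = l_out, half_length_inner = l_in,
    area_outer = area_outer, area_inner = area_outer / 2,
    e_outer = rbind(M + a * axis, M - a * axis, M + b * nvec, M - b * nvec),
    e_inner = rbind(
      M + a / sqrt(2) * axis, M - a / sqrt(2) * axis,
      M + b / sqrt(2) * nvec, M - b / sqrt(2) * nvec
    )
  )
}

#' Build a rodscule whose inner rod has the given pose
#'
#' Inverse of the geometry derivation: given the inner rod (the shape that
#' is expected to match the cell), place P, Q, R accordingly.
#'
#' @param center numeric length-2 barycenter `c(x, y)`.
#' @param angle axis orientation in radians.
#' @param half_length straight-segment half-length of the inner rod (px).
#' @param radius inner rod radius (px); the cell half-width.
#' @return a [rodscule_state()].
#' @export
rodscule_from_rod <- function(center, angle, half_length, radius) {
  stopifnot(radius > 0, half_length >= 0)
  a <- sqrt(2) * (half_length + radius)
  b <- sqrt(2) * radius
  axis <- c(cos(angle), sin(angle))
  nvec <- c(-sin(angle), cos(angle))
  P <- center + a * axis
  Q <- center - a / 2 * axis + sqrt(3) / 2 * b * nvec
  R <- center - a / 2 * axis - sqrt(3) / 2 * b * nvec
  rodscule_state(P, Q, R)
}

#' Initialize a rodscule from a pair of spots
#'
#' The two spots (e.g. the spindle pole bodies) approximately define the
#' longitudinal axis of the cell; the inner rod axis is laid through them
#' and extended by `margin` at both ends so its cap centers sit `margin`
#' beyond the spots.
#'
#' @param spot_a,spot_b numeric length-2 spot positions `c(x, y)`.
#' @param width default cell width in px (twice the inner rod radius).
#' @param margin axial extension beyond each spot in px.
#' @return a [rodscule_state()].
#' @export
initialize_from_spots <- function(spot_a, spot_b, width = 12, margin = 8) {
  spot_a <- as.numeric(spot_a); spot_b <- as.numeric(spot_b)
  d <- spot_b - spot_a
  len <- sqrt(sum(d^2))
  if (len < 1e-9) stop("the two spots coincide")
  dir <- d / len
  k1 <- spot_a - margin * dir
  k2 <- spot_b + margin * dir
  center <- (k1 + k2) / 2
  rodscule_from_rod(
    center,
    atan2(dir[2], dir[1]),
    half_length = len / 2 + margin,
    radius = width / 2
  )
}

# Pixels, coverage weights and (mirror-extended) image values over the
# bounding box of the outer rod. Shared by rod_energy and measurements.
rod_support <- function(image, geom, pad = 1.5) {
  nr <- nrow(image); nc <- ncol(image)
  p <- geom$radius_outer + pad
  x0 <- floor(min(geom$C1[1], geom$C2[1]) - p)
  x1 <- ceiling(max(geom$C1[1], geom$C2[1]) + p)
  y0 <- floor(min(geom$C1[2], geom$C2[2]) - p)
  y1 <- ceiling(max(geom$C1[2], geom$C2[2]) + p)
  if (x1 < 1 || x0 > nc || y1 < 1 || y0 > nr) {
    stop("rod lies entirely outside the image")
  }
  xs <- x0:x1; ys <- y0:y1
  X <- rep(xs, times = length(ys))
  Y <- rep(ys, each = length(xs))
  w_out <- stadium_coverage(X, Y, geom$C1, geom$C2, geom$radius_outer)
  w_in <- stadium_coverage(X, Y, geom$K1, geom$K2, geom$radius_inner)
  f <- image[cbind(mirror_index(Y, nr), mirror_index(X, nc))]
  list(X = X, Y = Y, w_out = w_out, w_in = w_in, f = f)
}

#' Rodscule contrast energy
#'
#' The energy is the normalised contrast between the ring and the inner rod,
#' `E = (1/|Sigma|) * (int_{Sigma \ Sigma'} f  -  int_{Sigma'} f)`.
#' It is zero on constant images, negative when the inner rod is brighter
#' than the ring, and minimal when the inner rod coincides with a bright
#' cell on dark background. Integrals are discretised with a 1-px
#' anti-aliased coverage weight; the inner weights are renormalised so the
#' discrete inner area is exactly half the discrete outer area, which makes
#' the constant-image energy vanish identically. Pixels outside the image
#' take mirrored boundary values.
#'
#' @param image numeric matrix (rows = y, columns = x).
#' @param state a [rodscule_state()].
#' @return scalar energy in intensity units.
#' @export
rod_energy <- function(image, state) {
  geom <- rod_geometry(state)
  sup <- rod_support(image, geom)
  W_out <- sum(sup$w_out)
  W_in <- sum(sup$w_in)
  if (W_out <= 0 || W_in <= 0) stop("rod lies entirely outside the image")
  kappa <- W_out / (2 * W_in)
  (sum(sup$f * sup$w_out) - 2 * kappa * sum(sup$f * sup$w_in)) / W_out
}

#' Gradient of the contrast energy
#'
#' Central finite differences of [rod_energy()] with respect to the six
#' coordinates of P, Q, R. The anti-aliased discretisation makes the energy
#' piecewise smooth, so a 0.1-px step resolves the descent direction.
#'
#' @inheritParams rod_energy
#' @param step finite-difference step in px.
#' @return numeric length-6 gradient, ordered (Px, Py, Qx, Qy, Rx, Ry).
#' @export
energy_gradient <- function(image, state, step = 0.1) {
  v <- as_state_vector(state)
  vapply(seq_along(v), function(i) {
    vp <- v; vm <- v
    vp[i] <- v[i] + step
    vm[i] <- v[i] - step
    (rod_energy(image, state_from_vector(vp)) -
      rod_energy(image, state_from_vector(vm))) / (2 * step)
  }, numeric(1))
}

#' Fit a rodscule by conjugate-gradient energy minimisation
#'
#' Polak-Ribiere nonlinear conjugate gradient with backtracking line search
#' on the six snake coordinates. Iterations are monotone in energy;
#' termination on gradient norm, relative energy change, or iteration cap.
#' Non-convergence returns the best state found with `converged = FALSE`
#' rather than an error.
#'
#' @inheritParams rod_energy
#' @param init initial [rodscule_state()].
#' @param max_iter iteration cap.
#' @param grad_tol gradient-norm tolerance (intensity / px).
#' @param energy_tol relative energy-change tolerance.
#' @param fd_step finite-difference step for the gradient, px.
#' @return a list with `state`, `energy`, `energy_trace`, `iterations`,
#'   `converged`, and `status` (one of `"gradient"`, `"energy"`,
#'   `"line_search"`, `"max_iter"`).
#' @export
rodscule_optimize <- function(image, init, max_iter = 500, grad_tol = 1e-4,
                              energy_tol = 1e-9, fd_step = 0.1) {
  v <- as_state_vector(init)
  safe_energy <- function(v) {
    tryCatch(rod_energy(image, state_from_vector(v)), error = function(e) Inf)
  }
  E <- safe_energy(v)
  if (!is.finite(E)) stop("initial rodscule lies entirely outside the image")
  g <- energy_gradient(image, state_from_vector(v), step = fd_step)
  dir <- -g
  trace <- E
  step0 <- 1
  status <- "max_iter"
  for (it in seq_len(max_iter)) {
    gn <- sqrt(sum(g * g))
    if (gn < grad_tol) {
      status <- "gradient"
      break
    }
    # backtracking line search along dir
    t <- step0
    accepted <- FALSE
    for (ls in 1:30) {
      E2 <- safe_energy(v + t * dir)
      if (is.finite(E2) && E2 < E) {
        accepted <- TRUE
        break
      }
      t <- t / 2
    }
    if (!accepted) {
      if (isTRUE(all.equal(dir, -g))) {
        status <- "line_search"
        break
      }
      dir <- -g   # restart with steepest descent
      next
    }
    v <- v + t * dir
    step0 <- 2 * t
    E_old <- E
    E <- E2
    trace <- c(trace, E)
    g_new <- energy_gradient(image, state_from_vector(v), step = fd_step)
    beta <- max(0, sum(g_new * (g_new - g)) / sum(g * g))
    dir <- -g_new + beta * dir
    if (sum(dir * g_new) >= 0) dir <- -g_new
    g <- g_new
    if (abs(E_old - E) < energy_tol * (abs(E) + energy_tol)) {
      status <- "energy"
      break
    }
  }
  list(
    state = state_from_vector(v),
    energy = E,
    energy_trace = trace,
    iterations = length(trace) - 1,
    converged = status %in% c("gradient", "energy", "line_search"),
    status = status
  )
}

#' Point-in-rod test
#'
#' TRUE iff the point lies inside (or on the border of) the outer rod of the
#' state. Decomposes the stadium into its central rectangle and the two cap
#' discs.
#'
#' @param state a [rodscule_state()].
#' @param point numeric length-2 `c(x, y)`.
#' @export
rod_contains <- function(state, point) {
  g <- rod_geometry(state)
  rel <- as.numeric(point) - g$M
  ax <- sum(rel * g$axis)
  ay <- sum(rel * g$normal)
  l <- g$half_length_outer
  r <- g$radius_outer
  if (abs(ax) <= l && abs(ay) <= r) return(TRUE)
  (abs(ax) - l)^2 + ay^2 <= r^2 && abs(ax) > l
}

#' Average z-projection and contrast stretch
#'
#' Averages a z-stack along its third dimension (which suppresses
#' uncorrelated noise by sqrt(n)), then linearly stretches intensities
#' between the `probs` percentiles.
#'
#' @param stack a 2D matrix or a 3D array (y, x, z).
#' @param probs lower/upper percentiles for the linear stretch.
#' @param stretch set `FALSE` to skip contrast enhancement.
#' @return numeric matrix.
#' @export
preprocess_stack <- function(stack, probs = c(0.003, 0.997), stretch = TRUE) {
  if (is.matrix(stack)) {
    proj <- stack
  } else if (length(dim(stack)) == 3) {
    if (dim(stack)[3] < 1) stop("empty stack")
    proj <- apply(stack, c(1, 2), mean)
  } else {
    stop("expected a matrix or a 3D array")
  }
  if (!stretch) return(proj)
  q <- stats::quantile(proj, probs, names = FALSE)
  if (q[2] - q[1] < 1e-12) return(proj)   # constant image: nothing to stretch
  lo <- min(proj); hi <- max(proj)
  out <- (pmin(pmax(proj, q[1]), q[2]) - q[1]) / (q[2] - q[1]) * (hi - lo) + lo
  matrix(out, nrow(proj), ncol(proj))
}

# Energy scale of pure-background windows: median |E| of the init-shaped rod
# placed on a deterministic grid across the image. Used to flag
# non-informative (background-only) convergences.
background_energy_scale <- function(image, template_state, n_grid = 3) {
  g <- rod_geometry(template_state)
  nr <- nrow(image); nc <- ncol(image)
  span <- g$half_length_outer + g$radius_outer + 1
  xs <- seq(1 + span, nc - span, length.out = n_grid)
  ys <- seq(1 + span, nr - span, length.out = n_grid)
  if (any(!is.finite(xs)) || xs[1] > xs[n_grid] || ys[1] > ys[n_grid]) {
    return(NA_real_)
  }
  es <- c()
  for (x in xs) for (y in ys) {
    st <- rodscule_from_rod(c(x, y), g$theta, g$half_length_inner,
                            g$radius_inner)
    e <- tryCatch(rod_energy(image, st), error = function(e) NA_real_)
    es <- c(es, e)
  }
  stats::median(abs(es), na.rm = TRUE)
}

#' Segment several cells independently
#'
#' Runs [rodscule_optimize()] once per initialization. A result is flagged
#' `failed` when the geometry leaves the image or when the converged energy
#' magnitude is indistinguishable from pure-background energies (less than
#' `energy_factor` times the median background energy scale).
#'
#' @inheritParams rod_energy
#' @param initializations list of [rodscule_state()] objects.
#' @param energy_factor multiple of the background energy scale below which
#'   a fit is considered non-informative.
#' @param ... passed to [rodscule_optimize()].
#' @return a list, one element per initialization, each with `state`,
#'   `measurements` (or NULL on failure), `energy`, `converged`, `failed`,
#'   `status`.
#' @export
segment_cells <- function(image, initializations, energy_factor = 3, ...) {
  stopifnot(length(initializations) >= 1)
  e_bg <- background_energy_scale(image, initializations[[1]])
  lapply(initializations, function(init) {
    fit <- tryCatch(rodscule_optimize(image, init, ...), error = function(e) NULL)
    if (is.null(fit)) {
      return(list(state = init, measurements = NULL, energy = NA_real_,
                  converged = FALSE, failed = TRUE, status = "error"))
    }
    g <- tryCatch(rod_geometry(fit$state), error = function(e) NULL)
    out_of_image <- is.null(g) ||
      any(g$M < 1) || g$M[1] > ncol(image) || g$M[2] > nrow(image)
    low_contrast <- is.finite(e_bg) && abs(fit$energy) < energy_factor * e_bg
    failed <- out_of_image || low_contrast
    list(
      state = fit$state,
      measurements = if (failed) NULL else cell_measurements(fit$state, image,
                                                             energy = fit$energy),
      energy = fit$energy,
      converged = fit$converged,
      failed = failed,
      status = if (out_of_image) "out_of_image"
               else if (low_contrast) "low_contrast" else fit$status
    )
  })
}

#' Per-cell measurements from a fitted rodscule
#'
#' Length and width refer to the inner rod, the shape that matches the cell
#' at the energy optimum: length is tip-to-tip along the axis, width twice
#' the inner radius. Background fluorescence is the median intensity of the
#' inner-rod interior with `spot_mask_radius` neighborhoods around the given
#' spots excluded.
#'
#' @param state a fitted [rodscule_state()].
#' @param image numeric matrix.
#' @param spots optional n x 2 matrix of spot positions `(x, y)` to mask.
#' @param spot_mask_radius exclusion radius around each spot, px.
#' @param energy optional converged energy to carry through.
#' @return a list of class `cell_measurements`.
#' @export
cell_measurements <- function(state, image, spots = NULL,
                              spot_mask_radius = 4, energy = NA_real_) {
  g <- rod_geometry(state)
  len <- 2 * (g$half_length_inner + g$radius_inner)
  wid <- 2 * g$radius_inner
  ext1 <- g$M - (g$half_length_inner + g$radius_inner) * g$axis
  ext2 <- g$M + (g$half_length_inner + g$radius_inner) * g$axis
  sup <- rod_support(image, g)
  inside <- sup$w_in > 0.5
  keep <- inside
  if (!is.null(spots) && nrow(spots) > 0) {
    for (i in seq_len(nrow(spots))) {
      keep <- keep & ((sup$X - spots[i, 1])^2 + (sup$Y - spots[i, 2])^2 >
                        spot_mask_radius^2)
    }
  }
  bg <- if (any(keep)) stats::median(sup$f[keep]) else NA_real_
  structure(list(
    length = len,
    width = wid,
    orientation = g$theta,
    extremities = rbind(ext1, ext2),
    barycenter = g$M,
    background_fluorescence = bg,
    energy = energy
  ), class = "cell_measurements")
}

#' @export
print.cell_measurements <- function(x, ...) {
  cat(sprintf(
    "cell: length %.2f px, width %.2f px, angle %.3f rad, background %.1f\n",
    x$length, x$width, x$orientation, x$background_fluorescence
  ))
  invisible(x)
}

#' Sample points on the inner-rod boundary
#'
#' Equally spaced (in arc length) points on the boundary of the inner rod;
#' used for boundary-distance metrics against ground truth.
#'
#' @param state a [rodscule_state()].
#' @param n number of points.
#' @return n x 2 matrix of `(x, y)` coordinates.
#' @export
rod_boundary_points <- function(state, n = 200) {
  g <- rod_geometry(state)
  d <- g$axis; nv <- g$normal
  l <- g$half_length_inner; r <- g$radius_inner
  per_seg <- 2 * l
  per_cap <- pi * r
  per <- 2 * per_seg + 2 * per_cap
  s <- seq(0, per, length.out = n + 1)[seq_len(n)]
  t(vapply(s, function(si) {
    if (si < per_seg) {
      g$K1 + si * d + r * nv
    } else if (si < per_seg + per_cap) {
      a <- (si - per_seg) / r
      g$K2 + r * (cos(a) * nv + sin(a) * d)
    } else if (si < 2 * per_seg + per_cap) {
      g$K2 - (si - per_seg - per_cap) * d - r * nv
    } else {
      a <- (si - 2 * per_seg - per_cap) / r
      g$K1 - r * (cos(a) * nv + sin(a) * d)
    }
  }, numeric(2)))
}
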