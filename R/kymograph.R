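# Kymographs: time-versus-position matrices of tracked spot motion.
# Two kinds: "cell_frame" plots each spot at its signed projection onto the
# cell's axis (origin at the barycenter), "relative" places the two spots
# symmetrically about the midline at plus/minus half their separation, so
# brightness asymmetry is visible while positions stay mirror symmetric.

#' Signed axial coordinate of a point in a cell
#'
#' Orthogonal projection of the point onto the rod axis through the
#' barycenter M; the positive direction points from cap C1 towards C2 (as
#' oriented at segmentation time, stable across frames).
#'
#' @param point numeric length-2 `c(x, y)`.
#' @param cell a [rodscule_state()] or its [rod_geometry()].
#' @return scalar signed coordinate in px; attribute `outside` is TRUE when
#'   the point lies outside the outer rod (it is still projected).
#' @export
project_on_axis <- function(point, cell) {
  g <- if (inherits(cell, "rodscule_state")) rod_geometry(cell) else cell
  s <- sum((as.numeric(point) - g$M) * g$axis)
  out <- point_segment_distance(point[1], point[2], g$C1, g$C2) >
    g$radius_outer
  structure(s, outside = out)
}

new_kymograph <- function(mat, kind, columns, meta = list()) {
  structure(list(matrix = mat, kind = kind, columns = columns, meta = meta),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("kymograph (%s): %d frames x %d columns\n",
              x$kind, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

# render one spot amplitude at a (fractional) column, optionally with a
# 1-px Gaussian smear for display
render_row <- function(row, col, amp, smear) {
  n <- length(row)
  if (smear > 0) {
    cols <- seq_len(n)
    row <- row + amp * exp(-(cols - col)^2 / (2 * smear^2))
  } else {
    c0 <- round(col)
    if (c0 >= 1 && c0 <= n) row[c0] <- row[c0] + amp
  }
  row
}

#' Cell-frame kymograph
#'
#' One row per frame; each track's spot is rendered at its axial coordinate
#' (column offset from the matrix midline = projection onto the cell axis)
#' with its fitted amplitude. Background is zero.
#'
#' @param tracks list of `track` objects whose `positions` carry `x`, `y`
#'   and (optionally) `A`; amplitude defaults to `intensity`.
#' @param cell a [rodscule_state()].
#' @param smear Gaussian display smear in px; 0 gives the raw single-column
#'   rendering used for numeric checks.
#' @return a `kymograph` object; `columns` gives each column's axial
#'   coordinate in px (0 at the barycenter).
#' @export
kymo_cell_frame <- function(tracks, cell, smear = 0) {
  stopifnot(length(tracks) >= 1)
  g <- rod_geometry(cell)
  half <- ceiling(g$half_length_outer + g$radius_outer)
  cols <- -half:half
  n_frames <- max(vapply(tracks, function(tr) nrow(tr$positions),
                         integer(1)))
  mat <- matrix(0, n_frames, length(cols))
  for (tr in tracks) {
    amps <- tr$positions$A %||% tr$positions$intensity
    for (t in seq_len(nrow(tr$positions))) {
      s <- project_on_axis(c(tr$positions$x[t], tr$positions$y[t]), g)
      a <- amps[t]
      if (!is.na(tr$f_t0) && t > tr$f_t0) a <- 0
      mat[t, ] <- render_row(mat[t, ], as.numeric(s) + half + 1, a, smear)
    }
  }
  new_kymograph(mat, "cell_frame", cols,
                meta = list(barycenter = g$M, theta = g$theta))
}

#' Relative (spot-to-spot) kymograph
#'
#' Per frame, the two spots are placed symmetrically about the midline at
#' plus/minus half their Euclidean separation, carrying their fitted
#' amplitudes; frames past a track's loss frame render with amplitude 0 on
#' that side. Invariant under rigid motion of the cell.
#'
#' @param track_a,track_b `track` objects over a shared frame range.
#' @param smear display smear as in [kymo_cell_frame()].
#' @return a `kymograph` object; `columns` in px, 0 at the midline.
#' @export
kymo_relative <- function(track_a, track_b, smear = 0) {
  n <- min(nrow(track_a$positions), nrow(track_b$positions))
  pa <- track_a$positions[seq_len(n), ]
  pb <- track_b$positions[seq_len(n), ]
  d <- sqrt((pa$x - pb$x)^2 + (pa$y - pb$y)^2)
  half <- ceiling(max(d) / 2) + 2
  cols <- -half:half
  mat <- matrix(0, n, length(cols))
  aa <- pa$A %||% pa$intensity
  ab <- pb$A %||% pb$intensity
  for (t in seq_len(n)) {
    va <- if (!is.na(track_a$f_t0) && t > track_a$f_t0) 0 else aa[t]
    vb <- if (!is.na(track_b$f_t0) && t > track_b$f_t0) 0 else ab[t]
    mat[t, ] <- render_row(mat[t, ], -d[t] / 2 + half + 1, va, smear)
    mat[t, ] <- render_row(mat[t, ], d[t] / 2 + half + 1, vb, smear)
  }
  new_kymograph(mat, "relative", cols, meta = list(separation = d))
}

#' Write a kymograph to disk
#'
#' Saves the matrix both as a 32-bit float TIFF and as a tab-delimited text
#' matrix.
#'
#' @param kymo a `kymograph`.
#' @param path_tiff,path_txt output paths (either may be NULL to skip).
#' @export
write_kymograph <- function(kymo, path_tiff = NULL, path_txt = NULL) {
  if (!is.null(path_tiff)) {
    m <- kymo$matrix
    top <- max(m, 1e-12)
    tiff::writeTIFF(m / top, path_tiff, bits.per.sample = 32)
  }
  if (!is.null(path_txt)) {
    utils::write.table(kymo$matrix, path_txt, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(kymo)
}
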