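# End-to-end pipeline: detection -> segmentation -> tracking -> measurement
# -> kymographs. Static (single time point) inputs stop after segmentation
# and spot quantification; dynamic inputs additionally produce tracks,
# loss frames and kymographs.

# pair detections into cells: mutual nearest neighbours within a separation
# window (the two poles of one spindle are closer to each other than to any
# spot of another cell)
pair_spots <- function(det, min_sep = 6, max_sep = 60) {
  n <- nrow(det)
  if (n < 2) return(list())
  dmat <- as.matrix(stats::dist(cbind(det$x, det$y)))
  diag(dmat) <- Inf
  dmat[dmat < min_sep | dmat > max_sep] <- Inf
  nn <- apply(dmat, 1, which.min)
  pairs <- list()
  used <- rep(FALSE, n)
  for (i in seq_len(n)) {
    j <- nn[i]
    if (!used[i] && !used[j] && is.finite(dmat[i, j]) && nn[j] == i &&
        i < j) {
      used[i] <- used[j] <- TRUE
      pairs[[length(pairs) + 1]] <- c(i, j)
    }
  }
  pairs
}

#' Run the full analysis pipeline
#'
#' Input may be a single frame (matrix), a list of channels each holding a
#' list of frames, or a TIFF path (read with [read_stack()]). With a single
#' time point the pipeline performs spot detection, cell segmentation and
#' quantification only; with a time-lapse it additionally tracks the two
#' spots per cell per channel, estimates loss frames and builds both
#' kymographs. Deterministic for fixed input and configuration.
#'
#' @param input matrix, list of channels (each a list of frames), or path.
#' @param config a [pipeline_config()].
#' @param write set FALSE to skip writing files to `config$out_dir`.
#' @return list with `cells` (data frame of per-cell measurements), `spots`
#'   (data frame of per-spot fits, per frame when dynamic), `tracks`,
#'   `kymographs` (NULL for static input), and `static` flag.
#' @export
run_pipeline <- function(input, config = pipeline_config(), write = TRUE) {
  if (is.character(input)) input <- read_stack(input)
  if (is.matrix(input)) input <- list(list(input))
  if (is.matrix(input[[1]])) input <- list(input)   # one channel
  ref <- input[[1]]
  static <- length(ref) == 1
  frame1 <- ref[[1]]

  # detection on the (preprocessed) reference frame
  resp <- log_filter(frame1, config$log_sigma)
  det <- detect_spots(resp, n_max = 64, min_separation = 5,
                      threshold = stats::quantile(resp, 0.999))
  pairs <- pair_spots(det)
  inits <- lapply(pairs, function(pr) {
    initialize_from_spots(c(det$x[pr[1]], det$y[pr[1]]),
                          c(det$x[pr[2]], det$y[pr[2]]),
                          width = config$cell_width,
                          margin = config$cell_margin)
  })
  if (length(inits) == 0) {
    return(list(cells = data.frame(), spots = data.frame(),
                tracks = NULL, kymographs = NULL, static = static))
  }
  seg <- segment_cells(frame1, inits)
  ok <- !vapply(seg, `[[`, logical(1), "failed")

  cell_rows <- list()
  spot_rows <- list()
  tracks_out <- list()
  kymos_out <- list()
  sigma0 <- config$diffraction_limit / config$pixel_size

  cells_ok <- which(ok)
  for (ci in cells_ok) {
    st <- seg[[ci]]$state
    pr <- pairs[[ci]]
    spots_xy <- rbind(c(det$x[pr[1]], det$y[pr[1]]),
                      c(det$x[pr[2]], det$y[pr[2]]))
    meas <- cell_measurements(st, frame1, spots = spots_xy)
    cell_rows[[length(cell_rows) + 1]] <- data.frame(
      cell = ci,
      Px = st$P[1], Py = st$P[2], Qx = st$Q[1], Qy = st$Q[2],
      Rx = st$R[1], Ry = st$R[2],
      length_px = meas$length, width_px = meas$width,
      length_um = meas$length * config$pixel_size,
      width_um = meas$width * config$pixel_size,
      orientation_deg = meas$orientation * 180 / pi,
      ext1x = meas$extremities[1, 1], ext1y = meas$extremities[1, 2],
      ext2x = meas$extremities[2, 1], ext2y = meas$extremities[2, 2],
      mx = meas$barycenter[1], my = meas$barycenter[2],
      background = meas$background_fluorescence,
      energy = seg[[ci]]$energy,
      status = seg[[ci]]$status
    )

    if (static) {
      for (ch in seq_along(input)) {
        img <- input[[ch]][[1]]
        for (s in 1:2) {
          fit <- fit_spot_gaussian(img, spots_xy[s, ],
                                   window = config$fit_window,
                                   init_sigma = sigma0)
          spot_rows[[length(spot_rows) + 1]] <- data.frame(
            frame = 1, channel = ch, cell = ci, spot = s,
            x = fit$mu[1], y = fit$mu[2], A = fit$A, B = fit$B,
            sigma_x = fit$sigma[1], sigma_y = fit$sigma[2],
            theta = fit$theta, residual = fit$residual_rms,
            method = "gaussfit"
          )
        }
      }
    } else {
      trk <- track_two_spots(input, list(st),
                             log_sigma = config$log_sigma,
                             max_displacement = config$max_displacement,
                             weights = config$weights,
                             fit_window = config$fit_window)[[1]]
      if (isTRUE(trk$skipped)) next
      noise_sd <- estimate_noise_mad(frame1)
      cell_bg <- meas$background_fluorescence
      for (ch in seq_along(trk$tracks)) {
        for (s in 1:2) {
          tr <- trk$tracks[[ch]][[s]]
          # peak height above the cell's background fluorescence: robust to
          # fits whose own offset strays when the window touches the edge
          amps <- tr$positions$A + tr$positions$B - cell_bg
          f0 <- detect_loss_frame(amps[!is.na(amps)], noise_std = noise_sd,
                                  k = config$loss_k)
          tr$f_t0 <- as.integer(f0)
          trk$tracks[[ch]][[s]] <- tr
          G <- tr$cost
          spot_rows[[length(spot_rows) + 1]] <- data.frame(
            frame = tr$positions$frame, channel = ch, cell = ci, spot = s,
            x = tr$positions$x, y = tr$positions$y,
            A = tr$positions$A, B = tr$positions$B,
            sigma_x = NA_real_, sigma_y = NA_real_, theta = NA_real_,
            residual = NA_real_, method = "gaussfit"
          )
        }
      }
      tracks_out[[as.character(ci)]] <- trk$tracks
      kc <- kymo_cell_frame(trk$tracks[[1]], st)
      kr <- kymo_relative(trk$tracks[[1]][[1]], trk$tracks[[1]][[2]])
      kymos_out[[as.character(ci)]] <- list(cell_frame = kc, relative = kr)
      if (write) {
        dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
        write_kymograph(kc,
          path_txt = file.path(config$out_dir,
                               sprintf("kymo_cell_%d_cellframe.txt", ci)))
        write_kymograph(kr,
          path_txt = file.path(config$out_dir,
                               sprintf("kymo_cell_%d_relative.txt", ci)))
      }
    }
  }

  cells_df <- if (length(cell_rows)) do.call(rbind, cell_rows)
              else data.frame()
  spots_df <- if (length(spot_rows)) do.call(rbind, spot_rows)
              else data.frame()
  if (nrow(spots_df) > 0) {
    # inter-spot distance per cell/channel/frame
    spots_df$inter_spot_dist <- NA_real_
    for (ci in unique(spots_df$cell)) {
      for (ch in unique(spots_df$channel)) {
        for (fr in unique(spots_df$frame)) {
          sel <- spots_df$cell == ci & spots_df$channel == ch &
            spots_df$frame == fr
          if (sum(sel) == 2) {
            xy <- spots_df[sel, c("x", "y")]
            spots_df$inter_spot_dist[sel] <-
              sqrt(diff(xy$x)^2 + diff(xy$y)^2)
          }
        }
      }
    }
  }
  if (write) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_results(cells_df, file.path(config$out_dir, "cells.txt"))
    write_results(spots_df, file.path(config$out_dir, "spots.txt"))
  }
  list(cells = cells_df, spots = spots_df,
       tracks = if (static) NULL else tracks_out,
       kymographs = if (static) NULL else kymos_out,
       static = static)
}
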