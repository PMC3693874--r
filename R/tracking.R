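# Spot tracking by dynamic programming on an acyclic weighted graph.
#
# Vertices are per-frame spot candidates; edges connect candidates in
# consecutive frames whose displacement is within the declared bound
# (causality: edges only run forward in time). The cost of the optimal path
# to a vertex follows the Bellman recursion
#   G(x) = 0 at the source, otherwise min_j { G(j) + C(j, x) },
# and the overall track is the minimum-cost path to any last-frame vertex.
# The edge cost is a weighted sum C(i,j) = sum_q lambda_q f_q(i,j) of
# bounded terms: normalised intensity, intensity variation, migration
# distance, directional persistence, and a large penalty for leaving the
# segmented cell. The directional term depends on the previous step, so the
# DP state is the (predecessor, current) vertex pair - an exact polynomial
# reformulation.
#
# For very low PSNR a dense variant (track_dense) runs the same recursion
# over every pixel of the LoG response, which accumulates filter evidence
# across frames instead of committing to sparse per-frame detections.

#' Default tracking cost weights
#'
#' All terms except the outside-cell penalty are bounded in [0, 1]; the
#' outside-cell weight is deliberately large so that leaving the cell is
#' heavily penalised without being strictly forbidden.
#'
#' @param intensity,intensity_variation,distance,direction,outside_cell
#'   non-negative weights.
#' @return named numeric vector of class `cost_weights`.
#' @export
cost_weights <- function(intensity = 1, intensity_variation = 0.5,
                         distance = 0.5, direction = 0.25,
                         outside_cell = 10) {
  w <- c(intensity = intensity, intensity_variation = intensity_variation,
         distance = distance, direction = direction,
         outside_cell = outside_cell)
  if (any(w < 0)) stop("weights must be non-negative")
  if (all(w == 0)) stop("at least one weight must be positive")
  structure(w, class = "cost_weights")
}

#' Build the spot-candidate track graph
#'
#' @param candidates list (one element per frame, in order) of data frames
#'   with columns `x`, `y` and `intensity`.
#' @param max_displacement per-frame displacement bound, px; candidate
#'   pairs farther apart get no edge at all.
#' @return a list of class `track_graph` with `vertices` (data frame:
#'   frame, idx, x, y, intensity, intensity_norm) and `edges` (data frame:
#'   from, to, dist). Intensities are normalised to the sequence's robust
#'   maximum (0.99 quantile), clipped at 1.
#' @export
build_track_graph <- function(candidates, max_displacement) {
  stopifnot(length(candidates) >= 2)
  if (nrow(candidates[[1]]) < 1) stop("frame 1 has no candidates (no source)")
  n_per <- vapply(candidates, nrow, integer(1))
  offs <- cumsum(c(0, n_per[-length(n_per)]))
  vertices <- do.call(rbind, lapply(seq_along(candidates), function(t) {
    d <- candidates[[t]]
    if (nrow(d) == 0) {
      return(data.frame(frame = integer(0), idx = integer(0),
                        x = numeric(0), y = numeric(0),
                        intensity = numeric(0)))
    }
    data.frame(frame = t, idx = as.integer(offs[t]) + seq_len(nrow(d)),
               x = d$x, y = d$y, intensity = d$intensity)
  }))
  amax <- stats::quantile(vertices$intensity, 0.99, names = FALSE)
  if (!is.finite(amax) || amax <= 0) amax <- max(vertices$intensity, 1)
  vertices$intensity_norm <- pmin(vertices$intensity / amax, 1)
  edges <- list()
  for (t in seq_len(length(candidates) - 1)) {
    a <- vertices[vertices$frame == t, ]
    b <- vertices[vertices$frame == t + 1, ]
    if (nrow(a) == 0 || nrow(b) == 0) next
    dmat <- outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2
    hit <- which(dmat <= max_displacement^2, arr.ind = TRUE)
    if (nrow(hit) == 0) next
    edges[[t]] <- data.frame(
      from = a$idx[hit[, 1]], to = b$idx[hit[, 2]],
      dist = sqrt(dmat[hit])
    )
  }
  structure(list(
    vertices = vertices,
    edges = if (length(edges)) do.call(rbind, edges)
            else data.frame(from = integer(0), to = integer(0),
                            dist = numeric(0)),
    n_frames = length(candidates),
    max_displacement = max_displacement
  ), class = "track_graph")
}

#' Edge cost between two candidates
#'
#' `C(i, j) = sum_q lambda_q f_q(i, j)` with
#' `f_int = 1 - I_hat_j`, `f_var = |I_hat_j - I_hat_i|`,
#' `f_dist = d(i, j) / max_displacement`,
#' `f_dir = (1 - cos phi)/2` (phi = turn angle given the predecessor's
#' position; 0 for the first step), and `f_out = 1` if `v_j` lies outside
#' the cell.
#'
#' @param v_i,v_j single-row slices of a `track_graph$vertices` data frame
#'   (needing `x`, `y`, `intensity_norm`).
#' @param weights a [cost_weights()] vector.
#' @param max_displacement normalisation for the distance term, px.
#' @param cell optional [rodscule_state()]; `v_j` outside its rod incurs the
#'   outside-cell penalty.
#' @param prev optional numeric length-2 position of the predecessor of
#'   `v_i`, enabling the directional term.
#' @return non-negative scalar cost.
#' @export
edge_cost <- function(v_i, v_j, weights, max_displacement,
                      cell = NULL, prev = NULL) {
  d <- sqrt((v_j$x - v_i$x)^2 + (v_j$y - v_i$y)^2)
  f <- weights[["intensity"]] * (1 - v_j$intensity_norm) +
    weights[["intensity_variation"]] *
      abs(v_j$intensity_norm - v_i$intensity_norm) +
    weights[["distance"]] * d / max_displacement
  if (!is.null(prev)) {
    u <- c(v_i$x - prev[1], v_i$y - prev[2])
    v <- c(v_j$x - v_i$x, v_j$y - v_i$y)
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu > 1e-9 && nv > 1e-9) {
      f <- f + weights[["direction"]] * (1 - sum(u * v) / (nu * nv)) / 2
    }
  }
  if (!is.null(cell) && !rod_contains(cell, c(v_j$x, v_j$y))) {
    f <- f + weights[["outside_cell"]]
  }
  unname(f)
}

# edge lookup: list mapping frame t -> adjacency of vertex-index pairs
edge_lookup <- function(graph) {
  el <- vector("list", graph$n_frames)
  v <- graph$vertices
  for (t in 2:graph$n_frames) {
    to_t <- v$idx[v$frame == t]
    el[[t]] <- graph$edges[graph$edges$to %in% to_t, , drop = FALSE]
  }
  el
}

#' Globally optimal track by dynamic programming
#'
#' Forward Bellman recursion over (predecessor, current) vertex pairs (the
#' directional term is path dependent), terminal selection over last-frame
#' candidates, backpointer reconstruction. Ties (within 1e-9) resolve to the
#' lowest predecessor index, identically to [brute_force_path()]. If no
#' last-frame vertex is reachable the track is truncated at the last
#' reachable frame and flagged.
#'
#' @param graph a [build_track_graph()] result.
#' @param weights a [cost_weights()] vector.
#' @param cell optional [rodscule_state()] for the outside-cell term.
#' @param source vertex index (in frame 1) used as the track source.
#' @return a list of class `track`: `path` (vertex indices, one per frame),
#'   `positions` (data frame frame/x/y/intensity), `cost`, `truncated`,
#'   `f_t0` (NA until [detect_loss_frame()] fills it).
#' @export
dp_optimal_path <- function(graph, weights = cost_weights(), cell = NULL,
                            source = NULL) {
  v <- graph$vertices
  TT <- graph$n_frames
  eps <- 1e-9
  src <- if (is.null(source)) v$idx[v$frame == 1][1] else source
  stopifnot(v$frame[v$idx == src] == 1)
  # H[[t]]: named list keyed "i|j" -> cost of best path ending with edge
  # i -> j (frame(j) = t); BP: the best predecessor k of i.
  H <- vector("list", TT)
  BP <- vector("list", TT)
  e2 <- graph$edges[graph$edges$from == src, , drop = FALSE]
  e2 <- e2[v$frame[e2$to] == 2, , drop = FALSE]
  H[[2]] <- list(); BP[[2]] <- list()
  for (r in seq_len(nrow(e2))) {
    j <- e2$to[r]
    key <- paste(src, j, sep = "|")
    H[[2]][[key]] <- edge_cost(v[src, ], v[j, ], weights,
                               graph$max_displacement, cell, prev = NULL)
    BP[[2]][[key]] <- NA_integer_
  }
  if (TT >= 3) {
    for (t in 3:TT) {
      H[[t]] <- list(); BP[[t]] <- list()
      et <- graph$edges[v$frame[graph$edges$to] == t, , drop = FALSE]
      for (r in seq_len(nrow(et))) {
        i <- et$from[r]; j <- et$to[r]
        # predecessors k with a state (k, i) at frame t-1
        prev_keys <- names(H[[t - 1]])
        prev_keys <- prev_keys[endsWith(prev_keys, paste0("|", i))]
        if (length(prev_keys) == 0) next
        best <- Inf; best_k <- NA_integer_
        ks <- as.integer(sub("\\|.*", "", prev_keys))
        ord <- order(ks)
        for (m in ord) {
          k <- ks[m]
          cc <- edge_cost(v[i, ], v[j, ], weights, graph$max_displacement,
                          cell, prev = c(v$x[k], v$y[k]))
          val <- H[[t - 1]][[prev_keys[m]]] + cc
          if (val < best - eps) {
            best <- val; best_k <- k
          }
        }
        key <- paste(i, j, sep = "|")
        H[[t]][[key]] <- best
        BP[[t]][[key]] <- best_k
      }
    }
  }
  # terminal selection: deepest frame with reachable states
  t_end <- TT
  while (t_end >= 2 && length(H[[t_end]]) == 0) t_end <- t_end - 1
  if (t_end < 2) {
    pos <- v[v$idx == src, c("frame", "x", "y", "intensity")]
    return(structure(list(path = src, positions = pos, cost = 0,
                          truncated = TRUE, f_t0 = NA_integer_),
                     class = "track"))
  }
  keys <- names(H[[t_end]])
  costs <- unlist(H[[t_end]])
  ij <- do.call(rbind, strsplit(keys, "\\|"))
  ii <- as.integer(ij[, 1]); jj <- as.integer(ij[, 2])
  cand <- which(costs <= min(costs) + eps)
  cand <- cand[order(jj[cand], ii[cand])]   # smallest terminal, then pred
  pick <- cand[1]
  path <- integer(t_end)
  path[t_end] <- jj[pick]
  path[t_end - 1] <- ii[pick]
  G <- costs[pick]
  if (t_end >= 3) {
    for (t in t_end:3) {
      key <- paste(path[t - 1], path[t], sep = "|")
      path[t - 2] <- BP[[t]][[key]]
    }
  }
  path <- as.integer(path)
  pos <- v[match(path, v$idx), c("frame", "x", "y", "intensity")]
  rownames(pos) <- NULL
  structure(list(path = path, positions = pos, cost = unname(G),
                 truncated = t_end < TT, f_t0 = NA_integer_),
            class = "track")
}

#' @export
print.track <- function(x, ...) {
  cat(sprintf("track: %d frames, cost %.4f%s%s\n",
              nrow(x$positions), x$cost,
              if (x$truncated) ", truncated" else "",
              if (!is.na(x$f_t0)) sprintf(", lost at frame %d", x$f_t0)
              else ""))
  invisible(x)
}

#' Exhaustive-path oracle
#'
#' Enumerates every source-to-last-frame path and returns the minimum-cost
#' one, with the same tie rule as [dp_optimal_path()] (ties within 1e-9
#' resolve to the reverse-lexicographically smallest vertex sequence).
#' Intended as a test oracle; errors beyond 1e6 paths.
#'
#' @inheritParams dp_optimal_path
#' @param max_paths safety cap on the number of enumerated paths.
#' @return a `track` (same structure as [dp_optimal_path()]).
#' @export
brute_force_path <- function(graph, weights = cost_weights(), cell = NULL,
                             source = NULL, max_paths = 1e6) {
  v <- graph$vertices
  TT <- graph$n_frames
  eps <- 1e-9
  src <- if (is.null(source)) v$idx[v$frame == 1][1] else source
  succ <- split(graph$edges$to, graph$edges$from)
  # count paths first
  count_from <- function(i, t) {
    if (t == TT) return(1)
    s <- succ[[as.character(i)]]
    s <- s[v$frame[s] == t + 1]
    if (length(s) == 0) return(0)
    sum(vapply(s, count_from, numeric(1), t = t + 1))
  }
  if (count_from(src, 1) > max_paths) stop("too many paths to enumerate")
  best_cost <- Inf
  best_path <- NULL
  best_depth <- 1
  rec <- function(path, cost) {
    t <- length(path)
    i <- path[t]
    if (t == TT) {
      take <- FALSE
      if (cost < best_cost - eps) {
        take <- TRUE
      } else if (cost <= best_cost + eps && !is.null(best_path) &&
                 length(best_path) == TT) {
        # reverse-lexicographic comparison
        for (m in TT:1) {
          if (path[m] < best_path[m]) { take <- TRUE; break }
          if (path[m] > best_path[m]) break
        }
      }
      if (take) {
        best_cost <<- min(best_cost, cost)
        best_path <<- path
      }
      return(invisible())
    }
    if (t > best_depth && best_cost == Inf) {
      best_depth <<- t
      best_path <<- path      # deepest reachable prefix (truncated case)
    }
    s <- succ[[as.character(i)]]
    s <- s[v$frame[s] == t + 1]
    for (j in sort(s)) {
      prev <- if (t >= 2) c(v$x[path[t - 1]], v$y[path[t - 1]]) else NULL
      cc <- edge_cost(v[i, ], v[j, ], weights, graph$max_displacement,
                      cell, prev = prev)
      rec(c(path, j), cost + cc)
    }
  }
  rec(src, 0)
  truncated <- is.infinite(best_cost)
  if (truncated && is.null(best_path)) best_path <- src
  best_path <- as.integer(best_path)
  pos <- v[match(best_path, v$idx), c("frame", "x", "y", "intensity")]
  rownames(pos) <- NULL
  structure(list(path = best_path, positions = pos,
                 cost = if (truncated) NA_real_ else unname(best_cost),
                 truncated = truncated, f_t0 = NA_integer_),
            class = "track")
}

shift_matrix <- function(m, dy, dx, fill = Inf) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ys <- max(1, 1 + dy):min(nr, nr + dy)
  xs <- max(1, 1 + dx):min(nc, nc + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

#' Dense dynamic-programming tracker for very low PSNR
#'
#' Runs the Bellman recursion over every pixel of the per-frame LoG
#' responses: each pixel of each frame is a vertex with cost
#' `lambda_int * (1 - R_hat)` (response normalised to the sequence's 0.999
#' quantile), transitions are allowed within `max_displacement` with cost
#' `lambda_dist * d / max_displacement`, and pixels outside the optional
#' cell mask pay the outside-cell penalty. Because no per-frame detection
#' commits early, filter evidence accumulates over time, which keeps the
#' tracker reliable down to 0 dB PSNR.
#'
#' @param responses list of response matrices (one per frame), e.g. from
#'   [log_filter()].
#' @param max_displacement per-frame displacement bound, px.
#' @param weights a [cost_weights()] vector (intensity, distance and
#'   outside-cell terms are used).
#' @param mask optional logical matrix marking the admissible (cell) region.
#' @return a `track` with one (integer-pixel) position per frame.
#' @export
track_dense <- function(responses, max_displacement = 4,
                        weights = cost_weights(), mask = NULL) {
  TT <- length(responses)
  stopifnot(TT >= 2)
  rmax <- stats::quantile(unlist(responses), 0.999, names = FALSE)
  if (rmax <= 0) rmax <- max(unlist(responses), 1e-9)
  out_pen <- if (is.null(mask)) NULL else
    ifelse(mask, 0, weights[["outside_cell"]])
  cost_of <- function(r) {
    cst <- weights[["intensity"]] * (1 - pmin(r / rmax, 1))
    if (!is.null(out_pen)) cst <- cst + out_pen
    cst
  }
  offs <- expand.grid(dy = -max_displacement:max_displacement,
                      dx = -max_displacement:max_displacement)
  offs <- offs[offs$dy^2 + offs$dx^2 <= max_displacement^2, ]
  pen <- weights[["distance"]] *
    sqrt(offs$dy^2 + offs$dx^2) / max_displacement
  G <- cost_of(responses[[1]])
  BP <- vector("list", TT)
  for (t in 2:TT) {
    best <- matrix(Inf, nrow(G), ncol(G))
    barg <- matrix(1L, nrow(G), ncol(G))
    for (o in seq_len(nrow(offs))) {
      cand <- shift_matrix(G, offs$dy[o], offs$dx[o]) + pen[o]
      sel <- cand < best
      best[sel] <- cand[sel]
      barg[sel] <- o
    }
    G <- best + cost_of(responses[[t]])
    BP[[t]] <- barg
  }
  endi <- which(G == min(G), arr.ind = TRUE)[1, ]
  path <- matrix(0L, TT, 2)
  path[TT, ] <- endi
  for (t in TT:2) {
    o <- BP[[t]][path[t, 1], path[t, 2]]
    path[t - 1, ] <- c(path[t, 1] - offs$dy[o], path[t, 2] - offs$dx[o])
  }
  pos <- data.frame(frame = seq_len(TT), x = path[, 2], y = path[, 1],
                    intensity = vapply(seq_len(TT), function(t) {
                      responses[[t]][path[t, 1], path[t, 2]]
                    }, numeric(1)))
  structure(list(path = NULL, positions = pos, cost = min(G),
                 truncated = FALSE, f_t0 = NA_integer_),
            class = "track")
}

#' Detect the frame where a fading spot is lost
#'
#' Fits a two-level step function to the per-frame amplitude series by
#' least squares over all change points (equivalently, maximal correlation
#' with a step template) and compares the two levels with the detectability
#' threshold `background + k * noise_std`. Returns the last frame at which
#' the spot is still distinguishable from noise, or `NA` if the series
#' never crosses the threshold.
#'
#' @param amplitudes numeric vector of fitted per-frame amplitudes `A_t`
#'   (above local background).
#' @param background local background level, gray levels.
#' @param noise_std noise standard deviation, gray levels; estimate it from
#'   background pixels with [estimate_noise_mad()].
#' @param k threshold multiplier (threshold = background + k * noise_std;
#'   amplitudes are measured above background, so the criterion on `A_t` is
#'   `A_t >= k * noise_std`).
#' @return integer frame index `F_t0`, or `NA_integer_` (attribute `flag`
#'   explains why: `"constant"`, `"too_short"`).
#' @export
detect_loss_frame <- function(amplitudes, background = 0, noise_std,
                              k = 3) {
  n <- length(amplitudes)
  if (n < 3) {
    return(structure(NA_integer_, flag = "too_short"))
  }
  sse <- vapply(seq_len(n - 1), function(c) {
    hi <- amplitudes[1:c]
    lo <- amplitudes[(c + 1):n]
    sum((hi - mean(hi))^2) + sum((lo - mean(lo))^2)
  }, numeric(1))
  cstar <- which.min(sse)
  thr <- k * noise_std
  hi_mean <- mean(amplitudes[1:cstar])
  lo_mean <- mean(amplitudes[(cstar + 1):n])
  if (hi_mean >= thr && lo_mean < thr) {
    return(as.integer(cstar))
  }
  structure(NA_integer_, flag = "constant")
}

#' Noise standard deviation from background pixels
#'
#' Median-absolute-deviation estimate (consistent for Gaussian noise) over
#' the pixels of `image` where `mask` is TRUE (default: whole image).
#'
#' @param image numeric matrix.
#' @param mask optional logical matrix selecting background pixels.
#' @export
estimate_noise_mad <- function(image, mask = NULL) {
  px <- if (is.null(mask)) as.numeric(image) else image[mask]
  stats::mad(px)
}

#' Track two spots per cell across two channels
#'
#' For each segmented cell, detects the two reference-channel spots in
#' frame 1, tracks each with the dense DP tracker restricted to the cell's
#' rod (split along the cell midline so the two tracks cannot collapse onto
#' one pole), repeats per channel, and associates tracks across channels by
#' nearest frame-1 positions. Per-frame amplitudes come from the anchored
#' Gaussian fit at the tracked positions.
#'
#' @param channels list of channels; each channel is a list of frame
#'   matrices. Channel 1 is the reference.
#' @param cells list of fitted [rodscule_state()] objects.
#' @param log_sigma LoG scale for detection/response, px.
#' @param max_displacement per-frame bound, px.
#' @param weights a [cost_weights()] vector.
#' @param fit_window window for the per-frame amplitude fit, px.
#' @return list (one element per cell) of lists with `tracks`: per channel
#'   a list of two `track` objects (with per-frame `A`, `B` columns bound to
#'   `positions`), or `NULL` with `skipped = TRUE` when fewer than two
#'   frame-1 reference spots are found in the cell.
#' @export
track_two_spots <- function(channels, cells, log_sigma = 1.5,
                            max_displacement = 4,
                            weights = cost_weights(), fit_window = 9) {
  ref <- channels[[1]]
  TT <- length(ref)
  resp1 <- log_filter(ref[[1]], log_sigma)
  lapply(cells, function(cell) {
    nr <- nrow(ref[[1]]); nc <- ncol(ref[[1]])
    Xg <- rep(seq_len(nc), each = nr)
    Yg <- rep(seq_len(nr), times = nc)
    g <- rod_geometry(cell)
    # the admissible region is the segmented cell itself (inner rod),
    # eroded by 2 px so the cell-boundary response of the LoG filter cannot
    # capture the tracker once a spot has faded
    inrod <- stadium_coverage(Xg, Yg, g$K1, g$K2,
                              max(g$radius_inner - 2, 2)) > 0.5
    cell_mask <- matrix(inrod, nr, nc)
    det <- detect_spots(resp1, n_max = 2, min_separation = 5,
                        mask = cell_mask)
    if (nrow(det) < 2) {
      return(list(tracks = NULL, skipped = TRUE))
    }
    # split the rod along its midline so each spot is tracked in its own
    # half (the two structures sit towards opposite poles)
    ax <- (Xg - g$M[1]) * g$axis[1] + (Yg - g$M[2]) * g$axis[2]
    s1 <- sum((c(det$x[1], det$y[1]) - g$M) * g$axis)
    s2 <- sum((c(det$x[2], det$y[2]) - g$M) * g$axis)
    half1 <- matrix(inrod & (if (s1 <= s2) ax <= 0 else ax > 0), nr, nc)
    half2 <- matrix(inrod & (if (s1 <= s2) ax > 0 else ax <= 0), nr, nc)
    per_channel <- lapply(channels, function(frames) {
      resps <- lapply(frames, log_filter, sigma = log_sigma)
      lapply(list(half1, half2), function(msk) {
        tr <- track_dense(resps, max_displacement, weights, mask = msk)
        fits <- lapply(seq_len(TT), function(t) {
          tryCatch(fit_spot_gaussian(frames[[t]],
                                     c(tr$positions$x[t], tr$positions$y[t]),
                                     window = fit_window,
                                     init_sigma = log_sigma),
                   error = function(e) list(A = NA_real_, B = NA_real_))
        })
        tr$positions$A <- vapply(fits, function(f) f$A, numeric(1))
        tr$positions$B <- vapply(fits, function(f) f$B, numeric(1))
        tr
      })
    })
    list(tracks = per_channel, skipped = FALSE)
  })
}
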