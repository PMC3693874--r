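test_that("graph construction obeys causality and the displacement bound", {
  cands <- list(
    data.frame(x = 10, y = 10, intensity = 100),
    data.frame(x = 12, y = 10, intensity = 100),
    data.frame(x = 13, y = 11, intensity = 100)
  )
  g <- build_track_graph(cands, max_displacement = 4)
  expect_equal(nrow(g$edges), 2)                      # a chain
  expect_true(all(g$vertices$frame[g$edges$from] <
                    g$vertices$frame[g$edges$to]))
  # a jump far beyond the bound gets no edge
  cands_jump <- cands
  cands_jump[[2]]$x <- 50
  gj <- build_track_graph(cands_jump, max_displacement = 4)
  expect_equal(nrow(gj$edges), 0)
  expect_error(build_track_graph(list(data.frame(x = numeric(0),
                                                 y = numeric(0),
                                                 intensity = numeric(0)),
                                      cands[[2]]), 4), "source")
  # K last-frame candidates give K possible terminals
  cands_k <- list(data.frame(x = 10, y = 10, intensity = 100),
                  data.frame(x = c(9, 11, 12), y = c(10, 10, 11),
                             intensity = c(80, 90, 100)))
  gk <- build_track_graph(cands_k, 5)
  expect_equal(sum(gk$vertices$frame == 2), 3)
})

test_that("edge cost matches hand arithmetic of the declared terms", {
  w <- cost_weights(intensity = 1, intensity_variation = 0.5,
                    distance = 0.5, direction = 0.25, outside_cell = 10)
  vi <- data.frame(x = 0, y = 0, intensity_norm = 1)
  vj <- data.frame(x = 3, y = 4, intensity_norm = 0.6)
  # f_int = 0.4, f_var = 0.4, f_dist = 5/10
  expect_equal(edge_cost(vi, vj, w, max_displacement = 10),
               1 * 0.4 + 0.5 * 0.4 + 0.5 * 0.5)
  # identical intensity, zero displacement, max-normalised: zero cost
  vsame <- data.frame(x = 0, y = 0, intensity_norm = 1)
  expect_equal(edge_cost(vsame, vsame, w, 10), 0)
  # direction term: straight continuation costs 0, reversal costs lambda
  prev <- c(-3, -4)
  expect_equal(edge_cost(vi, vj, w, 10, prev = prev),
               0.4 + 0.2 + 0.25 + 0.25 * 0)
  expect_equal(edge_cost(vi, vj, w, 10, prev = c(3, 4)) -
                 edge_cost(vi, vj, w, 10, prev = prev),
               0.25 * 1)
  # outside-cell penalty is exactly additive
  cell <- rodscule_from_rod(c(0, 0), 0, 10, 5)
  far <- data.frame(x = 300, y = 300, intensity_norm = 0.6)
  expect_equal(edge_cost(vi, far, w, 1000, cell = cell) -
                 edge_cost(vi, far, w, 1000),
               10)
  expect_error(cost_weights(intensity = -1), "non-negative")
})

test_that("dynamic programming equals exhaustive enumeration", {
  set.seed(7)
  for (rep in 1:100) {
    n_frames <- sample(3:6, 1)
    cands <- random_candidates(n_frames, max_cands = 4, spread = 15)
    g <- build_track_graph(cands, max_displacement = 20)
    dp <- dp_optimal_path(g)
    bf <- brute_force_path(g)
    expect_identical(dp$path, bf$path)
    if (!dp$truncated) expect_equal(dp$cost, bf$cost, tolerance = 1e-9)
  }
})

test_that("equal-cost paths resolve ties identically in DP and oracle", {
  # two mirror-symmetric middle candidates with identical costs
  cands <- list(
    data.frame(x = 0, y = 0, intensity = 100),
    data.frame(x = c(2, 2), y = c(1, -1), intensity = c(100, 100)),
    data.frame(x = 4, y = 0, intensity = 100)
  )
  g <- build_track_graph(cands, max_displacement = 5)
  dp <- dp_optimal_path(g)
  bf <- brute_force_path(g)
  expect_identical(dp$path, bf$path)
  expect_equal(dp$cost, bf$cost, tolerance = 1e-12)
})

test_that("candidate order within frames does not change the chosen path", {
  set.seed(21)
  cands <- random_candidates(5, max_cands = 4, spread = 12)
  g <- build_track_graph(cands, max_displacement = 18)
  ref <- dp_optimal_path(g)
  perm <- lapply(cands, function(d) d[sample(nrow(d)), , drop = FALSE])
  gp <- build_track_graph(perm, max_displacement = 18)
  out <- dp_optimal_path(gp)
  expect_equal(out$positions$x, ref$positions$x, tolerance = 1e-12)
  expect_equal(out$positions$y, ref$positions$y, tolerance = 1e-12)
  expect_equal(out$cost, ref$cost, tolerance = 1e-12)
})

test_that("path cost accumulates monotonically (all terms non-negative)", {
  set.seed(9)
  cands <- random_candidates(6)
  g <- build_track_graph(cands, max_displacement = 25)
  tr <- dp_optimal_path(g)
  if (!tr$truncated) {
    v <- g$vertices
    w <- cost_weights()
    cum <- 0
    for (t in 2:length(tr$path)) {
      prev <- if (t >= 3) c(v$x[tr$path[t - 2]], v$y[tr$path[t - 2]])
              else NULL
      cc <- edge_cost(v[tr$path[t - 1], ], v[tr$path[t], ], w,
                      g$max_displacement, prev = prev)
      expect_gte(cc, 0)
      cum <- cum + cc
    }
    # G equals the recomputed sum of edge costs along the path
    expect_equal(cum, tr$cost, tolerance = 1e-9)
  }
})

test_that("unreachable last frames truncate the track with a flag", {
  cands <- list(
    data.frame(x = 10, y = 10, intensity = 100),
    data.frame(x = 12, y = 10, intensity = 100),
    data.frame(x = 90, y = 90, intensity = 100)   # unreachable
  )
  g <- build_track_graph(cands, max_displacement = 4)
  tr <- dp_optimal_path(g)
  expect_true(tr$truncated)
  expect_equal(nrow(tr$positions), 2)
})

test_that("dense DP tracks a single spot exactly on clean sequences", {
  truth <- random_walk_track(c(32, 32), 12, 2.5, c(64, 64), seed = 6)
  spec <- phantom_spec(c(64, 64),
                       spots = list(phantom_spot(truth[1, ], A = 120,
                                                 sigma = 1.5)),
                       background_intensity = 30, noise_std = 0)
  tl <- timelapse_spec(spec, 12, list(truth), list(rep(120, 12)),
                       max_step = 3)
  frames <- generate_timelapse(tl)$frames
  resps <- lapply(frames, log_filter, sigma = 1.5)
  tr <- track_dense(resps, max_displacement = 4)
  rmse <- sqrt(mean((tr$positions$x - truth[, 1])^2 +
                      (tr$positions$y - truth[, 2])^2))
  expect_lt(rmse, 1)
})

test_that("the outside-cell term saves tracking from bright distractors", {
  # a bright extracellular distractor path runs parallel to the true spot
  n <- 12
  cell <- rodscule_from_rod(c(32, 22), 0, 18, 7)
  truth <- cbind(seq(20, 42, length.out = n), rep(22, n))
  distract <- cbind(seq(20, 42, length.out = n), rep(48, n))
  frames <- lapply(seq_len(n), function(t) {
    spec <- phantom_spec(c(64, 64),
                         spots = list(phantom_spot(truth[t, ], A = 60,
                                                   sigma = 1.5),
                                      phantom_spot(distract[t, ], A = 90,
                                                   sigma = 1.5)),
                         background_intensity = 30, noise_std = 6,
                         seed = 100 + t)
    render_phantom(spec)$noisy
  })
  resps <- lapply(frames, log_filter, sigma = 1.5)
  nr <- 64; nc <- 64
  Xg <- rep(seq_len(nc), each = nr); Yg <- rep(seq_len(nr), times = nc)
  g <- rod_geometry(cell)
  mask <- matrix(rodcell:::stadium_coverage(Xg, Yg, g$K1, g$K2,
                                            g$radius_inner) > 0.5, nr, nc)
  with_pen <- track_dense(resps, 4, mask = mask)
  without <- track_dense(resps, 4)
  err_with <- sqrt(mean((with_pen$positions$x - truth[, 1])^2 +
                          (with_pen$positions$y - truth[, 2])^2))
  err_without <- sqrt(mean((without$positions$x - truth[, 1])^2 +
                             (without$positions$y - truth[, 2])^2))
  expect_lt(err_with, 2)
  expect_gt(err_without, err_with)   # it locks onto the brighter outsider
})

test_that("loss-frame detection finds step and gradual fades", {
  set.seed(12)
  sigma <- 10
  # step fade at frame 20 of 42
  amps <- c(rnorm(20, 10 * sigma, sigma), rnorm(22, 0, sigma))
  f <- detect_loss_frame(amps, noise_std = sigma)
  expect_true(abs(f - 20) <= 1)
  # linear fade crossing k*sigma at a computable frame
  profile <- seq(8 * sigma, 0, length.out = 40)
  t_star <- max(which(profile >= 3 * sigma))
  fl <- detect_loss_frame(profile + rnorm(40, 0, sigma / 2),
                          noise_std = sigma)
  expect_true(abs(fl - t_star) <= 2)
  # constant series: no loss
  expect_true(is.na(detect_loss_frame(rnorm(42, 8 * sigma, sigma),
                                      noise_std = sigma)))
  short <- detect_loss_frame(c(1, 2), noise_std = 1)
  expect_true(is.na(short))
  expect_identical(attr(short, "flag"), "too_short")
})

test_that("two spots in two channels are tracked inside their cell", {
  cellp <- phantom_cell(c(40, 32), 56, 14, 0, intensity = 100)
  sp <- list(phantom_spot(c(30, 32), A = 120, sigma = 1.3),
             phantom_spot(c(50, 32), A = 120, sigma = 1.3))
  spec <- phantom_spec(c(64, 80), cells = list(cellp), spots = sp,
                       background_intensity = 25, noise_std = 6, seed = 5)
  n <- 10
  tr1 <- cbind(seq(30, 26, length.out = n), rep(32, n))
  tr2 <- cbind(seq(50, 54, length.out = n), rep(32, n))
  tl <- timelapse_spec(spec, n, list(tr1, tr2),
                       list(rep(120, n), rep(120, n)), max_step = 2)
  frames <- generate_timelapse(tl)$frames
  res <- track_two_spots(list(frames, frames), list(truth_state(cellp)),
                         log_sigma = 1.3, max_displacement = 3)[[1]]
  expect_false(res$skipped)
  expect_length(res$tracks, 2)           # two channels
  expect_length(res$tracks[[1]], 2)      # two spots
  # identical channels give identical tracks (cross-channel association
  # is the identity)
  expect_equal(res$tracks[[1]][[1]]$positions$x,
               res$tracks[[2]][[1]]$positions$x)
  for (s in 1:2) {
    p <- res$tracks[[1]][[s]]$positions
    gt <- if (p$x[1] < 40) tr1 else tr2
    rmse <- sqrt(mean((p$x - gt[, 1])^2 + (p$y - gt[, 2])^2))
    expect_lt(rmse, 1.5)
  }
})
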