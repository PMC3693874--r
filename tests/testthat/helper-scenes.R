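# Shared builders for synthetic test scenes.

# single-cell scene used by segmentation tests: length 60, width 14,
# angle 0.3 rad, interior 229 on background 25 (8-bit)
standard_cell_scene <- function(noise_std = 0, seed = 1) {
  cell <- phantom_cell(c(60, 45), length = 60, width = 14,
                       orientation = 0.3, intensity = 229)
  spec <- phantom_spec(c(90, 120), cells = list(cell),
                       background_intensity = 25,
                       noise_std = noise_std, seed = seed)
  list(spec = spec, cell = cell, render = render_phantom(spec))
}

# ground-truth rodscule state for a phantom cell
truth_state <- function(cell) {
  rodscule_from_rod(cell$center, cell$orientation,
                    half_length = cell$length / 2 - cell$width / 2,
                    radius = cell$width / 2)
}

# mean distance between a state's inner-rod boundary and a phantom cell's
# boundary
boundary_distance <- function(state, cell, n = 200) {
  gt <- rod_geometry(truth_state(cell))
  bp <- rod_boundary_points(state, n = n)
  d <- rodcell:::point_segment_distance(bp[, 1], bp[, 2], gt$K1, gt$K2)
  mean(abs(d - gt$radius_inner))
}

# random small candidate sets for DP-vs-oracle comparisons
random_candidates <- function(n_frames, max_cands = 4, spread = 20) {
  lapply(seq_len(n_frames), function(t) {
    n <- sample.int(max_cands, 1)
    data.frame(x = runif(n, 0, spread), y = runif(n, 0, spread),
               intensity = runif(n, 50, 200))
  })
}

# wrap an angle difference into (-pi/2, pi/2]
normalize_angle_diff <- function(d) {
  d <- d %% pi
  if (d > pi / 2) d <- d - pi
  d
}

# a hand-made track object
make_track <- function(x, y, A, f_t0 = NA_integer_) {
  structure(list(
    path = NULL,
    positions = data.frame(frame = seq_along(x), x = x, y = y,
                           intensity = A, A = A),
    cost = 0, truncated = FALSE, f_t0 = f_t0
  ), class = "track")
}
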